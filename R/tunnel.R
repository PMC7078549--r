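## Ligand-tunnel geometry: an axis defined by three anchor residues and
## grid-sampled cross-section free areas along it. This is a documented
## simplification of surface-extrusion tunnel tools: the analysis consumes
## only cross-section area vs offset, which is computed directly.

#' Tunnel axis from three anchor residues
#'
#' The three anchor Calphas define a plane perpendicular to the tunnel
#' axis; the axis runs through their centroid along the plane normal,
#' extended +/- 15 A (a 30 A line), oriented so that the side containing
#' the protein centre of geometry has positive offsets.
#'
#' @param model `StructureModel`.
#' @param anchors three author residue numbers (or, with
#'   `by = "index"`, residue indices).
#' @param by "resno" (default) or "index".
#' @return object of class `TunnelAxis`: `origin` (A), `normal` (unit),
#'   `anchors`, `half_length` (15 A), `sphere_radius` (1 A).
#' @export
tunnel_axis <- function(model, anchors, by = c("resno", "index")) {
  by <- match.arg(by)
  stopifnot(length(anchors) == 3L)
  idx <- if (by == "resno") match(anchors, model$residues$resno) else anchors
  if (any(is.na(idx)) || any(idx < 1 | idx > n_residues(model)))
    stop("anchor residue(s) not found: ",
         paste(anchors[is.na(idx)], collapse = ", "), call. = FALSE)
  p <- ca_xyz(model)[idx, , drop = FALSE]
  v1 <- p[2, ] - p[1, ]; v2 <- p[3, ] - p[1, ]
  nrm <- c(v1[2] * v2[3] - v1[3] * v2[2],
           v1[3] * v2[1] - v1[1] * v2[3],
           v1[1] * v2[2] - v1[2] * v2[1])
  ln <- sqrt(sum(nrm^2))
  if (ln < 1e-8 * max(sqrt(sum(v1^2)), sqrt(sum(v2^2))))
    stop("anchor Calphas are collinear; no plane is defined", call. = FALSE)
  nrm <- unname(nrm / ln)
  origin <- unname(colMeans(p))
  cog <- colMeans(ca_xyz(model))
  if (sum(nrm * (cog - origin)) < 0) nrm <- -nrm
  structure(list(origin = origin, normal = nrm, anchors = anchors,
                 half_length = 15, sphere_radius = 1),
            class = "TunnelAxis")
}

plane_basis <- function(normal) {
  a <- if (abs(normal[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - sum(a * normal) * normal
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(normal[2] * e1[3] - normal[3] * e1[2],
          normal[3] * e1[1] - normal[1] * e1[3],
          normal[1] * e1[2] - normal[2] * e1[1])
  rbind(e1, e2)
}

heavy_atom_table <- function(model) {
  if (!is.null(model$atoms)) {
    a <- model$atoms[toupper(model$atoms$element) != "H", , drop = FALSE]
    data.frame(x = a$x, y = a$y, z = a$z, r = vdw_radius(a$element))
  } else {
    ca <- ca_xyz(model)
    data.frame(x = ca[, 1], y = ca[, 2], z = ca[, 3], r = vdw_radius("C"))
  }
}

#' Cross-section area profile along a tunnel axis
#'
#' At each offset along the 30 A axis, samples a square grid on the disc of
#' radius `max_radius` in the section plane; a grid point is free when its
#' distance to every heavy atom exceeds that atom's van der Waals radius
#' (plus `probe`). Only the connected free region containing the axis
#' point (or the free point nearest to it) counts; its area is the free
#' fraction of the disc times `pi * max_radius^2`.
#'
#' @param model `StructureModel` (heavy atoms; Calphas if atoms absent).
#' @param axis `TunnelAxis`.
#' @param step offset spacing along the axis, A (default 0.5: the 1 A
#'   spheres tiling the axis, with overlap).
#' @param max_radius maximal radial extent of a section, A (default 6).
#' @param grid grid spacing in the section plane, A (default 0.25).
#' @param probe added to every atom radius, A (default 0).
#' @return object of class `TunnelProfile`: data.frame-like list with
#'   `offsets`, `areas` (A^2) and the sampling parameters.
#' @export
cross_section_profile <- function(model, axis, step = 0.5, max_radius = 6,
                                  grid = 0.25, probe = 0) {
  at <- heavy_atom_table(model)
  axyz <- as.matrix(at[, c("x", "y", "z")])
  bb_lo <- apply(axyz, 2, min); bb_hi <- apply(axyz, 2, max)
  if (any(axis$origin < bb_lo) || any(axis$origin > bb_hi))
    warning("tunnel axis origin lies outside the model bounding box; ",
            "sections may be entirely free", call. = FALSE)
  E <- plane_basis(axis$normal)
  g <- seq(-max_radius, max_radius, by = grid)
  gx <- rep(g, times = length(g)); gy <- rep(g, each = length(g))
  in_disc <- gx^2 + gy^2 <= max_radius^2
  ndisc <- sum(in_disc)
  nside <- length(g)
  disc_area <- pi * max_radius^2
  offsets <- seq(-axis$half_length, axis$half_length, by = step)
  rmax <- max(at$r) + probe
  areas <- numeric(length(offsets))
  adot <- axyz %*% axis$normal
  o_dot <- sum(axis$origin * axis$normal)
  for (oi in seq_along(offsets)) {
    center <- axis$origin + offsets[oi] * axis$normal
    near <- which(abs(adot - (o_dot + offsets[oi])) <= rmax)
    if (length(near)) {
      rel <- sweep(axyz[near, , drop = FALSE], 2, center)
      rad <- sqrt(rowSums(rel^2) - (rel %*% axis$normal)^2)
      near <- near[rad <= max_radius + rmax]
    }
    free <- matrix(FALSE, nside, nside)
    if (length(near) == 0L) {
      free[matrix(in_disc, nside, nside)] <- TRUE
    } else {
      pts <- cbind(gx, gy) %*% E
      pts <- pts + matrix(center, nrow(pts), 3, byrow = TRUE)
      sub <- axyz[near, , drop = FALSE]
      rr <- (at$r[near] + probe)^2
      ok <- rep(TRUE, length(gx))
      for (k in seq_along(near)) {
        dx <- pts[, 1] - sub[k, 1]; dy <- pts[, 2] - sub[k, 2]
        dz <- pts[, 3] - sub[k, 3]
        ok <- ok & (dx * dx + dy * dy + dz * dz > rr[k])
        }
      free[] <- ok & in_disc
    }
    areas[oi] <- connected_free_area(free, nside, ndisc, disc_area)
  }
  structure(list(offsets = offsets, areas = areas,
                 step = step, max_radius = max_radius, grid = grid,
                 probe = probe, axis = axis),
            class = "TunnelProfile")
}

## flood fill (4-connectivity) from the grid cell nearest the axis point;
## returns the component's share of the disc area
connected_free_area <- function(free, nside, ndisc, disc_area) {
  if (!any(free)) return(0)
  c0 <- (nside + 1L) %/% 2L
  if (free[c0, c0]) {
    seed <- c(c0, c0)
  } else {
    idx <- which(free, arr.ind = TRUE)
    d2 <- (idx[, 1] - c0)^2 + (idx[, 2] - c0)^2
    seed <- idx[which.min(d2), ]
  }
  comp <- matrix(FALSE, nside, nside)
  stack_r <- integer(nside * nside); stack_c <- integer(nside * nside)
  top <- 1L; stack_r[1] <- seed[1]; stack_c[1] <- seed[2]
  comp[seed[1], seed[2]] <- TRUE
  while (top > 0L) {
    r <- stack_r[top]; cc <- stack_c[top]; top <- top - 1L
    for (dd in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
      nr <- r + dd[1]; ncol <- cc + dd[2]
      if (nr >= 1L && nr <= nside && ncol >= 1L && ncol <= nside &&
          free[nr, ncol] && !comp[nr, ncol]) {
        comp[nr, ncol] <- TRUE
        top <- top + 1L
        stack_r[top] <- nr; stack_c[top] <- ncol
      }
    }
  }
  sum(comp) / ndisc * disc_area
}

#' Per-offset gain and loss between two tunnel profiles
#'
#' @param native,deformed `TunnelProfile`s on identical offset grids.
#' @return data.frame with offset, native, deformed, gain, loss (A^2);
#'   attributes `integrated_gain` and `integrated_loss` hold the
#'   trapezoidal integrals (A^2 * A).
#' @export
profile_difference <- function(native, deformed) {
  if (length(native$offsets) != length(deformed$offsets) ||
      max(abs(native$offsets - deformed$offsets)) > 1e-9)
    stop("profiles are on different offset grids", call. = FALSE)
  gain <- pmax(deformed$areas - native$areas, 0)
  loss <- pmax(native$areas - deformed$areas, 0)
  out <- data.frame(offset = native$offsets, native = native$areas,
                    deformed = deformed$areas, gain = gain, loss = loss)
  trap <- function(y) sum(diff(native$offsets) * (utils::head(y, -1) +
                                                    utils::tail(y, -1)) / 2)
  attr(out, "integrated_gain") <- trap(gain)
  attr(out, "integrated_loss") <- trap(loss)
  out
}

#' Constriction of a tunnel profile
#'
#' The minimum cross-section area within an offset window; the tunnel
#' bottleneck near the catalytic site. Ties break toward smaller offset.
#'
#' @param profile `TunnelProfile`.
#' @param window length-2 offset range (default: whole profile).
#' @return list with `offset` and `area`.
#' @export
constriction <- function(profile, window = range(profile$offsets)) {
  sel <- profile$offsets >= window[1] & profile$offsets <= window[2]
  if (!any(sel)) stop("empty offset window", call. = FALSE)
  off <- profile$offsets[sel]; ar <- profile$areas[sel]
  i <- which.min(ar)  # first minimum = smallest offset on ties
  list(offset = off[i], area = ar[i])
}
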