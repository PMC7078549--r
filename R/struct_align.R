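## Structural superposition, gap-free aligned-core extraction, pairwise
## RMSD matrices and their hierarchical clustering.

#' Construct an AlignedCore
#'
#' The aligned core is the set of alignment columns occupied (gap-free) in
#' every structure of a dataset; each structure maps every column to
#' exactly one residue, in increasing order.
#'
#' @param indices named list of strictly increasing integer vectors, one
#'   per structure, all the same length (1-based residue indices).
#' @export
aligned_core <- function(indices) {
  stopifnot(is.list(indices), !is.null(names(indices)))
  len <- unique(vapply(indices, length, 1L))
  if (length(len) != 1L)
    stop("all structures must map the same number of core columns",
         call. = FALSE)
  for (nm in names(indices)) {
    v <- indices[[nm]]
    if (len > 1 && any(diff(v) <= 0))
      stop("core indices for '", nm, "' are not strictly increasing",
           call. = FALSE)
  }
  structure(list(n_col = len, indices = indices), class = "AlignedCore")
}

#' @export
print.AlignedCore <- function(x, ...) {
  cat("AlignedCore:", x$n_col, "columns over", length(x$indices),
      "structures\n")
  invisible(x)
}

#' Aligned core from a gapped FASTA alignment
#'
#' Reads a (structure-based) multiple alignment in gapped FASTA and maps
#' its gap-free columns onto residue indices of each structure. Each
#' record's ungapped sequence must match the corresponding structure's
#' residue sequence.
#'
#' @param fasta path to a gapped FASTA file.
#' @param structures named list of `StructureModel`s. Records are matched
#'   to structures by name when all FASTA names match, otherwise by order.
#' @return `AlignedCore`.
#' @export
load_alignment <- function(fasta, structures) {
  aln <- Biostrings::readAAStringSet(fasta)
  recs <- toupper(as.character(aln))
  rnames <- sub(" .*", "", names(aln))
  if (is.null(names(structures)))
    names(structures) <- vapply(structures, function(m) m$id, "")
  if (all(rnames %in% names(structures))) {
    structures <- structures[rnames]
  } else if (length(recs) != length(structures)) {
    stop("alignment has ", length(recs), " records but ",
         length(structures), " structures were given", call. = FALSE)
  }
  ncol_aln <- unique(nchar(recs))
  if (length(ncol_aln) != 1L)
    stop("alignment records differ in length", call. = FALSE)
  mats <- lapply(recs, function(s) strsplit(s, "")[[1]])
  for (k in seq_along(structures)) {
    ung <- paste(mats[[k]][!mats[[k]] %in% c("-", ".")], collapse = "")
    seq_k <- model_sequence(structures[[k]])
    if (ung != seq_k) {
      mis <- which(strsplit(ung, "")[[1]] !=
                     strsplit(seq_k, "")[[1]][seq_len(nchar(ung))])
      stop("alignment record for '", names(structures)[k],
           "' disagrees with the structure sequence (first mismatch at ",
           "position ", if (length(mis)) mis[1] else nchar(seq_k) + 1, ")",
           call. = FALSE)
    }
  }
  gapfree <- Reduce(`&`, lapply(mats, function(v) !v %in% c("-", ".")))
  idx <- lapply(mats, function(v) cumsum(!v %in% c("-", "."))[gapfree])
  names(idx) <- names(structures)
  aligned_core(idx)
}

## Longest increasing subsequence (on the second column), used to keep
## residue correspondences sequential.
lis_select <- function(values) {
  n <- length(values)
  if (n == 0L) return(integer(0))
  parent <- integer(n); tails <- integer(0); tails_idx <- integer(0)
  for (i in seq_len(n)) {
    ## binary search: first tail >= values[i]
    lo <- 1L; hi <- length(tails_idx) + 1L
    while (lo < hi) {
      mid <- (lo + hi) %/% 2L
      if (values[tails_idx[mid]] < values[i]) lo <- mid + 1L else hi <- mid
    }
    pos <- lo
    parent[i] <- if (pos > 1L) tails_idx[pos - 1L] else 0L
    tails_idx[pos] <- i
  }
  out <- integer(0); cur <- tails_idx[length(tails_idx)]
  while (cur > 0L) { out <- c(cur, out); cur <- parent[cur] }
  out
}

#' Iterative Calpha core alignment of a structure dataset
#'
#' Pairwise-aligns every structure to a reference by iterated rigid
#' superposition and nearest-Calpha correspondence (residues paired when
#' their Calphas are within `cutoff` A after fitting, kept one-to-one and
#' sequential), re-fitting until the correspondence set is stable, then
#' intersects the pairwise correspondences into a common core. A
#' deterministic stand-in for an external structure-based aligner when one
#' is not supplied.
#'
#' @param structures named list of `StructureModel`s (>= 2).
#' @param reference name (or index) of the reference structure.
#' @param cutoff correspondence distance cutoff, A (default 4.0).
#' @param max_iter iteration cap per pair (default 50).
#' @return `AlignedCore`.
#' @export
iterative_core_align <- function(structures, reference = 1L,
                                 cutoff = 4.0, max_iter = 50L) {
  if (length(structures) < 2L) stop("need at least 2 structures", call. = FALSE)
  if (is.null(names(structures)))
    names(structures) <- vapply(structures, function(m) m$id, "")
  ref_name <- if (is.character(reference)) reference else names(structures)[reference]
  ref <- ca_xyz(structures[[ref_name]])
  maps <- list()
  for (nm in setdiff(names(structures), ref_name)) {
    mob <- ca_xyz(structures[[nm]])
    n0 <- min(nrow(mob), nrow(ref))
    corr <- cbind(seq_len(n0), seq_len(n0))
    for (it in seq_len(max_iter)) {
      fit <- superimpose(mob, ref, corr)
      moved <- apply_transform(mob, fit)
      ## nearest mobile Calpha for each reference residue
      dmat <- outer(rowSums(ref^2), rep(1, nrow(moved))) +
        outer(rep(1, nrow(ref)), rowSums(moved^2)) - 2 * ref %*% t(moved)
      dmat[dmat < 0] <- 0
      nn <- apply(dmat, 1, which.min)
      nd <- sqrt(dmat[cbind(seq_len(nrow(ref)), nn)])
      cand <- cbind(mobile = nn, ref = seq_len(nrow(ref)))[nd < cutoff, ,
                                                           drop = FALSE]
      cand_d <- nd[nd < cutoff]
      ## one-to-one: keep the closest reference residue per mobile residue
      ord <- order(cand_d)
      cand <- cand[ord, , drop = FALSE]
      cand <- cand[!duplicated(cand[, "mobile"]), , drop = FALSE]
      cand <- cand[order(cand[, "ref"]), , drop = FALSE]
      ## sequential: longest increasing subsequence of mobile indices
      keep <- lis_select(cand[, "mobile"])
      new_corr <- cbind(cand[keep, "mobile"], cand[keep, "ref"])
      if (nrow(new_corr) < 3L)
        stop("correspondence between '", nm, "' and the reference collapsed ",
             "below 3 residues", call. = FALSE)
      if (nrow(new_corr) == nrow(corr) && all(new_corr == corr)) break
      corr <- new_corr
    }
    maps[[nm]] <- corr
  }
  common_ref <- Reduce(intersect, lapply(maps, function(m) m[, 2]))
  common_ref <- sort(common_ref)
  if (length(common_ref) < 3L)
    stop("no common core: fewer than 3 columns shared by all structures",
         call. = FALSE)
  idx <- stats::setNames(vector("list", length(structures)), names(structures))
  idx[[ref_name]] <- common_ref
  for (nm in names(maps)) {
    m <- maps[[nm]]
    idx[[nm]] <- m[match(common_ref, m[, 2]), 1]
  }
  aligned_core(idx)
}

#' Pairwise RMSD matrix over an aligned core
#'
#' Entry (i, j) is the minimal (least-squares superposed) Calpha RMSD
#' between structures i and j over the core columns.
#'
#' @param structures named list of `StructureModel`s.
#' @param core `AlignedCore` covering all of them.
#' @return object of class `DistanceMatrix`: list with `labels`, `matrix`
#'   (symmetric, zero diagonal, A) and `kind = "rmsd"`.
#' @export
rmsd_matrix <- function(structures, core) {
  if (is.null(names(structures)))
    names(structures) <- vapply(structures, function(m) m$id, "")
  nms <- names(structures)
  stopifnot(all(nms %in% names(core$indices)))
  n <- length(nms)
  m <- matrix(0, n, n, dimnames = list(nms, nms))
  coords <- lapply(nms, function(nm)
    ca_xyz(structures[[nm]])[core$indices[[nm]], , drop = FALSE])
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    m[i, j] <- m[j, i] <- superimpose(coords[[j]], coords[[i]])$rmsd
  }
  structure(list(labels = nms, matrix = m, kind = "rmsd"),
            class = "DistanceMatrix")
}

#' @export
print.DistanceMatrix <- function(x, ...) {
  cat("DistanceMatrix (", x$kind, "): ", length(x$labels), " labels\n", sep = "")
  print(round(x$matrix, 3))
  invisible(x)
}

#' Hierarchical clustering of a distance matrix
#'
#' Agglomerative clustering (default: average linkage) of a symmetric
#' distance matrix, with Newick text and optional heatmap artifacts.
#'
#' @param dm `DistanceMatrix` or plain symmetric matrix with zero diagonal.
#' @param linkage hclust method (default "average").
#' @param heatmap_file optional path for a clustered heatmap (png).
#' @param newick_file optional path for the dendrogram in Newick text.
#' @return list with `hclust`, `order` (ordered labels), `newick`.
#' @export
cluster_distances <- function(dm, linkage = "average",
                              heatmap_file = NULL, newick_file = NULL) {
  m <- if (inherits(dm, "DistanceMatrix")) dm$matrix else as.matrix(dm)
  if (nrow(m) != ncol(m) || max(abs(m - t(m))) > 1e-8)
    stop("distance matrix must be symmetric", call. = FALSE)
  if (nrow(m) == 1L) {
    return(list(hclust = NULL, order = rownames(m),
                newick = paste0("(", rownames(m), ");")))
  }
  hc <- stats::hclust(stats::as.dist(m), method = linkage)
  nwk <- ape::write.tree(ape::as.phylo(hc))
  if (!is.null(newick_file)) writeLines(nwk, newick_file)
  if (!is.null(heatmap_file)) {
    pheatmap::pheatmap(m, cluster_rows = hc, cluster_cols = hc,
                       filename = heatmap_file, silent = TRUE)
  }
  list(hclust = hc, order = hc$labels[hc$order], newick = nwk)
}

#' Cut a clustering into k groups
#' @param cl result of [cluster_distances()].
#' @param k number of groups.
#' @export
cluster_groups <- function(cl, k) {
  stats::cutree(cl$hclust, k = k)
}
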