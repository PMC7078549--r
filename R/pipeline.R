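## End-to-end orchestration: a run configuration (YAML-able list) drives
## alignment, normal modes, fluctuation/correlation profiles, the
## Bhattacharyya comparison, conformer generation and tunnel profiling,
## writing a reproducible artifact tree with a machine-readable manifest.

#' Build a run configuration
#'
#' @param structures list of `list(path =, chain =, group =)` entries, or
#'   a named list of in-memory `StructureModel`s.
#' @param reference id (name) of the reference structure.
#' @param alignment optional path to an external gapped FASTA alignment;
#'   when NULL the internal iterative Calpha aligner is used.
#' @param constants ENM force-field constants ([enm_constants()]).
#' @param n_modes number of internal modes for conformer generation
#'   (default 6: reported modes 7-12).
#' @param amplitude conformer amplitude factor (default 15).
#' @param anchors optional named list of 3-vectors of anchor residue
#'   numbers per structure (enables the tunnel stage).
#' @param blocks optional named list of residue-index blocks for
#'   correlation-domain summaries.
#' @param seed integer seed recorded and used for any sampling stage.
#' @param bc_variance_fraction subspace fraction for [bc_score()].
#' @export
run_config <- function(structures, reference, alignment = NULL,
                       constants = enm_constants(), n_modes = 6L,
                       amplitude = 15, anchors = NULL, blocks = NULL,
                       seed = 1L, bc_variance_fraction = 0.95) {
  cfg <- list(structures = structures, reference = reference,
              alignment = alignment, constants = constants,
              n_modes = n_modes, amplitude = amplitude,
              anchors = anchors, blocks = blocks, seed = as.integer(seed),
              bc_variance_fraction = bc_variance_fraction)
  class(cfg) <- "natdyn_config"
  cfg
}

#' Read a run configuration from YAML
#' @param path YAML file.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  cn <- y$constants
  constants <- if (is.null(cn)) enm_constants() else
    enm_constants(a = cn$a, b = cn$b, c = cn$c, d = cn$d)
  run_config(structures = y$structures,
             reference = y$reference,
             alignment = y$alignment,
             constants = constants,
             n_modes = if (is.null(y$n_modes)) 6L else as.integer(y$n_modes),
             amplitude = if (is.null(y$amplitude)) 15 else y$amplitude,
             anchors = y$anchors, blocks = y$blocks,
             seed = if (is.null(y$seed)) 1L else y$seed,
             bc_variance_fraction =
               if (is.null(y$bc_variance_fraction)) 0.95
               else y$bc_variance_fraction)
}

#' Validate a run configuration
#'
#' Checks referenced files exist and groups are non-empty before any
#' computation starts.
#' @param config from [run_config()] or [read_config()].
#' @export
validate_config <- function(config) {
  st <- config$structures
  if (length(st) == 0L) stop("no structures in configuration", call. = FALSE)
  from_files <- !inherits(st[[1]], "StructureModel")
  if (from_files) {
    for (s in st) {
      if (is.null(s$path) || !file.exists(s$path))
        stop("structure file missing: ", s$path, call. = FALSE)
      if (is.null(s$chain)) stop("structure entry lacks a chain", call. = FALSE)
      if (is.null(s$group) || !nzchar(s$group))
        stop("structure entry lacks a group label", call. = FALSE)
    }
  }
  if (!is.null(config$alignment) && !file.exists(config$alignment))
    stop("alignment file missing: ", config$alignment, call. = FALSE)
  invisible(TRUE)
}

load_config_structures <- function(config) {
  st <- config$structures
  if (inherits(st[[1]], "StructureModel")) {
    if (is.null(names(st)))
      names(st) <- vapply(st, function(m) m$id, "")
    return(st)
  }
  models <- list()
  for (s in st) {
    m <- read_structure(s$path, s$chain, strip_het = TRUE)
    models[[m$id]] <- m
  }
  models
}

run_stage <- function(name, log, expr) {
  t0 <- Sys.time()
  res <- tryCatch(withCallingHandlers(expr, warning = function(w) {
    log$warnings <- c(log$warnings, paste0(name, ": ", conditionMessage(w)))
    invokeRestart("muffleWarning")
  }), error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
  log$timings[[name]] <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  res
}

#' Run the full comparative-dynamics pipeline
#'
#' Produces under `out_dir`: the pairwise RMSD matrix with heatmap and
#' dendrogram, per-structure normalized fluctuation profiles (CSV +
#' overlay plot), correlation maps (CSV) with optional domain-block
#' summaries, the Bhattacharyya similarity matrix with heatmap and
#' dendrogram, per-mode conformers (PDB) with metadata, optional tunnel
#' profiles with per-mode gain/loss tables and panels, and
#' `manifest.json` recording versions, seeds, parameters and checksums of
#' the deterministic text artifacts.
#'
#' @param config from [run_config()].
#' @param out_dir output directory (created).
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- new.env(); log$warnings <- character(0); log$timings <- list()

  models <- run_stage("read", log, load_config_structures(config))
  ref <- config$reference
  if (!ref %in% names(models))
    stop("reference '", ref, "' is not among the structures", call. = FALSE)

  core <- run_stage("align", log, {
    if (!is.null(config$alignment))
      load_alignment(config$alignment, models)
    else iterative_core_align(models, reference = ref)
  })

  rmat <- run_stage("rmsd", log, rmsd_matrix(models, core))
  utils::write.csv(rmat$matrix, file.path(out_dir, "rmsd_matrix.csv"))
  cl <- cluster_distances(rmat,
                          heatmap_file = file.path(out_dir, "rmsd_heatmap.png"),
                          newick_file = file.path(out_dir, "rmsd_dendrogram.nwk"))

  nm <- run_stage("modes", log, {
    lapply(models, function(m) {
      net <- build_network(ca_xyz(m), constants = config$constants)
      list(network = net, modes = compute_modes(net))
    })
  })

  run_stage("fluct", log, {
    prof <- lapply(nm, function(x) fluctuations(x$modes)$fluctuations)
    maxn <- max(vapply(prof, length, 1L))
    tab <- data.frame(residue_index = seq_len(maxn))
    for (nmod in names(prof))
      tab[[nmod]] <- c(prof[[nmod]], rep(NA, maxn - length(prof[[nmod]])))
    utils::write.csv(tab, file.path(out_dir, "fluctuations.csv"),
                     row.names = FALSE)
    grDevices::png(file.path(out_dir, "fluctuations.png"), 900, 500)
    graphics::matplot(tab$residue_index, as.matrix(tab[, -1]), type = "l",
                      lty = 1, xlab = "residue index",
                      ylab = "normalized fluctuation")
    graphics::legend("topright", legend = names(prof), col = seq_along(prof),
                     lty = 1, cex = 0.7)
    grDevices::dev.off()
    NULL
  })

  run_stage("corr", log, {
    blocks_out <- NULL
    for (nmod in names(nm)) {
      cm <- correlations(nm[[nmod]]$modes)
      utils::write.csv(cm$map,
                       file.path(out_dir, paste0("correlations_", nmod, ".csv")),
                       row.names = FALSE)
      if (!is.null(config$blocks)) {
        db <- domain_blocks(cm, lapply(config$blocks, function(b)
          seq(b[[1]], b[[2]])))
        db$structure <- nmod
        blocks_out <- rbind(blocks_out, db)
      }
    }
    if (!is.null(blocks_out))
      utils::write.csv(blocks_out, file.path(out_dir, "domain_blocks.csv"),
                       row.names = FALSE)
    NULL
  })

  bc <- run_stage("bc", log, {
    refca <- ca_xyz(models[[ref]])[core$indices[[ref]], , drop = FALSE]
    covs <- lapply(names(models), function(nmod) {
      mob <- ca_xyz(models[[nmod]])[core$indices[[nmod]], , drop = FALSE]
      rot <- if (nmod == ref) NULL else superimpose(mob, refca)$rotation
      core_covariance(nm[[nmod]]$modes, core$indices[[nmod]], rotation = rot,
                      id = nmod)
    })
    names(covs) <- names(models)
    bcm <- bc_matrix(covs, variance_fraction = config$bc_variance_fraction,
                     heatmap_file = file.path(out_dir, "bc_heatmap.png"),
                     newick_file = file.path(out_dir, "bc_dendrogram.nwk"))
    utils::write.csv(bcm$matrix, file.path(out_dir, "bc_matrix.csv"))
    bcm
  })

  run_stage("conformers", log, {
    meta_all <- NULL
    conf_dir <- file.path(out_dir, "conformers")
    dir.create(conf_dir, showWarnings = FALSE)
    for (nmod in names(models)) {
      sweep_res <- mode_sweep(models[[nmod]], nm[[nmod]]$network,
                              nm[[nmod]]$modes,
                              mode_numbers = 6 + seq_len(config$n_modes),
                              amplitude = config$amplitude)
      for (key in names(sweep_res$conformers))
        write_model(sweep_res$conformers[[key]],
                    file.path(conf_dir, paste0(nmod, "_", key, ".pdb")))
      meta_all <- rbind(meta_all, sweep_res$metadata)
    }
    utils::write.csv(meta_all, file.path(out_dir, "conformer_metadata.csv"),
                     row.names = FALSE)
    meta_all
  })

  if (!is.null(config$anchors)) run_stage("tunnel", log, {
    tun_dir <- file.path(out_dir, "tunnel")
    dir.create(tun_dir, showWarnings = FALSE)
    for (nmod in intersect(names(config$anchors), names(models))) {
      anch <- unlist(config$anchors[[nmod]])
      axis <- tunnel_axis(models[[nmod]], anch)
      native <- cross_section_profile(models[[nmod]], axis)
      tab <- data.frame(offset = native$offsets, native = native$areas)
      for (m in 6 + seq_len(config$n_modes)) for (s in c(1, -1)) {
        cf <- displace_along_mode(models[[nmod]], nm[[nmod]]$modes, m,
                                  config$amplitude, s)
        rx <- relax_in_mode_space(cf$xyz, nm[[nmod]]$network,
                                  nm[[nmod]]$modes, exclude_modes = m)
        dm <- models[[nmod]]
        dm$residues[, c("x", "y", "z")] <- rx$xyz
        if (!is.null(dm$atoms)) dm <- rebuild_all_atom(models[[nmod]], rx$xyz)
        prof <- cross_section_profile(dm, tunnel_axis(dm, anch))
        dif <- profile_difference(native, prof)
        key <- sprintf("m%d%s", m, if (s > 0) "p" else "n")
        tab[[paste0(key, "_area")]] <- prof$areas
        tab[[paste0(key, "_gain")]] <- dif$gain
        tab[[paste0(key, "_loss")]] <- dif$loss
      }
      utils::write.csv(tab, file.path(tun_dir, paste0(nmod, "_profile.csv")),
                       row.names = FALSE)
      grDevices::png(file.path(tun_dir, paste0(nmod, "_panels.png")), 900, 900)
      graphics::par(mfrow = c(config$n_modes, 1), mar = c(2, 4, 1, 1))
      for (m in 6 + seq_len(config$n_modes)) {
        pa <- tab[[sprintf("m%dp_area", m)]]
        na_ <- tab[[sprintf("m%dn_area", m)]]
        graphics::matplot(tab$offset, cbind(tab$native, pa, na_), type = "l",
                          lty = 1, col = c("black", "orange", "blue"),
                          ylab = sprintf("mode %d area", m))
      }
      grDevices::dev.off()
    }
    NULL
  })

  text_artifacts <- sort(setdiff(
    list.files(out_dir, recursive = TRUE),
    c("manifest.json",
      grep("\\.png$", list.files(out_dir, recursive = TRUE), value = TRUE))))
  manifest <- list(
    package = "natdyn",
    version = as.character(utils::packageVersion("natdyn")),
    seed = config$seed,
    parameters = list(constants = config$constants,
                      n_modes = config$n_modes,
                      amplitude = config$amplitude,
                      bc_variance_fraction = config$bc_variance_fraction,
                      reference = config$reference),
    structures = names(models),
    core_columns = core$n_col,
    warnings = log$warnings,
    checksums = as.list(tools::md5sum(file.path(out_dir, text_artifacts))))
  names(manifest$checksums) <- text_artifacts
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
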