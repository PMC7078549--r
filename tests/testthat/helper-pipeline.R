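## small three-structure synthetic dataset written as PDB files + config
small_spec <- function(seed) {
  fold_spec(list(
    list(type = "strand", length = 5), list(type = "loop", length = 3),
    list(type = "helix", length = 8), list(type = "loop", length = 3),
    list(type = "strand", length = 5), list(type = "loop", length = 3),
    list(type = "strand", length = 5), list(type = "loop", length = 3),
    list(type = "helix", length = 8), list(type = "loop", length = 3),
    list(type = "strand", length = 5)), seed = seed)
}

make_pipeline_config <- function(dir, seed = 1) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  base <- make_fold(small_spec(seed), id = "s1")
  entries <- list()
  for (k in 1:3) {
    m <- if (k == 1) base else perturb(base, 0.3, seed = seed * 10 + k)
    m$id <- paste0("s", k)
    p <- file.path(dir, paste0("s", k, ".pdb"))
    write_model(m, p)
    entries[[k]] <- list(path = p, chain = "A", group = paste0("g", k))
  }
  run_config(structures = entries, reference = "s1_A",
             n_modes = 2, amplitude = 15,
             anchors = list(s1_A = c(10, 25, 40)),
             blocks = list(nterm = c(1, 25), cterm = c(26, 51)),
             seed = seed)
}
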