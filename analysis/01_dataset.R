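#!/usr/bin/env Rscript
## Build the synthetic study dataset: nine Calpha structures on the shared
## sandwich fold, in three groups whose elastic networks differ in overall
## stiffness (mimicking families with distinct intrinsic dynamics), plus a
## run configuration. Everything downstream reads from results/data.

suppressMessages(library(natdyn))

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

groups <- list(main = 1.0, inter = 0.5, outlier = 0.15)  # stiffness scale
base <- make_fold(default_fold_spec(seed = 42), id = "ref")

entries <- list()
meta <- NULL
k <- 0
for (g in names(groups)) {
  for (r in 1:3) {
    k <- k + 1
    m <- if (k == 1) base else perturb(base, 0.3, seed = 100 + k)
    m$id <- sprintf("%s%d", g, r)
    path <- file.path(out, paste0(m$id, ".pdb"))
    write_model(m, path)
    entries[[k]] <- list(path = path, chain = "A", group = g)
    meta <- rbind(meta, data.frame(id = paste0(m$id, "_A"), group = g,
                                   stiffness = groups[[g]]))
  }
}
write.csv(meta, file.path(out, "dataset.csv"), row.names = FALSE)

cfg <- list(reference = "main1_A", n_modes = 6, amplitude = 15, seed = 42,
            structures = entries,
            anchors = list(main1_A = c(30, 75, 110)))
yaml::write_yaml(cfg, file.path(out, "config.yaml"))

cat("wrote", k, "structures (", nrow(ca_xyz(base)), "residues each) and",
    "config.yaml under", out, "\n")
cat("groups:", paste(sprintf("%s (stiffness x%.2f)", names(groups),
                             unlist(groups)), collapse = ", "), "\n")
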