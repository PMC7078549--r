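#!/usr/bin/env Rscript
## Intrinsic dynamics stage: elastic-network normal modes per structure,
## normalized fluctuation profiles (overlaid across the dataset), and the
## cross-correlation map of the reference with a two-block domain summary
## across the sheet's central split.

suppressMessages(library(natdyn))

data_dir <- "results/data"
out <- "results/analysis"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

meta <- read.csv(file.path(data_dir, "dataset.csv"))
profs <- list()
for (id in meta$id) {
  m <- read_structure(file.path(data_dir, paste0(sub("_A$", "", id), ".pdb")),
                      "A")
  suppressWarnings(md <- compute_modes(build_network(ca_xyz(m))))
  profs[[id]] <- fluctuations(md)$fluctuations
  if (id == meta$id[1]) {
    write_modes(md, file.path(out, "reference_modes.txt"), n_modes = 12)
    cm <- correlations(md)
    write.csv(cm$map, file.path(out, "reference_correlations.csv"),
              row.names = FALSE)
    n <- length(profs[[id]])
    ## split at the midpoint of the element order, the analogue of the
    ## groove between the central strands of the sandwich
    db <- domain_blocks(cm, list(nterm = 1:62, cterm = 63:n))
    write.csv(db, file.path(out, "reference_domain_blocks.csv"),
              row.names = FALSE)
    inter <- db[db$block_a != db$block_b, ]
    intra <- db[db$block_a == db$block_b, ]
    cat(sprintf("reference domains: intra max |C| %.2f / %.2f, inter max |C| %.2f\n",
                intra$max_abs_c[1], intra$max_abs_c[2], inter$max_abs_c))
  }
}

tab <- data.frame(residue_index = seq_along(profs[[1]]))
for (id in names(profs)) tab[[id]] <- profs[[id]]
write.csv(tab, file.path(out, "fluctuations.csv"), row.names = FALSE)

png(file.path(out, "fluctuations.png"), 1000, 500)
matplot(tab$residue_index, as.matrix(tab[, -1]), type = "l", lty = 1,
        col = as.integer(factor(meta$group)),
        xlab = "residue index", ylab = "normalized fluctuation")
legend("topright", legend = unique(meta$group),
       col = seq_along(unique(meta$group)), lty = 1)
dev.off()

peaks <- order(profs[[1]], decreasing = TRUE)[1:10]
cat("most flexible residues of the reference:",
    paste(sort(peaks), collapse = " "), "\n")
cat("profiles written for", length(profs), "structures\n")
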