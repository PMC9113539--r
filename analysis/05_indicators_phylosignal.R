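#!/usr/bin/env Rscript
# Indicator OTUs per elevation zone on the selection transect, then the
# phylogenetic-signal battery: preferred elevation against the true
# Brownian optima, bootstrap patristic-distance nulls for High and Low
# indicator sets, clade-divergence contrasts, and root-to-tip distances
# by indicator type.

suppressMessages(library(elevassembly))

d <- "results/datasets/wm_selection"
stopifnot(dir.exists(d))
dir.create("results/indicators", showWarnings = FALSE, recursive = TRUE)
seed <- 31L

tab <- read_otu_table(file.path(d, "otu_table.tsv"))
md <- read_metadata(file.path(d, "metadata.tsv"))
tree <- read_tree(file.path(d, "tree.nwk"))
vd <- validate_dataset(tab, md, tree)
zones <- assign_zones(vd$metadata$elevation)

iv <- indval(normalize(vd$table, "css"), zones, n_perm = 999, seed = seed)
write.table(iv, "results/indicators/indval.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
sig <- iv[iv$significant & iv$group %in% c("High", "Low"), ]
message(sprintf("significant indicators: %d High, %d Low (alpha = 0.05)",
                sum(sig$group == "High"), sum(sig$group == "Low")))

pe <- suppressWarnings(preferred_elevation(vd$table, vd$metadata))
write.table(pe, "results/indicators/preferred_elevation.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
side <- jsonlite::read_json(file.path(d, "simulation.json"))
true_opt <- unlist(side$true_optima)
ok <- !is.na(pe$preferred_elevation)
message(sprintf("preferred elevation vs true optimum: Pearson r = %.3f (%d OTUs)",
                cor(pe$preferred_elevation[ok], true_opt[pe$otu_id[ok]]),
                sum(ok)))

for (z in c("High", "Low")) {
  ids <- sig$otu_id[sig$group == z]
  if (length(ids) < 2) next
  bp <- bootstrap_pd_null(ids, otu_ids(vd$table), vd$tree, n_boot = 1000,
                          seed = seed + 1L)
  message(sprintf(
    "%s indicators: mean pairwise patristic %.3f vs null 95%% [%.3f, %.3f], p = %.3g",
    z, bp$observed, bp$ci[1], bp$ci[2], bp$p))
}

if (nrow(sig) >= 4 && length(unique(sig$group)) == 2) {
  labels <- setNames(tolower(sig$group), sig$otu_id)
  cd <- suppressWarnings(clade_divergence_test(vd$tree, labels,
                                               seed = seed + 2L))
  write.table(cd$clades, "results/indicators/clades.tsv", sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(cd$comparisons, "results/indicators/clade_comparisons.tsv",
              sep = "\t", quote = FALSE, row.names = FALSE)
  rt <- root_to_tip(vd$tree, sig$otu_id, labels)
  print(rt$summary)
  message(sprintf("root-to-tip Kruskal-Wallis p = %.3g", rt$kruskal$p))
}
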