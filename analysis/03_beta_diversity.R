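#!/usr/bin/env Rscript
# Beta diversity and matrix-correlation inference per dataset: unweighted
# UniFrac, Bray-Curtis, the Sorensen turnover/nestedness partition, ANOSIM
# by elevation zone, Mantel and partial-Mantel tests of beta diversity
# against elevation controlling for horizontal distance, and the Mantel
# correlogram of distance decay.

suppressMessages(library(elevassembly))

dirs <- list.dirs("results/datasets", recursive = FALSE)
dir.create("results/beta", showWarnings = FALSE, recursive = TRUE)
seed <- 11L

for (d in dirs) {
  name <- basename(d)
  tab <- read_otu_table(file.path(d, "otu_table.tsv"))
  md <- read_metadata(file.path(d, "metadata.tsv"))
  tree <- read_tree(file.path(d, "tree.nwk"))
  vd <- validate_dataset(filter_low_depth_samples(tab, "q1"), md, tree)
  md <- vd$metadata

  uf <- unweighted_unifrac(vd$table, vd$tree)
  part <- sorensen_partition(vd$table)
  write.table(as.matrix(uf), file.path("results/beta",
                                       paste0(name, "_unifrac.tsv")),
              sep = "\t", quote = FALSE, col.names = NA)

  elev_dm <- covariate_distance(md$elevation, md$sample_id, "elevation")
  geo_dm <- geodesic_matrix(md)
  mt <- mantel(uf, elev_dm, n_perm = 999, seed = seed)
  pm <- partial_mantel(uf, elev_dm, geo_dm, n_perm = 999, seed = seed + 1L)
  cg <- mantel_correlogram(uf, geo_dm, n_perm = 999, seed = seed + 2L)
  write.table(cg, file.path("results/beta", paste0(name, "_correlogram.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)

  zones <- assign_zones(md$elevation)
  an <- if (length(unique(zones)) >= 2)
    anosim(uf, zones, n_perm = 9999, seed = seed + 3L)

  message(sprintf(
    "%s: UniFrac %.2f +/- %.2f; turnover %.1f%%; Mantel(elev) r=%.2f p=%.3g; partial r=%.2f p=%.3g%s",
    name, mean(as.vector(uf)), sd(as.vector(uf)), part$turnover_percent,
    mt$statistic, mt$p, pm$statistic, pm$p,
    if (!is.null(an)) sprintf("; ANOSIM R=%.3f p=%.3g", an$statistic, an$p)
    else ""))
}
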