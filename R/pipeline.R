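# End-to-end orchestration: validate -> filter -> normalize -> alpha ->
# beta -> matrix tests -> null models -> classification -> indicators ->
# phylogenetic signal, with every stage seeded from one root seed and all
# settings recorded in the output bundle.

#' Pipeline configuration
#'
#' Either point at on-disk inputs (`table_path`, `metadata_path`,
#' `tree_path`) or request a synthetic dataset (`design` + `regime`); the
#' two modes are mutually exclusive. All thresholds carry the analysis
#' defaults: depth cutoff at the first quartile, CSS normalization,
#' beta-NTI threshold 2, RC threshold 0.95, zones split below 500 m and
#' above 1,000 m.
#'
#' @param table_path,metadata_path,tree_path input file paths (real-data
#'   mode).
#' @param design,regime synthetic mode (see [simulate_dataset()]).
#' @param synthetic_config generator settings for synthetic mode.
#' @param min_depth depth threshold (`"q1"` or integer).
#' @param norm_method `"css"` or `"tss"`.
#' @param n_perm_anosim,n_perm_mantel,n_null permutation/null counts.
#' @param bnti_threshold,rc_threshold classification thresholds.
#' @param zone_high,zone_low elevation zone boundaries, meters.
#' @param alpha significance level for indicator flags.
#' @param seed root seed; every stochastic stage derives its stream from
#'   it.
#' @param out_dir output directory.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(table_path = NULL, metadata_path = NULL,
                            tree_path = NULL, design = NULL, regime = NULL,
                            synthetic_config = elevassembly::synthetic_config(),
                            min_depth = "q1", norm_method = "css",
                            n_perm_anosim = 9999, n_perm_mantel = 999,
                            n_null = 999, bnti_threshold = 2,
                            rc_threshold = 0.95, zone_high = 1000,
                            zone_low = 500, alpha = 0.05, seed = 1,
                            out_dir = "pipeline_out") {
  real <- !is.null(table_path) || !is.null(metadata_path) || !is.null(tree_path)
  synth <- !is.null(design) || !is.null(regime)
  if (real && synth)
    stop("real-data paths and a synthetic regime are mutually exclusive")
  if (!real && !synth)
    stop("provide input paths or a synthetic design/regime")
  structure(as.list(environment()), class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes the ordered stage chain and writes TSV matrices and a JSON
#' summary (plus a plain-text log) under `config$out_dir`. Output JSON
#' contains the seed and every setting, and is byte-identical across
#' reruns with the same configuration.
#'
#' @param config a [pipeline_config()].
#' @return The summary list, invisibly; side effect: files under
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  logf <- function(...) cat(format(Sys.time(), "%Y-%m-%dT%H:%M:%S "),
                            sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  cat("", file = log_path)
  seed_for <- function(k) (config$seed * 97L + k) %% .Machine$integer.max
  summary <- list(package_version = as.character(utils::packageVersion("elevassembly")),
                  seed = config$seed,
                  settings = config[c("min_depth", "norm_method",
                                      "n_perm_anosim", "n_perm_mantel",
                                      "n_null", "bnti_threshold",
                                      "rc_threshold", "zone_high", "zone_low",
                                      "alpha")],
                  skipped = character(0))

  ## -- load / simulate ------------------------------------------------------
  ds <- stage("input", {
    if (!is.null(config$design)) {
      logf("simulating dataset: design=%s regime=%s", config$design,
           config$regime)
      simulate_dataset(config$design, config$regime,
                       config = config$synthetic_config,
                       seed = seed_for(1L))
    } else {
      logf("reading inputs")
      tab <- read_otu_table(config$table_path)
      meta <- read_metadata(config$metadata_path)
      tree <- if (!is.null(config$tree_path)) read_tree(config$tree_path)
      list(table = tab, metadata = meta, tree = tree)
    }
  })
  vd <- stage("validate", validate_dataset(ds$table, ds$metadata, ds$tree))
  summary$input <- list(n_samples = nrow(vd$table$counts),
                        n_otus = ncol(vd$table$counts),
                        synthetic = !is.null(config$design),
                        regime = if (!is.null(config$design)) config$regime)

  ## -- filter + normalize ---------------------------------------------------
  filt <- stage("filter", filter_low_depth_samples(vd$table, config$min_depth))
  vd <- stage("refilter-validate",
              validate_dataset(filt, vd$metadata, vd$tree))
  norm <- stage("normalize", normalize(vd$table, config$norm_method))
  summary$filter <- list(threshold = attr(filt, "depth_threshold"),
                         removed = attr(filt, "removed_samples"))
  write_otu_table(norm, file.path(config$out_dir, "normalized_table.tsv"))

  ## -- alpha ---------------------------------------------------------------
  rich <- stage("alpha", observed_richness(vd$table))
  write.table(data.frame(sample_id = names(rich), richness = rich),
              file.path(config$out_dir, "alpha_richness.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  summary$alpha <- list(mean_richness = mean(rich), sd_richness = sd(rich))

  ## -- beta ----------------------------------------------------------------
  meta <- vd$metadata
  bc <- stage("beta", bray_curtis(norm))
  part <- stage("beta", sorensen_partition(vd$table))
  uf <- if (!is.null(vd$tree))
    stage("beta", unweighted_unifrac(vd$table, vd$tree))
  write_dist <- function(d, name)
    write.table(as.matrix(d), file.path(config$out_dir, name), sep = "\t",
                quote = FALSE, col.names = NA)
  write_dist(bc, "bray_curtis.tsv")
  write_dist(part$beta_sor, "beta_sorensen.tsv")
  if (!is.null(uf)) write_dist(uf, "unifrac.tsv")
  summary$beta <- list(
    mean_unifrac = if (!is.null(uf)) mean(dist_vec(uf)),
    sd_unifrac = if (!is.null(uf)) sd(dist_vec(uf)),
    turnover_percent = part$turnover_percent,
    nestedness_percent = part$nestedness_percent)

  ## -- matrix tests --------------------------------------------------------
  zones <- setNames(as.character(assign_zones(meta$elevation,
                                              config$zone_high,
                                              config$zone_low)),
                    meta$sample_id)
  elev_dm <- covariate_distance(meta$elevation, meta$sample_id, "elevation")
  comm_dm <- if (!is.null(uf)) uf else bc
  summary$matrix_tests <- stage("matrix-tests", {
    res <- list()
    if (length(unique(zones)) >= 2) {
      an <- anosim(comm_dm, zones[meta$sample_id],
                   n_perm = config$n_perm_anosim, seed = seed_for(2L))
      res$anosim_zones <- list(R = an$statistic, p = an$p)
    }
    mt <- mantel(comm_dm, elev_dm, n_perm = config$n_perm_mantel,
                 seed = seed_for(3L))
    res$mantel_elevation <- list(r = mt$statistic, p = mt$p)
    if (all(c("latitude", "longitude") %in% names(meta)) &&
        all(is.finite(meta$latitude))) {
      geo_dm <- geodesic_matrix(meta)
      pm <- partial_mantel(comm_dm, elev_dm, geo_dm,
                           n_perm = config$n_perm_mantel, seed = seed_for(4L))
      res$partial_mantel_elevation_given_space <-
        list(r = pm$statistic, p = pm$p)
      cg <- mantel_correlogram(comm_dm, geo_dm, n_perm = config$n_perm_mantel,
                               seed = seed_for(5L))
      write.table(cg, file.path(config$out_dir, "mantel_correlogram.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    res
  })
  if (length(unique(zones)) < 2)
    summary$skipped <- c(summary$skipped, "anosim (single zone)")

  ## -- assembly null models -------------------------------------------------
  if (!is.null(vd$tree)) {
    bn <- stage("bnti", bnti(vd$table, vd$tree, n_null = config$n_null,
                             seed = seed_for(6L)))
    rc <- stage("raup-crick", raup_crick_bray(vd$table, n_null = config$n_null,
                                              seed = seed_for(7L)))
    cls <- stage("classify", classify_processes(bn, rc,
                                                config$bnti_threshold,
                                                config$rc_threshold))
    zs <- stage("zone-summary", zone_summary(cls, zones))
    write.table(cls, file.path(config$out_dir, "assembly_pairs.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(zs, file.path(config$out_dir, "assembly_zone_fractions.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    summary$assembly <- list(
      process_fractions = as.list(prop.table(table(cls$process))),
      n_pairs = nrow(cls), n_missing = attr(cls, "n_missing"))
  } else summary$skipped <- c(summary$skipped, "assembly (no tree)")

  ## -- indicators + phylogenetic signal ------------------------------------
  if (length(unique(zones)) >= 2) {
    iv <- stage("indval", indval(norm, zones[meta$sample_id],
                                 n_perm = config$n_perm_mantel,
                                 seed = seed_for(8L), alpha = config$alpha))
    write.table(iv, file.path(config$out_dir, "indicators.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    pe <- stage("preferred-elevation",
                suppressWarnings(preferred_elevation(vd$table, meta)))
    write.table(pe, file.path(config$out_dir, "preferred_elevation.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    summary$indicators <- list(
      n_significant = sum(iv$significant, na.rm = TRUE),
      by_zone = as.list(table(iv$group[iv$significant])))
    if (!is.null(vd$tree)) {
      sig <- iv[iv$significant & iv$group %in% c("High", "Low"), , drop = FALSE]
      summary$phylosignal <- stage("phylosignal", {
        ps <- list()
        for (z in c("High", "Low")) {
          ids <- sig$otu_id[sig$group == z]
          if (length(ids) >= 2) {
            bp <- bootstrap_pd_null(ids, otu_ids(vd$table), vd$tree,
                                    seed = seed_for(9L))
            ps[[paste0(tolower(z), "_indicator_pd")]] <-
              list(observed = bp$observed, ci = unname(bp$ci), p = bp$p)
          }
        }
        if (nrow(sig) >= 4 && length(unique(sig$group)) == 2) {
          labels <- setNames(tolower(sig$group), sig$otu_id)
          cd <- clade_divergence_test(vd$tree, labels, seed = seed_for(10L))
          ps$clade_comparisons <- cd$comparisons
          rt <- root_to_tip(vd$tree, sig$otu_id, labels)
          ps$root_to_tip <- list(summary = rt$summary,
                                 kruskal_p = rt$kruskal$p)
        }
        ps
      })
    }
  } else summary$skipped <- c(summary$skipped, "indicators (single zone)")

  logf("writing summary")
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(summary)
}
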