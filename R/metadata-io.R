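#' Read per-sample environmental metadata
#'
#' Reads a tab-separated metadata table with at least `sample_id` and
#' `elevation` columns; `pH`, `temperature`, `SOM`, `group`, `latitude` and
#' `longitude` are recognized when present. `"NA"` and empty cells become
#' missing values, never zeros.
#'
#' @param path file path to a TSV with a header row.
#' @return A `data.frame` with one row per sample.
#' @export
read_metadata <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE, na.strings = c("NA", ""))
  validate_metadata(df)
}

#' Validate a metadata data frame
#'
#' Enforces the metadata contract: unique sample ids, finite elevations,
#' pH inside (0, 14) where present, coordinates inside valid ranges.
#'
#' @param df data frame with at least `sample_id` and `elevation`.
#' @return The validated data frame (row names set to sample ids).
#' @export
validate_metadata <- function(df) {
  need <- c("sample_id", "elevation")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("metadata is missing required column(s): ", paste(miss, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  dup_check(df$sample_id, "sample")
  df$elevation <- as.numeric(df$elevation)
  if (any(is.na(df$elevation) | !is.finite(df$elevation)))
    stop("elevation must be finite for every sample")
  if ("pH" %in% names(df)) {
    ph <- as.numeric(df$pH)
    if (any(!is.na(ph) & (ph <= 0 | ph >= 14)))
      stop("pH values must lie in (0, 14)")
    df$pH <- ph
  }
  for (col in c("temperature", "SOM", "latitude", "longitude"))
    if (col %in% names(df)) df[[col]] <- as.numeric(df[[col]])
  if ("latitude" %in% names(df) &&
      any(abs(df$latitude) > 90, na.rm = TRUE))
    stop("latitude outside [-90, 90]")
  if ("longitude" %in% names(df) &&
      any(abs(df$longitude) > 180, na.rm = TRUE))
    stop("longitude outside [-180, 180]")
  rownames(df) <- df$sample_id
  df
}

#' Write sample metadata as TSV
#'
#' @param df metadata data frame.
#' @param path output file path.
#' @export
write_metadata <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Validate and align an OTU table, metadata and tree
#'
#' Checks the three inputs against each other: every table sample must have
#' a metadata record, and every table OTU must be a tree tip. The metadata
#' is reordered to the table's samples and the tree pruned to the table's
#' OTUs so all downstream axes agree.
#'
#' @param table an [otu_table()].
#' @param metadata metadata data frame (see [read_metadata()]).
#' @param tree rooted `phylo` tree, or `NULL` for tree-free analyses.
#' @param unmatched_otus `"error"` (default) to fail on table OTUs absent
#'   from the tree, `"prune"` to drop them from the table with a warning.
#' @return A list with elements `table`, `metadata`, `tree`, class
#'   `validated_dataset`.
#' @export
validate_dataset <- function(table, metadata, tree = NULL,
                             unmatched_otus = c("error", "prune")) {
  unmatched_otus <- match.arg(unmatched_otus)
  metadata <- validate_metadata(metadata)
  missing_meta <- setdiff(sample_ids(table), metadata$sample_id)
  if (length(missing_meta))
    stop("samples without metadata: ", paste(missing_meta, collapse = ", "))
  metadata <- metadata[match(sample_ids(table), metadata$sample_id), , drop = FALSE]
  if (!is.null(tree)) {
    lost <- setdiff(otu_ids(table), tree$tip.label)
    if (length(lost)) {
      if (unmatched_otus == "error")
        stop("OTUs absent from the tree: ", paste(lost, collapse = ", "))
      warning("dropping ", length(lost), " OTU(s) absent from the tree")
      keep <- setdiff(otu_ids(table), lost)
      table <- otu_table(table$counts[, keep, drop = FALSE],
                         normalized = table$normalized, method = table$method)
    }
    extra <- setdiff(tree$tip.label, otu_ids(table))
    if (length(extra)) tree <- ape::keep.tip(tree, otu_ids(table))
  }
  structure(list(table = table, metadata = metadata, tree = tree),
            class = "validated_dataset")
}
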