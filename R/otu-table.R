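#' Site-by-OTU abundance table
#'
#' Light container for a samples x OTUs abundance matrix. Raw tables hold
#' non-negative integer read counts; normalized tables (see [normalize()])
#' hold non-negative reals and carry the normalization method so that
#' count-only statistics (richness, rarefaction, Raup-Crick) can refuse them.
#'
#' @param counts numeric matrix, samples in rows, OTUs in columns, with
#'   unique row and column names.
#' @param normalized logical flag; `TRUE` only for tables produced by
#'   [normalize()].
#' @param method normalization method label (`"css"` or `"tss"`), `NULL` for
#'   raw counts.
#' @return An object of class `otu_table`.
#' @export
otu_table <- function(counts, normalized = FALSE, method = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) == 0L) stop("no samples in OTU table")
  if (ncol(counts) == 0L) stop("no OTUs in OTU table")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("OTU table must carry sample (row) and OTU (column) names")
  if (!is.numeric(counts) || any(!is.finite(counts)))
    stop("OTU table entries must be finite numbers")
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative abundance at sample '%s', OTU '%s'",
                 rownames(counts)[bad[1L]], colnames(counts)[bad[2L]]))
  }
  dup_check(rownames(counts), "sample")
  dup_check(colnames(counts), "OTU")
  structure(list(counts = counts, normalized = isTRUE(normalized),
                 method = method),
            class = "otu_table")
}

dup_check <- function(ids, what) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop(sprintf("duplicate %s id(s): %s", what, paste(dup, collapse = ", ")))
  invisible(ids)
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("otu_table: %d samples x %d OTUs (%s)\n",
              nrow(x$counts), ncol(x$counts),
              if (x$normalized) paste0("normalized, ", x$method) else "raw counts"))
  invisible(x)
}

#' @rdname otu_table
#' @param x an `otu_table`.
#' @export
sample_ids <- function(x) rownames(x$counts)

#' @rdname otu_table
#' @export
otu_ids <- function(x) colnames(x$counts)

#' @rdname otu_table
#' @export
library_sizes <- function(x) rowSums(x$counts)

#' Read a site-by-OTU table from a tab-separated file
#'
#' Expects a header row and ids in the first column. `orientation` declares
#' whether rows are samples (default) or OTUs; the returned table is always
#' samples x OTUs. Integer counts are preserved exactly.
#'
#' @param path file path.
#' @param orientation `"samples"` if rows are samples, `"otus"` if rows are
#'   OTUs (BIOM-style TSV export).
#' @return An [otu_table()].
#' @export
read_otu_table <- function(path, orientation = c("samples", "otus")) {
  orientation <- match.arg(orientation)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("no samples in OTU table")
  ids <- as.character(df[[1L]])
  m <- df[, -1L, drop = FALSE]
  for (j in seq_along(m)) {
    v <- suppressWarnings(as.numeric(m[[j]]))
    bad <- which(is.na(v) & !is.na(m[[j]]))
    if (length(bad))
      stop(sprintf("non-numeric abundance at row '%s', column '%s'",
                   ids[bad[1L]], names(m)[j]))
    m[[j]] <- v
  }
  m <- as.matrix(m)
  rownames(m) <- ids
  if (all(m == round(m))) storage.mode(m) <- "integer"
  if (orientation == "otus") m <- t(m)
  if (nrow(m) == 0L) stop("no samples in OTU table")
  otu_table(m)
}

#' Write a site-by-OTU table as TSV (samples in rows)
#'
#' @param x an [otu_table()].
#' @param path output file path.
#' @export
write_otu_table <- function(x, path) {
  df <- data.frame(sample_id = sample_ids(x), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
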