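#' Binding-site sets
#'
#' A `site_set` is a data frame of genomic intervals for one transcription
#' factor (TF), using 0-based half-open (BED) coordinates. Columns:
#' `chrom`, `start`, `end`, `name`, `strand` (`+`, `-` or `.`),
#' `signal_value` (ENCODE SignalValue, 0 if absent), `motif_pvalue`
#' (in (0,1], `NA` if absent) and `bound` (`TRUE` for ChIP-seq-identified
#' sites, `FALSE` for putative-only sites). Rows are sorted by
#' `(chrom, start)` and duplicates on `(chrom, start, end, strand)` are
#' invalid. Strand is retained for I/O only; no co-localization computation
#' uses it.
#'
#' @param sites data frame with at least `chrom`, `start`, `end`.
#' @param tf_id TF identifier.
#' @param cell_type optional cell-type label.
#' @return A `site_set` object (data frame subclass with `tf_id` and
#'   `cell_type` attributes).
#' @export
site_set <- function(sites, tf_id, cell_type = "") {
  stopifnot(is.data.frame(sites))
  n <- nrow(sites)
  df <- data.frame(
    chrom = as.character(sites$chrom %||% character(n)),
    start = as.integer(sites$start),
    end = as.integer(sites$end),
    name = as.character(sites$name %||% rep(".", n)),
    strand = as.character(sites$strand %||% rep(".", n)),
    signal_value = as.numeric(sites$signal_value %||% rep(0, n)),
    motif_pvalue = as.numeric(sites$motif_pvalue %||% rep(NA_real_, n)),
    bound = as.logical(sites$bound %||% rep(FALSE, n)),
    stringsAsFactors = FALSE
  )
  extra <- setdiff(names(sites), names(df))
  for (cl in extra) df[[cl]] <- sites[[cl]]
  if (n > 0) {
    if (any(df$start >= df$end))
      stopf("site_set '%s': %d interval(s) with end <= start", tf_id,
            sum(df$start >= df$end))
    if (any(df$signal_value < 0))
      stopf("site_set '%s': negative signal_value", tf_id)
    bad_p <- !is.na(df$motif_pvalue) &
      (df$motif_pvalue <= 0 | df$motif_pvalue > 1)
    if (any(bad_p)) stopf("site_set '%s': motif_pvalue outside (0, 1]", tf_id)
    df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
    rownames(df) <- NULL
    key <- paste(df$chrom, df$start, df$end, df$strand)
    if (anyDuplicated(key))
      stopf("site_set '%s': duplicate (chrom, start, end, strand) entries",
            tf_id)
  }
  structure(df, tf_id = as.character(tf_id),
            cell_type = as.character(cell_type),
            class = c("site_set", "data.frame"))
}

#' @export
print.site_set <- function(x, ...) {
  cat(sprintf("site_set '%s' (%s): %d sites, %d bound\n",
              attr(x, "tf_id"), attr(x, "cell_type"), nrow(x),
              sum(x$bound)))
  if (nrow(x) > 0) print.data.frame(utils::head(as.data.frame(x), 6))
  invisible(x)
}

#' TF identifier of a site set
#' @param x a [site_set()].
#' @return Character scalar.
#' @export
tf_id <- function(x) attr(x, "tf_id")

# Unique row key used when bound sites must be matched to putative sites.
site_key <- function(x) paste(x$chrom, x$start, x$end, x$strand, sep = ":")
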