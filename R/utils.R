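# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Center of a genomic interval
#'
#' Midpoint of a 0-based half-open interval, `floor((start + end) / 2)`;
#' peak summit offsets are never used.
#'
#' @param start,end interval bounds in bp.
#' @return Integer position.
#' @export
site_center <- function(start, end) floor((start + end) / 2)

# Hazen fractional rank in (0, 1); average ranks for ties.
fractional_rank <- function(x) {
  (rank(x, ties.method = "average") - 0.5) / length(x)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# GRanges from chrom/start/end columns (0-based half-open -> 1-based closed).
as_granges0 <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

# GRanges of single-bp points at site centers.
centers_granges <- function(df) {
  ctr <- site_center(df$start, df$end)
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = ctr + 1L, width = 1L)
  )
}

# TRUE for each row of `df` whose center lies inside some interval of `ivs`
# (both 0-based half-open data frames with chrom/start/end).
center_in_intervals <- function(df, ivs) {
  if (nrow(df) == 0) return(logical(0))
  if (is.null(ivs) || nrow(ivs) == 0) return(rep(FALSE, nrow(df)))
  IRanges::overlapsAny(centers_granges(df), as_granges0(ivs))
}
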