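#' Per-chromosome binned Hi-C contact map
#'
#' Holds symmetric dense matrices of normalized and raw contact counts at a
#' fixed bin size, a per-bin total of raw reads, and a logical coverage mask
#' (`TRUE` = bin retained). Bin indices are 0-based in the public API.
#'
#' @param chrom chromosome name.
#' @param bin_size bin size in bp.
#' @param bin_i,bin_j 0-based bin indices of sparse entries.
#' @param normalized normalized contact scores for the entries.
#' @param raw raw read counts for the entries (default: rounded normalized).
#' @param n_bins number of bins (default: `max(bin_i, bin_j) + 1`).
#' @return A `contact_map` object.
#' @export
contact_map <- function(chrom, bin_size, bin_i, bin_j, normalized,
                        raw = NULL, n_bins = NULL) {
  stopifnot(length(bin_i) == length(bin_j),
            length(bin_i) == length(normalized))
  raw <- raw %||% round(normalized)
  if (any(normalized < 0) || any(raw < 0))
    stopf("contact_map: negative contact counts")
  n_bins <- as.integer(n_bins %||% (max(bin_i, bin_j, 0L) + 1L))
  if (length(bin_i) > 0 && max(bin_i, bin_j) >= n_bins)
    stopf("contact_map: bin index beyond n_bins")
  norm <- matrix(0, n_bins, n_bins)
  rawm <- matrix(0, n_bins, n_bins)
  ii <- cbind(bin_i + 1L, bin_j + 1L)
  norm[ii] <- normalized
  rawm[ii] <- raw
  norm[ii[, 2:1, drop = FALSE]] <- normalized
  rawm[ii[, 2:1, drop = FALSE]] <- raw
  structure(
    list(chrom = chrom, bin_size = bin_size, n_bins = n_bins,
         norm = norm, raw = rawm, bin_raw_total = rowSums(rawm),
         mask = rep(TRUE, n_bins)),
    class = "contact_map"
  )
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf(
    "contact_map %s: %d bins x %d bp, %d masked, %.0f raw reads\n",
    x$chrom, x$n_bins, x$bin_size, sum(!x$mask), sum(x$bin_raw_total) / 2))
  invisible(x)
}

#' Symmetric lookup of contact values
#'
#' @param map a [contact_map()].
#' @param bin_i,bin_j 0-based bin indices (vectorized).
#' @param what `"normalized"` or `"raw"`.
#' @return Numeric vector of contact values; order of `bin_i`/`bin_j` is
#'   irrelevant.
#' @export
contact_lookup <- function(map, bin_i, bin_j,
                           what = c("normalized", "raw")) {
  what <- match.arg(what)
  m <- if (what == "normalized") map$norm else map$raw
  m[cbind(bin_i + 1L, bin_j + 1L)]
}

#' Mask low-coverage bins
#'
#' Bins whose total associated raw reads fall strictly below
#' `fraction` times the per-chromosome median (median taken over bins with
#' nonzero raw totals) are masked and excluded from the expected profile and
#' from all downstream sums.
#'
#' @param map a [contact_map()].
#' @param fraction coverage fraction (default 1/3 of the median).
#' @return The map with an updated `mask`.
#' @export
filter_low_coverage <- function(map, fraction = 1 / 3) {
  tot <- map$bin_raw_total
  nz <- tot[tot > 0]
  if (length(nz) == 0) stopf("filter_low_coverage: map has no raw reads")
  med <- stats::median(nz)
  map$mask <- tot >= fraction * med
  if (!any(map$mask))
    stopf("filter_low_coverage: all bins masked on %s", map$chrom)
  map
}

#' Expected contact score by sequence separation
#'
#' For each separation `s` (in bins) the expected value is the empirical
#' mean of normalized contact scores over all unmasked bin pairs at that
#' separation on the chromosome, counting zeros for unmasked pairs with no
#' recorded contact. Values are computed for every separation with at least
#' one valid pair, including the near-diagonal band that downstream scoring
#' never consumes.
#'
#' @param map a [contact_map()], typically after [filter_low_coverage()].
#' @return An `expected_profile` object with `values[s + 1]` holding the
#'   mean at separation `s` bins (`NA` where no valid pair exists).
#' @export
expected_profile <- function(map) {
  n <- map$n_bins
  ok <- map$mask
  vals <- rep(NA_real_, n)
  npairs <- integer(n)
  for (s in 0:(n - 1)) {
    i <- seq_len(n - s)
    keep <- ok[i] & ok[i + s]
    npairs[s + 1] <- sum(keep)
    if (npairs[s + 1] > 0)
      vals[s + 1] <- sum(map$norm[cbind(i[keep], i[keep] + s)]) /
        npairs[s + 1]
  }
  structure(list(chrom = map$chrom, bin_size = map$bin_size,
                 values = vals, n_pairs = npairs),
            class = "expected_profile")
}

#' Scoring configuration for contact co-localization
#'
#' Bundles the thresholds of the contact-scoring stage: the near-diagonal
#' exclusion (pairs separated by no more than `min_separation` are never
#' consumed), the low-coverage mask fraction, the minimum raw read count a
#' pair must exceed, and the adaptive bin-merging rules (base 5-kb bins,
#' merged to 25 kb for loci more than 100 kb apart and to 55 kb beyond
#' 1 Mb). All "more/less than" thresholds are strict.
#'
#' @param min_separation bp; pairs with bin separation `<=` this are skipped
#'   (default 25 kb, i.e. five 5-kb bins either side of the diagonal).
#' @param low_coverage_fraction fraction of the median for the coverage mask.
#' @param min_pair_raw_reads a merged pair needs strictly more raw reads.
#' @param merge_rules data frame `sep_gt` (bp, strict lower bound) and
#'   `bin_size` (bp); must be sorted with bin sizes odd multiples of the
#'   base bin so merged windows can be centered.
#' @param raw_filter_scope whether the raw-read threshold applies to the
#'   merged window sum (default) or to the base bin pair.
#' @return A `ccl_config` list.
#' @export
ccl_config <- function(min_separation = 25000,
                       low_coverage_fraction = 1 / 3,
                       min_pair_raw_reads = 20,
                       merge_rules = data.frame(
                         sep_gt = c(0, 1e5, 1e6),
                         bin_size = c(5000, 25000, 55000)),
                       raw_filter_scope = c("merged", "base")) {
  stopifnot(!is.unsorted(merge_rules$sep_gt),
            all(merge_rules$bin_size %% merge_rules$bin_size[1] == 0))
  structure(list(min_separation = min_separation,
                 low_coverage_fraction = low_coverage_fraction,
                 min_pair_raw_reads = min_pair_raw_reads,
                 merge_rules = merge_rules,
                 raw_filter_scope = match.arg(raw_filter_scope)),
            class = "ccl_config")
}

# Half-width (in base bins) of the merged window for a separation in bp.
merge_half_width <- function(sep_bp, config, base_bin) {
  rules <- config$merge_rules
  idx <- findInterval(sep_bp, rules$sep_gt, left.open = TRUE)
  idx[idx < 1] <- 1L
  (rules$bin_size[idx] %/% base_bin - 1L) %/% 2L
}

#' Observed/expected/raw contact at merged resolution for one locus pair
#'
#' Selects the merged bin size from the locus separation, centers a merged
#' window on each locus's base bin, and sums base-bin normalized counts,
#' raw counts and expected-profile values over the window (so the
#' observed/expected ratio is scale-consistent across merge levels).
#' Windows running off the chromosome or containing any masked base bin
#' invalidate the pair.
#'
#' @param map a [contact_map()].
#' @param profile matching [expected_profile()].
#' @param locus_i,locus_j loci in bp on the chromosome.
#' @param config a [ccl_config()].
#' @return List with `obs`, `exp`, `raw` and logical `valid`; invalid pairs
#'   carry `NA` values.
#' @export
effective_bin <- function(map, profile, locus_i, locus_j, config = ccl_config()) {
  bs <- map$bin_size
  bi <- locus_i %/% bs
  bj <- locus_j %/% bs
  sep_bins <- abs(bi - bj)
  if (sep_bins * bs <= config$min_separation)
    stopf("effective_bin: pair separation %d bp within the excluded band",
          sep_bins * bs)
  h <- merge_half_width(sep_bins * bs, config, bs)
  wi <- (bi - h):(bi + h)
  wj <- (bj - h):(bj + h)
  invalid <- list(obs = NA_real_, exp = NA_real_, raw = NA_real_,
                  valid = FALSE)
  if (min(wi, wj) < 0 || max(wi, wj) >= map$n_bins) return(invalid)
  if (!all(map$mask[c(wi, wj) + 1L])) return(invalid)
  obs <- sum(map$norm[wi + 1L, wj + 1L, drop = FALSE])
  raw <- sum(map$raw[wi + 1L, wj + 1L, drop = FALSE])
  seps <- abs(outer(wi, wj, "-"))
  expv <- profile$values[seps + 1L]
  if (anyNA(expv)) return(invalid)
  list(obs = obs, exp = sum(expv), raw = raw, valid = TRUE)
}

# Pairwise log(Obs/Exp) scores among a set of loci on one chromosome.
#
# Returns a symmetric P x P matrix S with S[p, q] = ln(obs/exp) for the
# merged-window contact between loci p and q, and NA where the pair is not
# consumed (same base bin, separation within the excluded band, window off
# the chromosome or touching a masked bin, raw reads not above the
# threshold, exp == 0, or obs == 0). Attributes count the skip reasons.
# This is the single scoring kernel behind all CCL variants; permutation
# nulls reuse it because label permutations only reassign loci.
pair_score_matrix <- function(map, profile, loci, config = ccl_config()) {
  bs <- map$bin_size
  n <- map$n_bins
  bins <- as.integer(loci %/% bs)
  if (any(bins < 0 | bins >= n))
    stopf("pair_score_matrix: locus outside the chromosome")
  P <- length(bins)
  S <- matrix(NA_real_, P, P)
  if (P < 2) return(S)

  # direct window sums, vectorized over pairs per offset: exact (no
  # large-cumsum cancellation) and fast for the window sizes in play
  window_sum <- function(m, ci, cj, h) {
    tot <- numeric(length(ci))
    for (a in -h:h) for (b in -h:h)
      tot <- tot + m[cbind(ci + a + 1L, cj + b + 1L)]
    tot
  }
  bad <- cumsum(!map$mask)  # prefix count of masked bins
  window_bad <- function(a, b) (bad[b + 1L] - ifelse(a >= 1, bad[a], 0)) > 0

  ut <- which(upper.tri(S), arr.ind = TRUE)
  p <- ut[, 1]; q <- ut[, 2]
  bi <- bins[p]; bj <- bins[q]
  s_bins <- abs(bi - bj)
  ok <- s_bins > 0 & (s_bins * bs) > config$min_separation
  h <- merge_half_width(s_bins * bs, config, bs)
  lo_i <- bi - h; hi_i <- bi + h
  lo_j <- bj - h; hi_j <- bj + h
  ok <- ok & lo_i >= 0 & lo_j >= 0 & hi_i < n & hi_j < n
  idx <- which(ok)
  skip <- c(band_or_edge = sum(!ok), masked = 0L, low_raw = 0L,
            zero_exp = 0L, zero_obs = 0L)
  if (length(idx) > 0) {
    msk <- window_bad(lo_i[idx], hi_i[idx]) | window_bad(lo_j[idx], hi_j[idx])
    skip["masked"] <- sum(msk)
    ok[idx][msk] <- FALSE
    idx <- idx[!msk]
  }
  if (length(idx) > 0) {
    obs <- numeric(length(idx))
    raw <- numeric(length(idx))
    ev <- numeric(length(idx))
    for (hh in unique(h[idx])) {
      at <- which(h[idx] == hh)
      sel <- idx[at]
      obs[at] <- window_sum(map$norm, bi[sel], bj[sel], hh)
      raw[at] <- window_sum(map$raw, bi[sel], bj[sel], hh)
      # expected sum over the window: counts of each separation offset
      d <- (-2 * hh):(2 * hh)
      w <- 2 * hh + 1 - abs(d)
      pm <- outer(abs(bi[sel] - bj[sel]), d, "+")  # separations >= 1
      vals <- matrix(profile$values[pm + 1L], nrow = nrow(pm))
      ev[at] <- as.numeric(vals %*% w)
      ev[at][rowSums(is.na(vals)) > 0] <- NA_real_
    }
    if (config$raw_filter_scope == "base")
      raw <- map$raw[cbind(bi[idx] + 1L, bj[idx] + 1L)]
    low <- !(raw > config$min_pair_raw_reads)
    skip["low_raw"] <- sum(low)
    zexp <- !low & (is.na(ev) | ev <= 0)
    skip["zero_exp"] <- sum(zexp)
    zobs <- !low & !zexp & obs <= 0
    skip["zero_obs"] <- sum(zobs)
    good <- !(low | zexp | zobs)
    S[cbind(p[idx][good], q[idx][good])] <- log(obs[good] / ev[good])
  }
  S[lower.tri(S)] <- t(S)[lower.tri(S)]
  attr(S, "skipped") <- skip
  attr(S, "bins") <- bins
  S
}
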