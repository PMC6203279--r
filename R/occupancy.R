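# Occupancy, resampling errors, group-contrast statistics and
# sequence-matched SignalValue comparisons.

#' Binding-site occupancy per group, with resampling errors
#'
#' Occupancy is the ratio of ChIP-seq-identified sites to total putative
#' sites in each group. Error bars are the standard deviation over
#' resamples, each omitting a uniformly random third of the putative
#' sites.
#'
#' @param putative [site_set()] of putative sites.
#' @param bound [site_set()] of bound sites; every bound site must match
#'   a putative site by (chrom, start, end, strand) key.
#' @param grouping group index per putative site (any vector).
#' @param n_resample resampling iterations (default 1000).
#' @param drop_frac fraction omitted per resample (default 1/3).
#' @param seed RNG seed.
#' @return An `occupancy_table` data frame: `group`, `n_putative`,
#'   `n_bound`, `occupancy` (NA for empty groups), `sd_resample`.
#' @export
occupancy <- function(putative, bound, grouping, n_resample = 1000,
                      drop_frac = 1 / 3, seed = 1) {
  pdf <- as.data.frame(putative)
  stopifnot(length(grouping) == nrow(pdf))
  is_bound <- site_key(pdf) %in% site_key(as.data.frame(bound))
  if (sum(is_bound) < nrow(as.data.frame(bound)))
    stopf("occupancy: bound sites not contained in the putative set")
  groups <- sort(unique(grouping))
  occ_of <- function(keep) {
    vapply(groups, function(g) {
      sel <- keep & grouping == g
      if (!any(sel)) return(NA_real_)
      mean(is_bound[sel])
    }, numeric(1))
  }
  full <- occ_of(rep(TRUE, nrow(pdf)))
  n_drop <- floor(drop_frac * nrow(pdf))
  res <- with_seed(seed, {
    vapply(seq_len(n_resample), function(i) {
      keep <- rep(TRUE, nrow(pdf))
      keep[sample.int(nrow(pdf), n_drop)] <- FALSE
      occ_of(keep)
    }, numeric(length(groups)))
  })
  res <- matrix(res, nrow = length(groups))
  out <- data.frame(
    group = groups,
    n_putative = vapply(groups, function(g) sum(grouping == g), numeric(1)),
    n_bound = vapply(groups, function(g) sum(is_bound & grouping == g),
                     numeric(1)),
    occupancy = full,
    sd_resample = apply(res, 1, stats::sd, na.rm = TRUE)
  )
  class(out) <- c("occupancy_table", "data.frame")
  out
}

#' Percentage change across an axis range
#'
#' `delta = 100 * (end - start) / start`.
#'
#' @param start,end endpoint values; `start` must be nonzero.
#' @return Percentage change.
#' @export
pct_change <- function(start, end) {
  if (any(start == 0)) stopf("pct_change: start value is zero")
  100 * (end - start) / start
}

# G-test of independence on a 2x2 table with Williams' continuity
# correction: G / q with q = 1 + (N/r1 + N/r2 - 1)(N/c1 + N/c2 - 1) /
# (6 N df), df = 1.
gtest_williams <- function(tab) {
  stopifnot(all(dim(tab) == c(2, 2)))
  n <- sum(tab)
  e <- outer(rowSums(tab), colSums(tab)) / n
  nz <- tab > 0
  g <- 2 * sum(tab[nz] * log(tab[nz] / e[nz]))
  q <- 1 + (sum(n / rowSums(tab)) - 1) * (sum(n / colSums(tab)) - 1) /
    (6 * n)
  stat <- g / q
  list(statistic = stat, p.value = stats::pchisq(stat, df = 1,
                                                 lower.tail = FALSE))
}

#' Occupancy contrast between top and bottom score terciles
#'
#' Splits sites into terciles of their co-localization score, forms the
#' 2x2 table of bound/unbound in the top versus bottom tercile, and tests
#' it with a G-test with Williams' correction or a chi-square test with
#' Yates' continuity correction. TFs without strictly more than
#' `min_per_group` sites in every tercile are skipped (returned as `NA`).
#'
#' @param scores per-site scores (numeric or `site_scores` frame).
#' @param bound logical per-site bound flags.
#' @param test `"gtest_williams"` or `"chisq_yates"`.
#' @param min_per_group minimum sites per tercile (default 300; 0
#'   disables).
#' @return List with `fractional_increase`
#'   (`(occ_top - occ_bottom) / occ_bottom`), `statistic`, `p`, `table`
#'   and logical `skipped`.
#' @export
tercile_contrast <- function(scores, bound,
                             test = c("gtest_williams", "chisq_yates"),
                             min_per_group = 300) {
  test <- match.arg(test)
  x <- if (is.data.frame(scores)) scores$ccl else scores
  stopifnot(length(x) == length(bound))
  g <- rank_normalize(x, 3)$group
  if (min_per_group > 0 && any(table(factor(g, 0:2)) <= min_per_group))
    return(list(fractional_increase = NA_real_, statistic = NA_real_,
                p = NA_real_, table = NULL, skipped = TRUE))
  top <- g == 2; bot <- g == 0
  tab <- rbind(top = c(bound = sum(bound[top]), unbound = sum(!bound[top])),
               bottom = c(sum(bound[bot]), sum(!bound[bot])))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warnf("tercile_contrast: degenerate 2x2 margin; p = 1")
    return(list(fractional_increase = NA_real_, statistic = 0, p = 1,
                table = tab, skipped = FALSE))
  }
  res <- if (test == "gtest_williams") {
    gtest_williams(tab)
  } else {
    ct <- stats::chisq.test(tab, correct = TRUE)
    list(statistic = unname(ct$statistic), p.value = ct$p.value)
  }
  occ_top <- mean(bound[top]); occ_bot <- mean(bound[bot])
  list(fractional_increase = if (occ_bot > 0) (occ_top - occ_bot) / occ_bot
       else NA_real_,
       statistic = res$statistic, p = res$p.value, table = tab,
       skipped = FALSE)
}

#' Sequence-matched SignalValue comparison between site groups
#'
#' Pairs sites across the two groups that share an identical sequence key
#' and identical values on every matching criterion (histone marks,
#' methylation, sub-compartment, ... supplied as columns); all possible
#' cross-group pairings are retained. SignalValues are rank-normalized to
#' fractional values per TF before differencing; the paired differences
#' are tested with a Wilcoxon signed-rank test, and a control
#' distribution is built by randomly re-pairing sites within the matched
#' sets.
#'
#' @param sites data frame with `tf`, `signal_value`, `seq_key`, a
#'   `group` column with two levels (first = "high"), and any further
#'   criterion columns named in `criteria`.
#' @param criteria character vector of column names that must match
#'   within a pair.
#' @param n_control control re-pairings (default 100).
#' @param seed RNG seed.
#' @return List with `pairs` (data frame of matched pairs and
#'   `delta_signal`), `p` (signed-rank), `control_deltas` (vector of
#'   control means) and `n_pairs`.
#' @export
match_signal_pairs <- function(sites, criteria = character(),
                               n_control = 100, seed = 1) {
  stopifnot(all(c("tf", "signal_value", "seq_key", "group") %in%
                  names(sites)))
  lev <- unique(sites$group)
  stopifnot(length(lev) == 2)
  sites$.frac <- stats::ave(sites$signal_value, sites$tf,
                            FUN = fractional_rank)
  keycols <- c("seq_key", criteria)
  key <- do.call(paste, c(sites[keycols], sep = "\r"))
  hi <- which(sites$group == lev[1])
  lo <- which(sites$group == lev[2])
  pairs <- merge(data.frame(key = key[hi], hi = hi),
                 data.frame(key = key[lo], lo = lo), by = "key")
  if (nrow(pairs) == 0)
    return(list(pairs = NULL, p = NA_real_, control_deltas = numeric(0),
                n_pairs = 0L))
  pairs$delta_signal <- sites$.frac[pairs$hi] - sites$.frac[pairs$lo]
  p <- if (all(pairs$delta_signal == 0)) 1 else
    suppressWarnings(stats::wilcox.test(pairs$delta_signal)$p.value)
  # control: group membership is destroyed by pooling both members of
  # every pair and re-pairing at random, so the control deltas center on
  # zero whatever the true shift
  pool <- c(sites$.frac[pairs$hi], sites$.frac[pairs$lo])
  np <- nrow(pairs)
  ctrl <- with_seed(seed, vapply(seq_len(n_control), function(i) {
    mix <- sample(pool)
    mean(mix[seq_len(np)] - mix[np + seq_len(np)])
  }, numeric(1)))
  list(pairs = pairs, p = p, control_deltas = ctrl,
       n_pairs = nrow(pairs))
}

#' Two-sided Wilcoxon rank-sum comparison
#'
#' @param values_a,values_b nonempty numeric vectors.
#' @return Two-sided p-value (1 when every value is tied).
#' @export
rank_sum_compare <- function(values_a, values_b) {
  stopifnot(length(values_a) > 0, length(values_b) > 0)
  if (length(unique(c(values_a, values_b))) == 1) return(1)
  suppressWarnings(stats::wilcox.test(values_a, values_b)$p.value)
}

#' Signed separation of sites from their nearest anchors
#'
#' For each site, the signed distance `site_center - anchor_position` to
#' the nearest anchor (TSS, CTCF site, ...), nearest by absolute
#' distance with ties resolved to the left anchor. Sites on chromosomes
#' without anchors are skipped with a warning. Also returns the
#' cumulative distribution of absolute separations and the mean absolute
#' deviation of the signed separations.
#'
#' @param sites a [site_set()] or site data frame.
#' @param anchors data frame with `chrom`, `pos`.
#' @return List with `distances` (per retained site), `cumulative` (data
#'   frame `abs_dist`, `fraction`) and `mad` (mean absolute deviation of
#'   signed distances).
#' @export
separation_profile <- function(sites, anchors) {
  stopifnot(nrow(anchors) > 0)
  df <- as.data.frame(sites)
  ctr <- site_center(df$start, df$end)
  d <- rep(NA_real_, nrow(df))
  for (cc in unique(df$chrom)) {
    ap <- sort(anchors$pos[anchors$chrom == cc])
    sel <- which(df$chrom == cc)
    if (length(ap) == 0) {
      warnf("separation_profile: no anchors on %s; %d site(s) skipped",
            cc, length(sel))
      next
    }
    k <- findInterval(ctr[sel], ap)
    left <- ap[pmax(k, 1)]
    right <- ap[pmin(k + 1, length(ap))]
    dl <- ctr[sel] - left
    dr <- ctr[sel] - right
    use_left <- k >= 1 & (k >= length(ap) | abs(dl) <= abs(dr))
    d[sel] <- ifelse(use_left, dl, dr)
  }
  d <- d[!is.na(d)]
  ad <- sort(abs(d))
  list(distances = d,
       cumulative = data.frame(abs_dist = ad,
                               fraction = seq_along(ad) / length(ad)),
       mad = mean(abs(d - mean(d))))
}
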