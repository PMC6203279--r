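# CCL scores: per-site sums of log observed/expected Hi-C contact
# enrichment against a partner site set (homotypic, heterotypic,
# integrated).

# Shared driver: score each query site against partner sites on the same
# chromosome. Query and partner loci are site centers; pairs falling in the
# same base bin are never consumed (this also removes self-pairs when a
# query site is itself a partner site).
score_against_partners <- function(query, partners, map, profile, config,
                                   tf, partner_id) {
  stopifnot(inherits(map, "contact_map"))
  q <- query[query$chrom == map$chrom, , drop = FALSE]
  p <- partners[partners$chrom == map$chrom, , drop = FALSE]
  out <- data.frame(chrom = q$chrom, start = q$start, end = q$end,
                    tf = tf, partner = partner_id,
                    ccl = 0, n_pairs = 0L, stringsAsFactors = FALSE)
  if (nrow(q) == 0 || nrow(p) == 0) return(out)
  loci <- c(site_center(q$start, q$end), site_center(p$start, p$end))
  S <- pair_score_matrix(map, profile, loci, config)
  qi <- seq_len(nrow(q))
  pi <- nrow(q) + seq_len(nrow(p))
  sub <- S[qi, pi, drop = FALSE]
  out$ccl <- rowSums(sub, na.rm = TRUE)
  out$n_pairs <- rowSums(!is.na(sub))
  attr(out, "skipped") <- attr(S, "skipped")
  out
}

#' Homotypic chromatin co-localization scores (CCL)
#'
#' For each query site i of a TF, the CCL score is the sum over
#' ChIP-seq-identified sites j of the same TF on the same chromosome of
#' the natural log of the merged-window observed/expected Hi-C contact
#' ratio. Pairs separated by no more than 25 kb, pairs in the same base
#' bin, pairs without strictly more than 20 raw reads, and pairs with
#' invalid merged windows are skipped; the number of consumed pairs per
#' site is recorded.
#'
#' @param putative query [site_set()] (putative sites; includes the bound
#'   subset). With `query = "bound"` only ChIP-seq-identified sites are
#'   scored.
#' @param bound partner [site_set()] of ChIP-seq-identified sites.
#' @param map a filtered [contact_map()].
#' @param profile the matching [expected_profile()].
#' @param config a [ccl_config()].
#' @param query which loci to score.
#' @return A `site_scores` data frame: `chrom, start, end, tf, partner,
#'   ccl, n_pairs`.
#' @export
ccl_homotypic <- function(putative, bound, map, profile,
                          config = ccl_config(),
                          query = c("putative", "bound")) {
  query <- match.arg(query)
  q <- if (query == "bound") bound else putative
  res <- score_against_partners(q, bound, map, profile, config,
                                tf = tf_id(putative) %||% tf_id(bound),
                                partner_id = tf_id(bound))
  class(res) <- c("site_scores", "data.frame")
  res
}

#' Heterotypic chromatin co-localization scores
#'
#' Scores each site i of TF A against the ChIP-seq-identified sites of TF
#' B on the same chromosome, with the same filters as [ccl_homotypic()].
#' The score is not symmetric: the A-to-B and B-to-A directions are
#' produced by two calls with the roles swapped.
#'
#' @param sites_a query [site_set()] for TF A.
#' @param bound_b partner [site_set()] of ChIP-seq-identified B sites.
#' @inheritParams ccl_homotypic
#' @return A `site_scores` data frame (one row per A site).
#' @export
ccl_heterotypic <- function(sites_a, bound_b, map, profile,
                            config = ccl_config()) {
  res <- score_against_partners(sites_a, bound_b, map, profile, config,
                                tf = tf_id(sites_a),
                                partner_id = tf_id(bound_b))
  class(res) <- c("site_scores", "data.frame")
  res
}

#' Integrated heterotypic co-localization scores
#'
#' Assuming additive effects of different TFs, the integrated score of a
#' site of TF A against a TF group G is the sum of its heterotypic scores
#' against each member of G.
#'
#' @param sites_a query [site_set()] for TF A.
#' @param bound_sets list of partner [site_set()]s (the group G; normally
#'   excludes TF A).
#' @inheritParams ccl_homotypic
#' @return A `site_scores` data frame with `partner` naming the group.
#' @export
ccl_integrated <- function(sites_a, bound_sets, map, profile,
                           config = ccl_config()) {
  if (length(bound_sets) == 0)
    stopf("ccl_integrated: empty partner group")
  parts <- lapply(bound_sets, function(b)
    ccl_heterotypic(sites_a, b, map, profile, config))
  res <- parts[[1]]
  for (k in seq_along(parts)[-1]) {
    res$ccl <- res$ccl + parts[[k]]$ccl
    res$n_pairs <- res$n_pairs + parts[[k]]$n_pairs
  }
  res$partner <- paste(vapply(bound_sets, tf_id, ""), collapse = "+")
  res
}

#' Fractional-rank normalization and quantile grouping of scores
#'
#' Replaces each score by its fractional rank in (0, 1) (average rank for
#' ties, Hazen position) and assigns quantile groups
#' `floor(rank * n_groups)` clipped to `n_groups - 1`, e.g. deciles with
#' `n_groups = 10` or terciles with `n_groups = 3`.
#'
#' @param scores numeric vector or a `site_scores` data frame.
#' @param n_groups number of quantile groups (>= 2).
#' @return Data frame with `rank` and 0-based `group` columns (appended to
#'   the input when it is a `site_scores` frame).
#' @export
rank_normalize <- function(scores, n_groups = 10) {
  stopifnot(n_groups >= 2)
  x <- if (is.data.frame(scores)) scores$ccl else scores
  if (length(x) < n_groups)
    stopf("rank_normalize: %d scores for %d groups", length(x), n_groups)
  r <- fractional_rank(x)
  g <- pmin(as.integer(floor(r * n_groups)), n_groups - 1L)
  if (is.data.frame(scores)) {
    scores$rank <- r
    scores$group <- g
    scores
  } else {
    data.frame(rank = r, group = g)
  }
}
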