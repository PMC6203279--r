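# Permutation nulls over binding-site labels, significant-pair calling,
# signed-KL contact enrichment (CE) and TF sub-network clustering.

# Per-site stratum labels: chromosome, or sub-compartment x chromosome
# when an annotation is supplied (label looked up at the site center).
site_strata <- function(df, annotation = NULL) {
  if (is.null(annotation)) return(df$chrom)
  lab <- rep(NA_character_, nrow(df))
  ctr <- site_center(df$start, df$end)
  for (cc in unique(df$chrom)) {
    ivs <- annotation[annotation$chrom == cc, , drop = FALSE]
    sel <- which(df$chrom == cc)
    if (nrow(ivs) == 0 || length(sel) == 0) next
    ivs <- ivs[order(ivs$start), , drop = FALSE]
    k <- findInterval(ctr[sel], ivs$start)
    ok <- k >= 1 & ctr[sel] < ivs$end[pmax(k, 1)]
    lab[sel][ok] <- ivs$label[k[ok]]
  }
  paste(df$chrom, lab, sep = "|")
}

#' Permute binding-site labels within strata
#'
#' Within each stratum (chromosome, or sub-compartment x chromosome when
#' `strata` is given) the pooled site positions of all TFs except
#' `fixed_tf` are randomly reassigned to TF labels, preserving each TF's
#' per-stratum site count; `fixed_tf` sites are untouched. Single-site
#' strata are left unpermuted. Deterministic given `seed`.
#'
#' @param site_sets named list of [site_set()]s.
#' @param fixed_tf TF whose sites stay fixed (`NULL` for none).
#' @param strata optional interval annotation with a `label` column
#'   (e.g. sub-compartments).
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return List of `n_perm` permutations, each a named list of
#'   [site_set()]s.
#' @export
permute_sites <- function(site_sets, fixed_tf = NULL, strata = NULL,
                          n_perm = 1, seed = 1) {
  stopifnot(n_perm >= 1)
  pool <- do.call(rbind, lapply(names(site_sets), function(tf) {
    df <- as.data.frame(site_sets[[tf]])
    df$.tf <- tf
    df
  }))
  moving <- pool$.tf != (fixed_tf %||% "")
  stratum <- site_strata(pool, strata)
  groups <- split(which(moving), stratum[moving])
  with_seed(seed, {
    lapply(seq_len(n_perm), function(p) {
      tf_new <- pool$.tf
      for (g in groups) {
        if (length(g) > 1) tf_new[g] <- pool$.tf[g][sample.int(length(g))]
      }
      out <- lapply(names(site_sets), function(tf) {
        df <- pool[tf_new == tf, setdiff(names(pool), ".tf"), drop = FALSE]
        site_set(df, tf, attr(site_sets[[tf]], "cell_type"))
      })
      stats::setNames(out, names(site_sets))
    })
  })
}

#' TFs with enough sites in every required stratum
#'
#' Excludes TFs with fewer than `min_sites` ChIP-seq-identified sites in
#' any required sub-compartment (default A1 and A2); `min_sites = 0`
#' disables the filter.
#'
#' @param site_sets named list of [site_set()]s (bound sites).
#' @param annotation interval data frame with a `label` column.
#' @param required stratum labels that must each hold enough sites.
#' @param min_sites threshold (strictly fewer is excluded; default 300).
#' @return Character vector of retained TF identifiers.
#' @export
min_site_filter <- function(site_sets, annotation,
                            required = c("A1", "A2"), min_sites = 300) {
  if (min_sites <= 0) return(names(site_sets))
  keep <- vapply(site_sets, function(ss) {
    lab <- sub("^[^|]*\\|", "", site_strata(as.data.frame(ss), annotation))
    all(vapply(required, function(r) sum(lab == r, na.rm = TRUE),
               numeric(1)) >= min_sites)
  }, logical(1))
  names(site_sets)[keep]
}

# Null engine for one chromosome: the pooled site positions are fixed, so
# the pairwise score matrix is computed once; the per-locus score of any
# site against the fixed partner TF is a row sum over the partner's
# columns, and a permutation draw for the query TF is a random
# per-stratum subset of the pooled non-partner loci.
build_score_pool <- function(bound_sets, maps, profiles,
                             config = ccl_config(), strata = NULL) {
  tfs <- names(bound_sets)
  pool <- do.call(rbind, lapply(tfs, function(tf) {
    df <- as.data.frame(bound_sets[[tf]])
    data.frame(chrom = df$chrom, start = df$start, end = df$end, tf = tf,
               stringsAsFactors = FALSE)
  }))
  pool$stratum <- site_strata(pool, strata)
  chrom_data <- list()
  for (cc in names(maps)) {
    sel <- which(pool$chrom == cc)
    if (length(sel) < 2) next
    loci <- site_center(pool$start[sel], pool$end[sel])
    S <- pair_score_matrix(maps[[cc]], profiles[[cc]], loci, config)
    chrom_data[[cc]] <- list(rows = sel, S = S)
  }
  list(pool = pool, chrom_data = chrom_data, tfs = tfs)
}

# Observed scores and n_perm null score vectors for direction a -> b.
direction_scores <- function(sp, tf_a, tf_b, n_perm, seed) {
  pool <- sp$pool
  obs <- numeric(0)
  null_list <- vector("list", n_perm)
  for (k in seq_len(n_perm)) null_list[[k]] <- numeric(0)
  with_seed(seed, {
    for (cd in sp$chrom_data) {
      rows <- cd$rows
      tf_of <- pool$tf[rows]
      b_cols <- which(tf_of == tf_b)
      if (length(b_cols) == 0) next
      svec <- rowSums(cd$S[, b_cols, drop = FALSE], na.rm = TRUE)
      a_rows <- which(tf_of == tf_a)
      obs <- c(obs, svec[a_rows])
      movable <- which(tf_of != tf_b)
      strat <- pool$stratum[rows]
      by_str <- split(movable, strat[movable])
      a_per_str <- table(strat[a_rows])
      for (k in seq_len(n_perm)) {
        pick <- unlist(lapply(names(by_str), function(st) {
          need <- if (st %in% names(a_per_str)) a_per_str[[st]] else 0L
          if (need == 0) return(integer(0))
          cand <- by_str[[st]]
          if (length(cand) <= 1) return(cand[seq_len(min(need, length(cand)))])
          cand[sample.int(length(cand), need)]
        }), use.names = FALSE)
        null_list[[k]] <- c(null_list[[k]], svec[pick])
      }
    }
  })
  list(obs = obs, null = null_list)
}

#' Empirical enrichment p-values for one pair direction
#'
#' For each top-fraction cutoff (taken from the pooled null score
#' distribution), counts observed sites at or above the cutoff and
#' compares with the per-permutation counts. The default p-value is the
#' smoothed conservative estimator `(1 + b) / (1 + n_perm)`; the
#' `"randomized"` method breaks ties uniformly, which makes the null
#' p-value distribution exactly uniform for this discrete count statistic
#' and is the appropriate choice for calibration diagnostics.
#'
#' @param obs numeric vector of observed per-site scores.
#' @param null list of per-permutation score vectors.
#' @param top_fracs upper-tail fractions examined (default 20%, 10%, 5%).
#' @param p_method `"conservative"` or `"randomized"`.
#' @return Data frame with one row per fraction: `frac`, `cutoff`,
#'   `obs_count`, `null_mean`, `p`.
#' @export
direction_pvalues <- function(obs, null, top_fracs = c(0.20, 0.10, 0.05),
                              p_method = c("conservative", "randomized")) {
  p_method <- match.arg(p_method)
  pooled <- unlist(null, use.names = FALSE)
  n_perm <- length(null)
  out <- lapply(top_fracs, function(f) {
    cutoff <- stats::quantile(pooled, 1 - f, names = FALSE, type = 7)
    oc <- sum(obs >= cutoff)
    pc <- vapply(null, function(x) sum(x >= cutoff), numeric(1))
    p <- if (p_method == "conservative") {
      (1 + sum(pc >= oc)) / (1 + n_perm)
    } else {
      (sum(pc > oc) + stats::runif(1) * (1 + sum(pc == oc))) / (1 + n_perm)
    }
    data.frame(frac = f, cutoff = cutoff, obs_count = oc,
               null_mean = mean(pc), p = p)
  })
  do.call(rbind, out)
}

#' Call significantly co-localized TF pairs
#'
#' Applies Benjamini-Hochberg correction across all pair directions,
#' separately per top fraction, and calls a pair significant only when
#' both of its directions pass at the FDR threshold. How the three
#' fractions combine into one per-direction decision is configurable:
#' `"any"` (default; a direction passes if its adjusted p meets the
#' threshold at any fraction), `"all"`, or a single fraction.
#'
#' @param directions data frame from the pair driver: columns `tf_a`,
#'   `tf_b`, `frac`, `obs_count`, `null_mean`, `p` (one row per direction
#'   per fraction).
#' @param fdr FDR threshold (default 0.05).
#' @param combine `"any"`, `"all"` or a fraction such as `0.10`.
#' @return Data frame with one row per unordered pair: per-direction
#'   minimum adjusted p-values, counts at the ranking fraction and the
#'   `significant` call.
#' @export
call_significant_pairs <- function(directions, fdr = 0.05,
                                   combine = "any") {
  d <- directions
  d$p_adj <- NA_real_
  for (f in unique(d$frac)) {
    sel <- d$frac == f
    d$p_adj[sel] <- stats::p.adjust(d$p[sel], method = "BH")
  }
  pass_fun <- function(padj, fracs) {
    if (identical(combine, "any")) return(any(padj <= fdr))
    if (identical(combine, "all")) return(all(padj <= fdr))
    f <- as.numeric(combine)
    any(padj[abs(fracs - f) < 1e-9] <= fdr)
  }
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  d$pair <- key(d$tf_a, d$tf_b)
  out <- lapply(split(d, d$pair), function(sub) {
    dirs <- split(sub, paste(sub$tf_a, sub$tf_b))
    passes <- vapply(dirs, function(x) pass_fun(x$p_adj, x$frac),
                     logical(1))
    minp <- vapply(dirs, function(x) min(x$p_adj), numeric(1))
    a <- dirs[[1]]$tf_a[1]; b <- dirs[[1]]$tf_b[1]
    data.frame(tf_a = a, tf_b = b,
               p_adj_ab = minp[1],
               p_adj_ba = if (length(dirs) > 1) minp[2] else minp[1],
               significant = all(passes),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Signed Kullback-Leibler contact-enrichment (CE) score
#'
#' Histograms the observed and null (expected) CCL scores on shared
#' unit-width bins and computes
#' `CE = sign * sum_k P_obs,k * log(P_obs,k / P_exp,k)` with natural log;
#' bins with zero observed probability contribute nothing. The sign is
#' positive when the observed median is at or above the null median
#' (right shift), negative otherwise. When some observed bin has zero
#' expected probability, one pseudo-observation is added to every
#' expected bin before normalization so the divergence stays finite.
#'
#' @param obs observed scores.
#' @param null null scores (pooled over permutations) or a list of
#'   per-permutation vectors.
#' @param bin_width histogram bin width (default 1 CCL unit).
#' @return CE score (signed KL divergence).
#' @export
ce_score <- function(obs, null, bin_width = 1) {
  if (is.list(null)) null <- unlist(null, use.names = FALSE)
  stopifnot(length(obs) > 0, length(null) > 0)
  ko <- floor(obs / bin_width)
  ke <- floor(null / bin_width)
  rng <- range(c(ko, ke))
  bins <- rng[1]:rng[2]
  co <- tabulate(ko - rng[1] + 1L, nbins = length(bins))
  ce <- tabulate(ke - rng[1] + 1L, nbins = length(bins))
  if (any(co > 0 & ce == 0)) ce <- ce + 1
  po <- co / sum(co)
  pe <- ce / sum(ce)
  nz <- po > 0
  kl <- sum(po[nz] * log(po[nz] / pe[nz]))
  sgn <- if (stats::median(obs) >= stats::median(null)) 1 else -1
  sgn * kl
}

#' Hierarchical clustering of TFs into proximity sub-networks
#'
#' Clusters TFs from a pairwise enrichment matrix (CE or PE). The default
#' distance is `d(A, B) = exp(-(M[A,B] + M[B,A]) / 2)`, which symmetrizes
#' the generally asymmetric enrichment; `"euclidean"` uses squared
#' Euclidean distance between matrix rows. Linkage is Ward's method or
#' average linkage. Cluster labels come from a dynamic-tree-style cut: the
#' number of clusters is scanned and the cut maximizing the mean
#' silhouette width subject to a minimum cluster size is kept, with a
#' fixed `k = 2` fallback when no cut satisfies the size constraint.
#'
#' @param mat square enrichment matrix with TF dimnames.
#' @param method `"ward"` or `"average"`.
#' @param distance `"ce_exp"` or `"euclidean"`.
#' @param cut `"dynamic"` or `"k2"`.
#' @param min_size minimum cluster size for the dynamic cut (default 3).
#' @param k_max largest cluster count scanned.
#' @return A `tf_clusters` list with the `hclust` tree, integer `labels`
#'   named by TF, `method` and `cut`.
#' @export
cluster_tfs <- function(mat, method = c("ward", "average"),
                        distance = c("ce_exp", "euclidean"),
                        cut = c("dynamic", "k2"), min_size = 3,
                        k_max = 8) {
  method <- match.arg(method)
  distance <- match.arg(distance)
  cut <- match.arg(cut)
  n <- nrow(mat)
  if (n < 3) stopf("cluster_tfs: need at least 3 TFs")
  stopifnot(ncol(mat) == n)
  d <- if (distance == "ce_exp") {
    stats::as.dist(exp(-(mat + t(mat)) / 2))
  } else {
    stats::dist(mat)^2
  }
  tree <- stats::hclust(d, method = if (method == "ward") "ward.D2"
                        else "average")
  labels <- stats::cutree(tree, k = 2)
  chosen_k <- 2L
  if (cut == "dynamic") {
    best <- -Inf
    for (k in 2:min(k_max, n - 1)) {
      lab <- stats::cutree(tree, k = k)
      if (min(table(lab)) < min_size) next
      sil <- cluster::silhouette(lab, d)
      sc <- mean(sil[, "sil_width"])
      if (sc > best) {
        best <- sc; labels <- lab; chosen_k <- k
      }
    }
  }
  structure(list(tree = tree, labels = labels, k = chosen_k,
                 method = method, cut = cut),
            class = "tf_clusters")
}

#' Rank TF pairs by percentage increase in high-proximity sites
#'
#' `%delta = 100 * (obs_count - null_mean) / null_mean` on the number of
#' sites in the high-score group (or of proximal site pairs for the
#' structure variant); pairs are ordered by decreasing `%delta`, ties
#' broken by smaller empirical p-value. A zero null mean yields `Inf`,
#' ranked first.
#'
#' @param pairs data frame with `obs_count`, `null_mean` and `p` columns.
#' @return The input with `pct_delta` and `rank` columns, reordered.
#' @export
rank_pairs <- function(pairs) {
  stopifnot(all(c("obs_count", "null_mean", "p") %in% names(pairs)))
  pairs$pct_delta <- ifelse(pairs$null_mean == 0, Inf,
                            100 * (pairs$obs_count - pairs$null_mean) /
                              pairs$null_mean)
  ord <- order(-pairs$pct_delta, pairs$p)
  pairs <- pairs[ord, , drop = FALSE]
  pairs$rank <- seq_len(nrow(pairs))
  rownames(pairs) <- NULL
  pairs
}

#' Full pairwise TF co-localization analysis from Hi-C
#'
#' Runs every ordered TF pair direction against its permutation null:
#' heterotypic CCL score vectors, empirical enrichment p-values at the
#' top 20/10/5% cutoffs, significant-pair calling at the FDR threshold,
#' CE scores, pair ranking by percentage increase, and sub-network
#' clustering of the CE matrix.
#'
#' @param bound_sets named list of bound [site_set()]s (>= 2 TFs).
#' @param maps named list of filtered [contact_map()]s by chromosome.
#' @param profiles matching [expected_profile()]s.
#' @param config a [ccl_config()].
#' @param n_perm permutations per direction (1000 in the full-scale
#'   analysis; smaller values are appropriate for simulation studies).
#' @param seed RNG seed.
#' @param strata optional sub-compartment annotation for stratified
#'   permutation.
#' @param top_fracs upper-tail fractions examined.
#' @param fdr FDR threshold.
#' @param combine per-direction combination rule (see
#'   [call_significant_pairs()]).
#' @param p_method see [direction_pvalues()].
#' @param rank_frac fraction whose counts feed [rank_pairs()] (default
#'   0.10).
#' @param cluster whether to cluster the CE matrix (needs >= 3 TFs).
#' @return List with `pairs` (ranked pair table), `directions`
#'   (per-direction per-fraction statistics), `ce` (matrix) and
#'   `clusters`.
#' @export
tf_pair_analysis <- function(bound_sets, maps, profiles,
                             config = ccl_config(), n_perm = 1000,
                             seed = 1, strata = NULL,
                             top_fracs = c(0.20, 0.10, 0.05), fdr = 0.05,
                             combine = "any",
                             p_method = "conservative",
                             rank_frac = 0.10, cluster = TRUE) {
  tfs <- names(bound_sets)
  stopifnot(length(tfs) >= 2)
  sp <- build_score_pool(bound_sets, maps, profiles, config, strata)
  dirs <- list()
  ce <- matrix(0, length(tfs), length(tfs), dimnames = list(tfs, tfs))
  idx <- 0L
  for (i in seq_along(tfs)) {
    for (j in seq_along(tfs)) {
      if (i == j) next
      idx <- idx + 1L
      ds <- direction_scores(sp, tfs[i], tfs[j], n_perm,
                             seed = seed + 104729L * i + j)
      pv <- direction_pvalues(ds$obs, ds$null, top_fracs, p_method)
      pv$tf_a <- tfs[i]; pv$tf_b <- tfs[j]
      dirs[[idx]] <- pv
      ce[tfs[i], tfs[j]] <- ce_score(ds$obs, ds$null)
    }
  }
  directions <- do.call(rbind, dirs)
  calls <- call_significant_pairs(directions, fdr, combine)
  rk <- directions[abs(directions$frac - rank_frac) < 1e-9, , drop = FALSE]
  key <- paste(pmin(rk$tf_a, rk$tf_b), pmax(rk$tf_a, rk$tf_b))
  agg <- do.call(rbind, lapply(split(rk, key), function(sub) {
    data.frame(tf_a = min(sub$tf_a[1], sub$tf_b[1]),
               tf_b = max(sub$tf_a[1], sub$tf_b[1]),
               obs_count = sum(sub$obs_count),
               null_mean = sum(sub$null_mean),
               p = min(sub$p), stringsAsFactors = FALSE)
  }))
  pairs <- merge(calls, agg, by = c("tf_a", "tf_b"))
  pairs <- rank_pairs(pairs)
  cl <- if (cluster && length(tfs) >= 3) cluster_tfs(ce) else NULL
  list(pairs = pairs, directions = directions, ce = ce, clusters = cl)
}
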