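# Independent brute-force oracles and small fixture builders. These
# deliberately re-derive every rule from first principles with plain
# loops, sharing no code with the package's scoring path.

# Expected profile: mean normalized count over unmasked pairs per
# separation, zeros included.
oracle_profile <- function(map) {
  n <- map$n_bins
  vals <- rep(NA_real_, n)
  for (s in 0:(n - 1)) {
    tot <- 0; cnt <- 0
    for (i in 1:(n - s)) {
      j <- i + s
      if (map$mask[i] && map$mask[j]) {
        tot <- tot + map$norm[i, j]
        cnt <- cnt + 1
      }
    }
    if (cnt > 0) vals[s + 1] <- tot / cnt
  }
  vals
}

# Merged-window log(obs/exp) for one locus pair; NA when any filter
# drops the pair. Thresholds follow the printed rules: strictly more
# than 25 kb separation, strictly more than 20 raw reads, 25-kb bins
# beyond 100 kb, 55-kb bins beyond 1 Mb.
oracle_pair <- function(map, prof_vals, locus_i, locus_j) {
  bs <- map$bin_size
  bi <- locus_i %/% bs
  bj <- locus_j %/% bs
  if (bi == bj) return(NA_real_)
  sep_bp <- abs(bi - bj) * bs
  if (sep_bp <= 25000) return(NA_real_)
  h <- if (sep_bp > 1e6) 5L else if (sep_bp > 1e5) 2L else 0L
  wi <- (bi - h):(bi + h)
  wj <- (bj - h):(bj + h)
  if (min(wi, wj) < 0 || max(wi, wj) >= map$n_bins) return(NA_real_)
  if (any(!map$mask[c(wi, wj) + 1])) return(NA_real_)
  obs <- 0; raw <- 0; ex <- 0
  for (a in wi) for (b in wj) {
    obs <- obs + map$norm[a + 1, b + 1]
    raw <- raw + map$raw[a + 1, b + 1]
    ev <- prof_vals[abs(a - b) + 1]
    if (is.na(ev)) return(NA_real_)
    ex <- ex + ev
  }
  if (!(raw > 20)) return(NA_real_)
  if (ex <= 0 || obs <= 0) return(NA_real_)
  log(obs / ex)
}

# Per-query-site CCL by full pair enumeration.
oracle_ccl <- function(query_centers, partner_centers, map, prof_vals) {
  vapply(query_centers, function(ci) {
    tot <- 0
    for (cj in partner_centers) {
      v <- oracle_pair(map, prof_vals, ci, cj)
      if (!is.na(v)) tot <- tot + v
    }
    tot
  }, numeric(1))
}

# Small deterministic contact map: power-law decay, no noise, heavy raw
# counts so no pair fails the read filter unless asked for.
toy_map <- function(n_bins = 60, bin_size = 5000, base = 1000,
                    alpha = 1, chrom = "chrT", seed = NULL) {
  up <- which(upper.tri(matrix(0, n_bins, n_bins)), arr.ind = TRUE)
  s <- up[, 2] - up[, 1]
  norm <- base * s^-alpha
  if (!is.null(seed)) {
    set.seed(seed)
    norm <- norm * exp(stats::rnorm(length(norm), 0, 0.3))
  }
  contact_map(chrom, bin_size, up[, 1] - 1L, up[, 2] - 1L, norm,
              raw = round(norm), n_bins = n_bins)
}

toy_sites <- function(bins, tf = "TF", bin_size = 5000, chrom = "chrT",
                      bound = TRUE) {
  start <- bins * bin_size + 2400L
  site_set(data.frame(chrom = chrom, start = start, end = start + 200L,
                      bound = bound), tf)
}

# Simple multi-model structure with given base coordinates.
toy_structure <- function(xyz, n_models = 10, jitter = 0, chrom = "chrS",
                          compartment = NULL, seed = 1) {
  set.seed(seed)
  n <- nrow(xyz)
  coords <- array(NA_real_, dim = c(n, 3, n_models))
  for (m in seq_len(n_models))
    coords[, , m] <- xyz + matrix(stats::rnorm(3 * n, sd = jitter),
                                  ncol = 3)
  genome_structure(
    data.frame(chrom = chrom, start = (seq_len(n) - 1) * 1e5),
    coords, compartment = compartment)
}

# Straight-line walk coordinates: particle i at (2 * r * i, 0, 0).
line_coords <- function(n, step = 1) {
  cbind(step * seq_len(n), 0, 0)
}

# Adjusted Rand index (independent of any clustering package).
rand_index_adj <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  expected <- si * sj / n
  (sij - expected) / ((si + sj) / 2 - expected)
}
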