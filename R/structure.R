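#' Multi-model particle genome structure
#'
#' Coordinates of a genome modelled as a string of fixed-size particles
#' (100 kb by default), with several alternative coordinate models per
#' cell. The particle radius is estimated as half the median 3D distance
#' between sequentially adjacent intra-chromosome particles, pooled over
#' models, because model units are arbitrary and the repulsive radius of
#' the source models corresponds to half the ideal sequential particle
#' separation.
#'
#' @param particles data frame with `chrom`, `start` (bp, sequentially
#'   ordered within each chromosome).
#' @param coords numeric array `n_particles x 3 x n_models`.
#' @param particle_size particle size in bp.
#' @param compartment per-particle `A`/`B` labels, or an interval data
#'   frame with a `label` column looked up by particle midpoint.
#' @return A `genome_structure` object.
#' @export
genome_structure <- function(particles, coords, particle_size = 1e5,
                             compartment = NULL) {
  stopifnot(is.data.frame(particles), length(dim(coords)) == 3,
            dim(coords)[1] == nrow(particles), dim(coords)[2] == 3)
  for (cc in unique(particles$chrom)) {
    s <- particles$start[particles$chrom == cc]
    if (is.unsorted(s, strictly = TRUE))
      stopf("genome_structure: particles not ordered within %s", cc)
  }
  n <- nrow(particles)
  m <- dim(coords)[3]
  adj <- which(particles$chrom[-n] == particles$chrom[-1])
  if (length(adj) == 0) stopf("genome_structure: no sequential particle pairs")
  d <- unlist(lapply(seq_len(m), function(k) {
    sqrt(rowSums((coords[adj, , k, drop = FALSE] -
                    coords[adj + 1L, , k, drop = FALSE])^2))
  }))
  radius <- stats::median(d) / 2
  comp <- rep(NA_character_, n)
  if (is.data.frame(compartment)) {
    mid <- particles$start + particle_size %/% 2
    for (cc in unique(particles$chrom)) {
      sel <- particles$chrom == cc
      ivs <- compartment[compartment$chrom == cc, , drop = FALSE]
      if (nrow(ivs) == 0) next
      idx <- findInterval(mid[sel], ivs$start)
      lab <- ifelse(idx >= 1 & mid[sel] < ivs$end[pmax(idx, 1)],
                    ivs$label[pmax(idx, 1)], NA_character_)
      comp[sel] <- substr(lab, 1, 1)  # sub-compartments collapse to A/B
    }
  } else if (!is.null(compartment)) {
    comp <- as.character(rep_len(compartment, n))
  }
  structure(list(particles = particles, coords = coords,
                 particle_size = particle_size, radius = radius,
                 n_particles = n, n_models = m, compartment = comp),
            class = "genome_structure")
}

#' @export
print.genome_structure <- function(x, ...) {
  cat(sprintf(
    "genome_structure: %d particles x %d models, %d chromosome(s), radius %.3g\n",
    x$n_particles, x$n_models, length(unique(x$particles$chrom)), x$radius))
  invisible(x)
}

# Kabsch least-squares superposition of coordinate set b onto a.
kabsch <- function(a, b) {
  ca <- colMeans(a); cb <- colMeans(b)
  h <- crossprod(sweep(b, 2, cb), sweep(a, 2, ca))
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  sweep(sweep(b, 2, cb) %*% t(rot), 2, ca, "+")
}

#' Model-consistency QC of a genome structure
#'
#' Superposes every model onto the first by rigid-body least squares and
#' computes a per-particle RMSD across models, in particle radii, as the
#' square root of the summed per-coordinate sample variances
#' (`sum_m ||x_m - mean||^2 / (M - 1)`). Particles with RMSD below one
#' radius count as well-defined; only those enter downstream analyses.
#'
#' @param structure a [genome_structure()].
#' @return A `structure_qc` list with `rmsd` (in radii), logical
#'   `defined_mask` and `coverage_fraction`.
#' @export
qc_structure <- function(structure) {
  n <- structure$n_particles
  m <- structure$n_models
  if (m < 2) {
    warnf("qc_structure: single model; all particles pass")
    return(structure(list(rmsd = rep(0, n), defined_mask = rep(TRUE, n),
                          coverage_fraction = 1), class = "structure_qc"))
  }
  fitted <- array(NA_real_, dim = dim(structure$coords))
  fitted[, , 1] <- structure$coords[, , 1]
  for (k in 2:m)
    fitted[, , k] <- kabsch(fitted[, , 1], structure$coords[, , k])
  mean_xyz <- apply(fitted, c(1, 2), mean)
  ss <- rowSums(vapply(seq_len(m), function(k)
    rowSums((fitted[, , k] - mean_xyz)^2), numeric(n)))
  rmsd <- sqrt(ss / (m - 1)) / structure$radius
  mask <- rmsd < 1
  structure(list(rmsd = rmsd, defined_mask = mask,
                 coverage_fraction = mean(mask)),
            class = "structure_qc")
}

# Sequential particle separation matrix helper: TRUE where a particle pair
# is eligible (different chromosomes, or more than `min_gap` particles
# apart on the same chromosome).
sequential_eligible <- function(structure, min_gap = 3L) {
  chrom <- structure$particles$chrom
  idx <- unlist(lapply(unique(chrom), function(cc) seq_len(sum(chrom == cc))))
  same <- outer(chrom, chrom, "==")
  gap <- abs(outer(idx, idx, "-"))
  !same | gap > min_gap
}

#' Consistently proximal particle pairs
#'
#' A particle pair is proximal only when both particles are well-defined,
#' their distance is within `threshold` particle radii in every model, and
#' the pair is more than three particles apart sequentially (300 kb) or on
#' different chromosomes. `mode` restricts to intra- (`"cis"`) or
#' inter-chromosomal (`"trans"`) pairs.
#'
#' @param structure a [genome_structure()].
#' @param qc matching [qc_structure()] output.
#' @param threshold distance threshold in particle radii (1.5, 2 or 3 in
#'   the source analyses).
#' @param mode `"all"`, `"cis"` or `"trans"`.
#' @param min_gap sequential exclusion in particles (default 3).
#' @return A `proximity_pairs` list with the logical adjacency matrix
#'   (`adjacency`), the pair index matrix (`pairs`), `threshold` and
#'   `mode`.
#' @export
consistent_pairs <- function(structure, qc, threshold = 3,
                             mode = c("all", "cis", "trans"),
                             min_gap = 3L) {
  mode <- match.arg(mode)
  stopifnot(threshold > 0)
  n <- structure$n_particles
  lim <- threshold * structure$radius
  close_all <- matrix(TRUE, n, n)
  for (k in seq_len(structure$n_models)) {
    d <- as.matrix(stats::dist(structure$coords[, , k]))
    close_all <- close_all & (d <= lim)
  }
  elig <- sequential_eligible(structure, min_gap)
  if (mode == "cis")
    elig <- elig & outer(structure$particles$chrom,
                         structure$particles$chrom, "==")
  if (mode == "trans")
    elig <- elig & outer(structure$particles$chrom,
                         structure$particles$chrom, "!=")
  adj <- close_all & elig &
    outer(qc$defined_mask, qc$defined_mask, "&")
  diag(adj) <- FALSE
  ut <- which(adj & upper.tri(adj), arr.ind = TRUE)
  structure(list(adjacency = adj, pairs = ut, threshold = threshold,
                 mode = mode, min_gap = min_gap),
            class = "proximity_pairs")
}

# Inverse-cube distance kernel averaged over models, zeroed for ineligible
# or ill-defined pairs. spatial_density and the permutation null reuse it:
# a circular permutation only changes the per-particle site-count vector.
density_kernel <- function(structure, qc, min_gap = 3L) {
  n <- structure$n_particles
  acc <- matrix(0, n, n)
  for (k in seq_len(structure$n_models)) {
    d <- as.matrix(stats::dist(structure$coords[, , k]))
    if (any(d[upper.tri(d)] == 0))
      stopf("density_kernel: coincident particles (zero distance)")
    acc <- acc + 1 / d^3
  }
  acc <- acc / structure$n_models
  acc[!sequential_eligible(structure, min_gap)] <- 0
  acc[!qc$defined_mask, ] <- 0
  acc[, !qc$defined_mask] <- 0
  diag(acc) <- 0
  acc
}

#' Spatial site density at each structure particle
#'
#' The radial density at particle i is the sum over particles j (well-
#' defined, more than 300 kb apart sequentially or on another chromosome)
#' of `n_j / d_ij^3`, where `n_j` is the weighted site count of particle j
#' and `d_ij` the inter-particle distance; computed per model and averaged
#' over models. The cube power makes the measure close-range focused.
#'
#' @param structure a [genome_structure()].
#' @param qc matching [qc_structure()] output.
#' @param track per-particle site counts: a numeric vector aligned to the
#'   particle list or a [linear_density()] track.
#' @param kernel optional precomputed inverse-cube distance kernel
#'   (recomputed when `NULL`).
#' @return Numeric vector of densities `r_i`.
#' @export
spatial_density <- function(structure, qc, track, kernel = NULL) {
  n_vec <- track_values(track, structure)
  kernel <- kernel %||% density_kernel(structure, qc)
  as.numeric(kernel %*% n_vec)
}

track_values <- function(track, structure) {
  if (is.numeric(track)) {
    stopifnot(length(track) == structure$n_particles)
    return(track)
  }
  if (inherits(track, "linear_density_track")) {
    key_t <- paste(track$chrom, track$start)
    key_p <- paste(structure$particles$chrom, structure$particles$start)
    idx <- match(key_p, key_t)
    out <- ifelse(is.na(idx), 0, track$value[idx])
    return(out)
  }
  stopf("spatial_density: unsupported track type")
}

#' Spatial density enrichment (SDE) against a circular-permutation null
#'
#' Compares the observed radial density at each particle with the mean
#' density over `n_perm` circular permutations of the site track along the
#' chromosome: within each chromosome, and separately within A and B
#' compartments, the per-particle site counts are rotated by an
#' independent random offset, preserving the sequential clustering of
#' sites and their compartment distribution. The score is printed as
#' `SDE_i = log2(r0_i / r_i)` (`orientation = "as_printed"`); the switch
#' `orientation = "enrichment"` returns `log2(r_i / r0_i)`, under which
#' positive values mean denser than expected.
#'
#' @inheritParams spatial_density
#' @param n_perm number of circular permutations (default 100).
#' @param seed RNG seed.
#' @param orientation `"as_printed"` or `"enrichment"`.
#' @return Data frame with `r`, `r0` and `sde` (NA where either density is
#'   zero).
#' @export
sde <- function(structure, qc, track, n_perm = 100, seed = 1,
                orientation = c("as_printed", "enrichment"),
                kernel = NULL) {
  orientation <- match.arg(orientation)
  if (all(is.na(structure$compartment)))
    stopf("sde: structure carries no compartment labels")
  n_vec <- track_values(track, structure)
  kernel <- kernel %||% density_kernel(structure, qc)
  r <- as.numeric(kernel %*% n_vec)
  groups <- split(seq_len(structure$n_particles),
                  list(structure$particles$chrom, structure$compartment),
                  drop = TRUE)
  r0 <- with_seed(seed, {
    acc <- numeric(structure$n_particles)
    for (p in seq_len(n_perm)) {
      perm <- n_vec
      for (g in groups) {
        off <- sample.int(length(g), 1) - 1L
        if (off > 0)
          perm[g] <- n_vec[g][c((off + 1):length(g), seq_len(off))]
      }
      acc <- acc + as.numeric(kernel %*% perm)
    }
    acc / n_perm
  })
  val <- ifelse(r > 0 & r0 > 0,
                if (orientation == "as_printed") log2(r0 / r)
                else log2(r / r0),
                NA_real_)
  data.frame(r = r, r0 = r0, sde = val)
}

#' Z-normalize SDE values on the low-density reference quartile
#'
#' Standardizes SDE values using the mean and standard deviation estimated
#' on the 25% of particles with the lowest sequential site density, whose
#' values most closely match a random background.
#'
#' @param sde_values numeric vector (or [sde()] output data frame).
#' @param track per-particle sequential site counts (vector or
#'   [linear_density()] track aligned to the same particles).
#' @param structure optional [genome_structure()] for track alignment.
#' @return Numeric vector of z-scores.
#' @export
z_normalize_sde <- function(sde_values, track, structure = NULL) {
  x <- if (is.data.frame(sde_values)) sde_values$sde else sde_values
  n_vec <- if (is.numeric(track)) track else track_values(track, structure)
  stopifnot(length(x) == length(n_vec))
  if (length(x) < 8) stopf("z_normalize_sde: need at least 8 particles")
  nref <- max(2L, floor(length(x) / 4))
  ref <- x[order(n_vec)[seq_len(nref)]]
  m <- mean(ref, na.rm = TRUE)
  s <- stats::sd(ref, na.rm = TRUE)
  if (!is.finite(s) || s == 0)
    stopf("z_normalize_sde: zero variance in the reference quartile")
  (x - m) / s
}

#' Map binding sites onto structure particles
#'
#' A site belongs to the particle whose region contains its center.
#' Sites on chromosomes absent from the structure, or whose center falls
#' beyond the modelled particles, are dropped with a warning.
#'
#' @param site_sets named list of [site_set()]s.
#' @param structure a [genome_structure()].
#' @return Data frame with `tf`, `particle` (index), `chrom`,
#'   `compartment`.
#' @export
structure_site_table <- function(site_sets, structure) {
  parts <- structure$particles
  rows <- lapply(site_sets, function(ss) {
    ctr <- site_center(ss$start, ss$end)
    idx <- rep(NA_integer_, nrow(ss))
    for (cc in unique(ss$chrom)) {
      psel <- which(parts$chrom == cc)
      if (length(psel) == 0) next
      sel <- ss$chrom == cc
      k <- findInterval(ctr[sel], parts$start[psel])
      ok <- k >= 1 & ctr[sel] < parts$start[psel][pmax(k, 1)] +
        structure$particle_size
      idx[sel][ok] <- psel[k[ok]]
    }
    if (anyNA(idx))
      warnf("structure_site_table: dropping %d unmapped '%s' site(s)",
            sum(is.na(idx)), tf_id(ss))
    data.frame(tf = tf_id(ss), particle = idx[!is.na(idx)],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$chrom <- parts$chrom[out$particle]
  out$compartment <- structure$compartment[out$particle]
  out
}

#' Crowding-level strata for structure permutation nulls
#'
#' The crowding level `N_j` of a binding site is the number of sites of
#' any TF on consistently proximal particles (same proximity rules as
#' [consistent_pairs()], so sequentially close sites are excluded).
#' Within each compartment, sites are ranked by `N_j` and split into
#' `n_groups` equal-sized groups (remainder spread over the lowest
#' groups, ties broken by site order).
#'
#' @param site_table combined [structure_site_table()] of all TFs.
#' @param pairs a [consistent_pairs()] result.
#' @param n_groups number of crowding groups (default 5; 10 or 20 give
#'   nearly identical control sets in the source analyses).
#' @return `site_table` with `crowding`, `stratum` and the permutation
#'   `cell` (chromosome x compartment x stratum) appended.
#' @export
crowding_strata <- function(site_table, pairs, n_groups = 5) {
  n_part <- nrow(pairs$adjacency)
  cnt <- tabulate(site_table$particle, nbins = n_part)
  near <- as.numeric(pairs$adjacency %*% cnt)
  site_table$crowding <- near[site_table$particle]
  site_table$stratum <- NA_integer_
  for (comp in unique(site_table$compartment)) {
    sel <- which(site_table$compartment %in% comp)
    n <- length(sel)
    k <- min(n_groups, n)
    sizes <- rep(n %/% k, k)
    if (n %% k > 0) sizes[seq_len(n %% k)] <- sizes[seq_len(n %% k)] + 1L
    ord <- sel[order(site_table$crowding[sel])]  # stable: ties by order
    site_table$stratum[ord] <- rep(seq_len(k), times = sizes)
  }
  site_table$cell <- paste(site_table$chrom, site_table$compartment,
                           site_table$stratum, sep = "|")
  site_table
}

# Count consistently proximal (A site, B site) pairs given per-particle
# site counts; unordered within-set pairs for the homotypic diagonal.
proximal_pair_count <- function(adj, count_a, count_b, homotypic) {
  if (homotypic) {
    as.numeric(count_a %*% adj %*% count_a) / 2
  } else {
    as.numeric(count_a %*% adj %*% count_b)
  }
}

#' Structural proximity enrichment (PE) between two TFs
#'
#' Counts consistently proximal site pairs between the two TFs (observed)
#' and compares with the mean count over permutations that shuffle all
#' site-to-particle assignments within chromosome x compartment x
#' crowding-stratum cells, preserving per-cell site counts for every TF.
#' `PE = log2(Obs / Exp)`; the empirical p-value uses the smoothed
#' `(1 + b) / (1 + n_perm)` estimator. `log_base = exp(1)` switches the
#' score to natural log.
#'
#' @param strata [crowding_strata()] output covering all TFs whose sites
#'   move in the null (including A and B).
#' @param tf_a,tf_b TF identifiers (equal for homotypic self-enrichment).
#' @param pairs a [consistent_pairs()] result.
#' @param n_perm permutations (default 100).
#' @param seed RNG seed.
#' @param log_base base of the enrichment log (default 2).
#' @return List with `pe`, `p`, `obs`, `exp` (`pe` is `NA` when the
#'   expected count is zero).
#' @export
pe_score <- function(strata, tf_a, tf_b, pairs, n_perm = 100, seed = 1,
                     log_base = 2) {
  n_part <- nrow(pairs$adjacency)
  adj <- pairs$adjacency * 1
  homotypic <- identical(tf_a, tf_b)
  ca <- tabulate(strata$particle[strata$tf == tf_a], nbins = n_part)
  cb <- tabulate(strata$particle[strata$tf == tf_b], nbins = n_part)
  obs <- proximal_pair_count(adj, ca, cb, homotypic)
  cells <- split(seq_len(nrow(strata)), strata$cell)
  perm_counts <- with_seed(seed, vapply(seq_len(n_perm), function(p) {
    part <- strata$particle
    for (g in cells) part[g] <- strata$particle[g][sample.int(length(g))]
    pa <- tabulate(part[strata$tf == tf_a], nbins = n_part)
    pb <- tabulate(part[strata$tf == tf_b], nbins = n_part)
    proximal_pair_count(adj, pa, pb, homotypic)
  }, numeric(1)))
  expc <- mean(perm_counts)
  pe <- if (expc > 0 && obs > 0) log(obs / expc, base = log_base)
        else NA_real_
  p <- (1 + sum(perm_counts >= obs)) / (1 + n_perm)
  list(pe = pe, p = p, obs = obs, exp = expc)
}

#' PE matrix over all TF pairs, with sub-network clustering
#'
#' Computes the symmetric TF x TF structural proximity enrichment matrix
#' (including homotypic self-enrichment on the diagonal) and clusters the
#' TFs with [cluster_tfs()]. In `mode = "trans"` only inter-chromosomal
#' particle pairs are counted (meaningful only at the 3-radius
#' threshold, where enough pairs exist).
#'
#' @param site_sets named list of [site_set()]s (>= 3 TFs).
#' @param structure a [genome_structure()].
#' @param qc matching [qc_structure()]; computed when `NULL`.
#' @param threshold distance threshold in particle radii.
#' @param mode `"all"`, `"cis"` or `"trans"`.
#' @param n_perm permutations per pair.
#' @param seed RNG seed.
#' @param n_groups crowding strata count.
#' @param cluster whether to cluster the matrix.
#' @return List with `pe` (matrix), `p` (matrix of empirical p-values) and
#'   `clusters` (a [cluster_tfs()] result or `NULL`).
#' @export
pe_matrix <- function(site_sets, structure, qc = NULL, threshold = 3,
                      mode = c("all", "cis", "trans"), n_perm = 100,
                      seed = 1, n_groups = 5, cluster = TRUE) {
  mode <- match.arg(mode)
  if (length(site_sets) < 3) stopf("pe_matrix: need at least 3 TFs")
  qc <- qc %||% qc_structure(structure)
  pairs <- consistent_pairs(structure, qc, threshold, mode)
  if (mode == "trans" && nrow(pairs$pairs) == 0)
    stopf("pe_matrix: no trans particle pairs in the structure")
  tab <- structure_site_table(site_sets, structure)
  strata <- crowding_strata(tab, pairs, n_groups)
  tfs <- names(site_sets)
  n_part <- structure$n_particles
  adj <- pairs$adjacency * 1
  count_mat <- function(part) {
    vapply(tfs, function(tf) tabulate(part[strata$tf == tf],
                                      nbins = n_part),
           numeric(n_part))
  }
  pair_counts <- function(part) {
    cm <- count_mat(part)
    pc <- t(cm) %*% adj %*% cm
    diag(pc) <- diag(pc) / 2  # homotypic: unordered within-set pairs
    pc
  }
  obs <- pair_counts(strata$particle)
  cells <- split(seq_len(nrow(strata)), strata$cell)
  # one shared set of permuted site-to-particle configurations evaluated
  # for every TF combination
  acc <- matrix(0, length(tfs), length(tfs))
  ge <- matrix(0, length(tfs), length(tfs))
  with_seed(seed, {
    for (p in seq_len(n_perm)) {
      part <- strata$particle
      for (g in cells) part[g] <- strata$particle[g][sample.int(length(g))]
      pc <- pair_counts(part)
      acc <- acc + pc
      ge <- ge + (pc >= obs)
    }
  })
  expc <- acc / n_perm
  pe <- ifelse(obs > 0 & expc > 0, log2(obs / expc), NA_real_)
  pv <- (1 + ge) / (1 + n_perm)
  dimnames(pe) <- dimnames(pv) <- list(tfs, tfs)
  cl <- NULL
  if (cluster) {
    filled <- pe
    filled[is.na(filled)] <- 0
    cl <- cluster_tfs(filled)
  }
  list(pe = pe, p = pv, clusters = cl, threshold = threshold, mode = mode)
}
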