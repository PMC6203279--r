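# Structure QC, proximity pairs, spatial density, SDE, crowding strata
# and PE scoring.

test_that("identical models give zero RMSD and a full mask", {
  st <- toy_structure(line_coords(10), n_models = 10, jitter = 0)
  qc <- qc_structure(st)
  expect_true(all(qc$rmsd == 0))
  expect_true(all(qc$defined_mask))
  expect_equal(qc$coverage_fraction, 1)
})

test_that("a single displaced particle has the closed-form RMSD", {
  # with many particles, superposition barely reacts to one outlier and
  # the sample-variance RMSD approaches d / sqrt(M) for a displacement d
  n <- 200
  st <- toy_structure(line_coords(n), n_models = 10, jitter = 0)
  st$coords[15, 2, 4] <- st$coords[15, 2, 4] + 2 * st$radius
  qc <- qc_structure(st)
  expect_equal(qc$rmsd[15], 2 / sqrt(10), tolerance = 0.02)
  expect_true(qc$defined_mask[15])  # 0.63 radii < 1
  # a 4-radius displacement crosses the threshold (4/sqrt(10) = 1.26)
  st$coords[15, 2, 4] <- st$coords[15, 2, 4] + 2 * st$radius
  qc2 <- qc_structure(st)
  expect_gt(qc2$rmsd[15], 1)
  expect_false(qc2$defined_mask[15])
})

test_that("superposition makes QC invariant to per-model rigid motions", {
  set.seed(3)
  xyz <- matrix(rnorm(60), ncol = 3)
  st <- toy_structure(xyz, n_models = 5, jitter = 0.05)
  qc1 <- qc_structure(st)
  st2 <- st
  for (m in 1:5) {
    rot <- qr.Q(qr(matrix(rnorm(9), 3)))
    if (det(rot) < 0) rot[, 1] <- -rot[, 1]
    st2$coords[, , m] <- st$coords[, , m] %*% rot +
      matrix(rnorm(3), 20, 3, byrow = TRUE)
  }
  qc2 <- qc_structure(st2)
  expect_equal(qc2$rmsd, qc1$rmsd, tolerance = 1e-9)
})

test_that("proximity requires all models and sequential distance", {
  n <- 12
  xyz <- line_coords(n)
  # bring particles 1 and 10 close: well beyond 3 sequential particles
  xyz[10, ] <- xyz[1, ] + c(0.5, 0, 0)
  st <- toy_structure(xyz, n_models = 10, jitter = 0)
  qc <- qc_structure(st)
  cp <- consistent_pairs(st, qc, threshold = 3)
  expect_true(cp$adjacency[1, 10])
  # same pair failing in one of ten models is dropped
  st2 <- st
  st2$coords[10, 1, 7] <- st2$coords[1, 1, 7] + 10
  cp2 <- consistent_pairs(st2, qc_structure(st2), threshold = 3)
  expect_false(cp2$adjacency[1, 10])
  # sequentially close pairs are excluded regardless of distance
  expect_false(cp$adjacency[1, 2])
  expect_false(cp$adjacency[1, 4])  # exactly 3 apart: excluded
  expect_false(cp$adjacency[5, 6])
})

test_that("proximity sets are monotone in the threshold", {
  set.seed(8)
  st <- toy_structure(matrix(rnorm(90, sd = 1), ncol = 3),
                      n_models = 5, jitter = 0.02)
  qc <- qc_structure(st)
  p15 <- consistent_pairs(st, qc, 1.5)$adjacency
  p20 <- consistent_pairs(st, qc, 2)$adjacency
  p30 <- consistent_pairs(st, qc, 3)$adjacency
  expect_true(all(p20[p15]))
  expect_true(all(p30[p20]))
})

test_that("trans mode keeps only inter-chromosome pairs", {
  xyz <- rbind(line_coords(6), line_coords(6) + 0.3)
  st <- toy_structure(xyz, n_models = 3, jitter = 0)
  st$particles$chrom <- rep(c("chr1", "chr2"), each = 6)
  st$particles$start <- rep((0:5) * 1e5, 2)
  qc <- qc_structure(st)
  cpt <- consistent_pairs(st, qc, 3, mode = "trans")
  ij <- cpt$pairs
  expect_true(all(st$particles$chrom[ij[, 1]] !=
                    st$particles$chrom[ij[, 2]]))
  cpc <- consistent_pairs(st, qc, 3, mode = "cis")
  ijc <- cpc$pairs
  expect_true(all(st$particles$chrom[ijc[, 1]] ==
                    st$particles$chrom[ijc[, 2]]))
})

test_that("spatial density matches the brute-force double loop", {
  set.seed(5)
  xyz <- matrix(rnorm(30, sd = 2), ncol = 3)
  st <- toy_structure(xyz, n_models = 4, jitter = 0.05)
  qc <- qc_structure(st)
  track <- runif(10)
  r <- spatial_density(st, qc, track)
  # oracle: per model, per eligible pair
  ora <- numeric(10)
  for (i in 1:10) {
    for (j in 1:10) {
      if (abs(i - j) <= 3) next
      if (!qc$defined_mask[i] || !qc$defined_mask[j]) next
      d3 <- mean(vapply(1:4, function(m)
        1 / sum((st$coords[i, , m] - st$coords[j, , m])^2)^1.5,
        numeric(1)))
      ora[i] <- ora[i] + track[j] * d3
    }
  }
  expect_equal(r, ora, tolerance = 1e-12)
  # two-particle single term: r = n / d^3 (need a gap > 3 particles)
  st2 <- toy_structure(rbind(c(0, 0, 0), c(40, 0, 0), c(80, 0, 0),
                             c(120, 0, 0), c(160, 0, 0)),
                       n_models = 2, jitter = 0)
  qc2 <- qc_structure(st2)
  r2 <- spatial_density(st2, qc2, c(1, 0, 0, 0, 1))
  expect_equal(r2[1], 1 / 160^3, tolerance = 1e-12)
})

test_that("doubling coordinates scales densities by one eighth", {
  set.seed(6)
  st <- toy_structure(matrix(rnorm(45, sd = 3), ncol = 3), n_models = 3,
                      jitter = 0)
  qc <- qc_structure(st)
  track <- rpois(15, 2)
  r1 <- spatial_density(st, qc, track)
  st2 <- st
  st2$coords <- st$coords * 2
  st2$radius <- st$radius * 2
  r2 <- spatial_density(st2, qc_structure(st2), track)
  expect_equal(r2, r1 / 8, tolerance = 1e-9)
})

test_that("SDE is identically zero for a uniform track", {
  set.seed(2)
  st <- toy_structure(matrix(rnorm(90, sd = 2), ncol = 3), n_models = 3,
                      jitter = 0, compartment = rep(c("A", "B"), 15))
  qc <- qc_structure(st)
  res <- sde(st, qc, rep(1, 30), n_perm = 10, seed = 1)
  expect_true(all(abs(res$sde) < 1e-12, na.rm = TRUE))
  # determinism under the seed
  trk <- rpois(30, 2)
  a <- sde(st, qc, trk, n_perm = 20, seed = 9)
  b <- sde(st, qc, trk, n_perm = 20, seed = 9)
  expect_identical(a, b)
})

test_that("rigid motion of all models leaves densities and SDE unchanged", {
  set.seed(12)
  st <- toy_structure(matrix(rnorm(90, sd = 2), ncol = 3), n_models = 3,
                      jitter = 0.05, compartment = rep(c("A", "B"), 15))
  qc <- qc_structure(st)
  trk <- rpois(30, 2)
  r1 <- spatial_density(st, qc, trk)
  s1 <- sde(st, qc, trk, n_perm = 10, seed = 3)
  rot <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(rot) < 0) rot[, 1] <- -rot[, 1]
  st2 <- st
  for (m in 1:3)
    st2$coords[, , m] <- st$coords[, , m] %*% rot +
      matrix(c(5, -2, 1), 30, 3, byrow = TRUE)
  qc2 <- qc_structure(st2)
  expect_equal(spatial_density(st2, qc2, trk), r1, tolerance = 1e-9)
  s2 <- sde(st2, qc2, trk, n_perm = 10, seed = 3)
  expect_equal(s2$sde, s1$sde, tolerance = 1e-9)
})

test_that("z-normalization standardizes on the low-density quartile", {
  x <- c(rnorm(25, 5, 2), rnorm(75, 0, 1))
  track <- c(rep(0, 25), rep(10, 75))  # first 25 are the reference
  z <- z_normalize_sde(x, track)
  ref <- x[1:25]
  expect_equal(z, (x - mean(ref)) / sd(ref), tolerance = 1e-12)
  # the reference mean shifts with the data, so a constant offset
  # cancels; a rescaling cancels too
  expect_equal(z_normalize_sde(x + 3, track), z, tolerance = 1e-12)
  expect_equal(z_normalize_sde(x * 2, track), z, tolerance = 1e-12)
  expect_error(z_normalize_sde(rep(1, 100), track), "zero variance")
  expect_error(z_normalize_sde(x[1:5], track[1:5]), "at least 8")
})

test_that("crowding strata are equal-sized within compartments", {
  n <- 40
  st <- toy_structure(matrix(rnorm(n * 3, sd = 2), ncol = 3),
                      n_models = 2, jitter = 0,
                      compartment = rep("A", n))
  qc <- qc_structure(st)
  cp <- consistent_pairs(st, qc, 3)
  tab <- data.frame(tf = "X", particle = rep(seq_len(n), each = 5))
  tab$chrom <- st$particles$chrom[tab$particle]
  tab$compartment <- st$compartment[tab$particle]
  strat <- crowding_strata(tab, cp, n_groups = 5)
  expect_equal(unname(table(strat$stratum)), rep(40L, 5),
               ignore_attr = TRUE)
  # remainder spreads over the lowest strata
  strat2 <- crowding_strata(tab[1:23, ], cp, n_groups = 5)
  expect_equal(as.integer(table(strat2$stratum)), c(5L, 5L, 5L, 4L, 4L))
})

test_that("PE follows log2(Obs/Exp) and its p-value smoothing", {
  # hand-built strata where permutation cannot change anything: Exp = Obs
  n <- 10
  xyz <- line_coords(n)
  xyz[8, ] <- xyz[1, ] + c(0.4, 0, 0)
  st <- toy_structure(xyz, n_models = 2, jitter = 0,
                      compartment = rep("A", n))
  qc <- qc_structure(st)
  cp <- consistent_pairs(st, qc, 3)
  tab <- data.frame(tf = c("A", "B"), particle = c(1L, 8L))
  tab$chrom <- st$particles$chrom[tab$particle]
  tab$compartment <- st$compartment[tab$particle]
  strat <- crowding_strata(tab, cp, n_groups = 5)
  # each site alone in its stratum cell: permutations are no-ops
  res <- pe_score(strat, "A", "B", cp, n_perm = 50, seed = 1)
  expect_equal(res$obs, 1)
  expect_equal(res$exp, 1)
  expect_equal(res$pe, 0)
  expect_equal(res$p, 1)
})

test_that("planted structure clusters give positive significant PE", {
  tfspec <- data.frame(tf_id = c("P1", "P2", "Q1", "Q2"), n_sites = 60L,
                       occupancy_target = 1, compartment_bias = 0)
  spec <- synthetic_spec(seed = 41, chrom_length = 8e6, n_chroms = 2,
                         tf_specs = tfspec, cluster_frac = 0.8,
                         planted_clusters = list(c("P1", "P2")))
  st <- make_structure(spec)
  qc <- qc_structure(st$structure)
  cp <- consistent_pairs(st$structure, qc, 3)
  tab <- structure_site_table(st$sites, st$structure)
  strat <- crowding_strata(tab, cp)
  planted <- pe_score(strat, "P1", "P2", cp, n_perm = 100, seed = 5)
  unrelated <- pe_score(strat, "Q1", "Q2", cp, n_perm = 100, seed = 5)
  expect_gt(planted$pe, 0)
  expect_lte(planted$p, 0.05)
  expect_gt(planted$pe, unrelated$pe)
})

test_that("pe_matrix recovers planted groups and validates trans mode", {
  grp1 <- paste0("G1_", 1:4)
  grp2 <- paste0("G2_", 1:4)
  tfspec <- data.frame(tf_id = c(grp1, grp2), n_sites = 60L,
                       occupancy_target = 1, compartment_bias = 0)
  spec <- synthetic_spec(seed = 19, chrom_length = 8e6, n_chroms = 2,
                         tf_specs = tfspec, cluster_frac = 0.8,
                         planted_clusters = list(grp1, grp2))
  st <- make_structure(spec)
  qc <- qc_structure(st$structure)
  pm <- pe_matrix(st$sites, st$structure, qc, threshold = 3,
                  n_perm = 60, seed = 3)
  expect_true(isSymmetric(unname(pm$pe)))
  expect_equal(rand_index_adj(pm$clusters$labels, rep(1:2, each = 4)), 1)
  # single-chromosome structure has no trans pairs
  spec1 <- synthetic_spec(seed = 19, chrom_length = 4e6, n_chroms = 1,
                          tf_specs = tfspec)
  st1 <- make_structure(spec1)
  expect_error(pe_matrix(st1$sites, st1$structure, threshold = 3,
                         mode = "trans"), "no trans")
})
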