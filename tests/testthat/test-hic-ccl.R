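# Expected profiles, coverage filtering, adaptive bin merging and CCL
# scoring against brute-force oracles.

test_that("low-coverage masking follows the strict one-third rule", {
  # three bins with controlled raw totals: per-bin totals are engineered
  # through the diagonal-free entries
  m <- contact_map("chrT", 5000,
                   bin_i = c(0L, 0L, 1L), bin_j = c(1L, 2L, 2L),
                   normalized = c(10, 1, 23),
                   raw = c(10, 1, 23), n_bins = 3)
  # bin totals: 11, 33, 24; median over nonzero = 24; threshold 8
  expect_equal(m$bin_raw_total, c(11, 33, 24))
  f <- filter_low_coverage(m, 1 / 3)
  expect_true(all(f$mask))
  # a bin strictly below fraction * median is masked, at the boundary kept
  m2 <- contact_map("chrT", 5000,
                    bin_i = c(0L, 1L, 2L), bin_j = c(1L, 2L, 3L),
                    normalized = c(5, 28, 5), raw = c(5, 28, 5), n_bins = 4)
  # totals 5, 33, 33, 5; median 19; third = 6.33: bins 1 and 4 masked
  f2 <- filter_low_coverage(m2, 1 / 3)
  expect_equal(f2$mask, c(FALSE, TRUE, TRUE, FALSE))
  # boundary: total exactly at fraction * median is retained
  m3 <- m2
  m3$bin_raw_total <- c(11, 33, 33, 33)
  f3 <- filter_low_coverage(m3, 1 / 3)
  expect_equal(f3$mask, c(TRUE, TRUE, TRUE, TRUE))
})

test_that("uniform maps mask nothing and give a constant profile", {
  n <- 12
  up <- which(upper.tri(diag(n)), arr.ind = TRUE)
  m <- contact_map("chrT", 5000, up[, 1] - 1L, up[, 2] - 1L,
                   rep(7, nrow(up)), raw = rep(50, nrow(up)), n_bins = n)
  f <- filter_low_coverage(m)
  expect_true(all(f$mask))
  pr <- expected_profile(f)
  expect_true(all(abs(pr$values[-1] - 7) < 1e-12))
})

test_that("expected profile matches the brute-force average", {
  m <- toy_map(n_bins = 20, seed = 42)
  m$mask[c(3, 11)] <- FALSE
  pr <- expected_profile(m)
  expect_equal(pr$values, oracle_profile(m), tolerance = 1e-12)
  # separations inside the excluded diagonal band are still computed
  expect_false(is.na(pr$values[2]))
})

test_that("merged bin size follows the separation rules", {
  cfg <- ccl_config()
  m <- toy_map(n_bins = 450)
  pr <- expected_profile(m)
  # 50 kb apart: base 5-kb bins (window half-width 0)
  eb <- effective_bin(m, pr, 100000, 150000, cfg)
  expect_equal(eb$obs, m$norm[21, 31])
  # 150 kb apart: 25-kb window = 5 x 5 base bins
  eb2 <- effective_bin(m, pr, 100000, 250000, cfg)
  expect_equal(eb2$obs, sum(m$norm[19:23, 49:53]))
  # 2 Mb apart: 55-kb window = 11 x 11 base bins
  eb3 <- effective_bin(m, pr, 100000, 2100000, cfg)
  expect_equal(eb3$obs, sum(m$norm[16:26, 416:426]))
  # inside the excluded band: error
  expect_error(effective_bin(m, pr, 100000, 125000, cfg), "excluded band")
})

test_that("obs/exp is one on a flat map at every merge level", {
  n <- 450
  up <- which(upper.tri(diag(n)), arr.ind = TRUE)
  m <- contact_map("chrT", 5000, up[, 1] - 1L, up[, 2] - 1L,
                   rep(3, nrow(up)), raw = rep(100, nrow(up)), n_bins = n)
  pr <- expected_profile(m)
  for (lj in c(150000, 400000, 2100000)) {
    eb <- effective_bin(m, pr, 100000, lj)
    expect_equal(eb$obs / eb$exp, 1, tolerance = 1e-12)
  }
})

test_that("masked windows invalidate pairs", {
  m <- toy_map(n_bins = 100)
  m$mask[50] <- FALSE
  pr <- expected_profile(m)
  # 25-kb window around bin 49 (0-based 48) touches masked bin 49
  eb <- effective_bin(m, pr, 245000, 100000)
  expect_false(eb$valid)
  # distant window untouched by the mask stays valid
  eb2 <- effective_bin(m, pr, 400000, 100000)
  expect_true(eb2$valid)
})

test_that("single-pair CCL equals ln(obs/exp) and ln 2 when obs = 2 exp", {
  n <- 60
  up <- which(upper.tri(diag(n)), arr.ind = TRUE)
  norm <- rep(5, nrow(up))
  m <- contact_map("chrT", 5000, up[, 1] - 1L, up[, 2] - 1L, norm,
                   raw = rep(100, nrow(up)), n_bins = n)
  pr <- expected_profile(m)
  # double the single consumed 5-kb pair (bins 10 and 20, 50 kb apart);
  # the profile is unaffected enough to keep exp near 5
  m2 <- m
  m2$norm[11, 21] <- m2$norm[21, 11] <- 10
  pr2 <- expected_profile(m)  # exp from the flat map
  q <- toy_sites(10L, "A")
  b <- toy_sites(20L, "A2")
  res <- ccl_heterotypic(q, b, m2, pr2)
  expect_equal(res$n_pairs, 1L)
  expect_equal(res$ccl, log(2), tolerance = 1e-12)
  # obs = exp everywhere gives CCL 0
  res0 <- ccl_heterotypic(q, b, m, pr)
  expect_equal(res0$ccl, 0, tolerance = 1e-12)
})

test_that("homotypic and heterotypic CCL match the brute-force oracle", {
  set.seed(7)
  m <- toy_map(n_bins = 260, seed = 11)
  m <- filter_low_coverage(m)
  pr <- expected_profile(m)
  qbins <- sort(sample(0:259, 25))
  pbins <- sort(sample(0:259, 20))
  q <- toy_sites(qbins, "A")
  p <- toy_sites(pbins, "B")
  res <- ccl_heterotypic(q, p, m, pr)
  ora <- oracle_ccl(site_center(q$start, q$end),
                    site_center(p$start, p$end), m, oracle_profile(m))
  expect_equal(res$ccl, ora, tolerance = 1e-12)
  # homotypic: same TF, partner set equals query set (self excluded by
  # the same-bin rule)
  resh <- ccl_homotypic(q, q, m, pr)
  orah <- oracle_ccl(site_center(q$start, q$end),
                     site_center(q$start, q$end), m, oracle_profile(m))
  expect_equal(resh$ccl, orah, tolerance = 1e-12)
})

test_that("pairs without more than 20 raw reads are excluded", {
  n <- 60
  up <- which(upper.tri(diag(n)), arr.ind = TRUE)
  m <- contact_map("chrT", 5000, up[, 1] - 1L, up[, 2] - 1L,
                   rep(5, nrow(up)), raw = rep(100, nrow(up)), n_bins = n)
  pr <- expected_profile(m)
  q <- toy_sites(10L, "A"); b <- toy_sites(20L, "B")
  for (raw_val in c(15, 20, 21)) {
    m$raw[11, 21] <- m$raw[21, 11] <- raw_val
    res <- ccl_heterotypic(q, b, m, pr)
    expect_equal(res$n_pairs, if (raw_val > 20) 1L else 0L)
  }
})

test_that("CCL is invariant to rescaling the normalized counts", {
  m <- toy_map(n_bins = 150, seed = 3)
  pr <- expected_profile(m)
  q <- toy_sites(c(5L, 40L, 90L), "A")
  b <- toy_sites(c(20L, 70L, 120L), "B")
  r1 <- ccl_heterotypic(q, b, m, pr)
  m2 <- m
  m2$norm <- m$norm * 13.7
  r2 <- ccl_heterotypic(q, b, m2, expected_profile(m2))
  expect_equal(r2$ccl, r1$ccl, tolerance = 1e-9)
})

test_that("no consumed pair sits within 25 kb of the diagonal", {
  m <- toy_map(n_bins = 40)
  pr <- expected_profile(m)
  # sites 5 bins apart (25 kb): excluded; 6 bins (30 kb): consumed
  q <- toy_sites(10L, "A")
  expect_equal(ccl_heterotypic(q, toy_sites(15L, "B"), m, pr)$n_pairs, 0L)
  expect_equal(ccl_heterotypic(q, toy_sites(16L, "B"), m, pr)$n_pairs, 1L)
})

test_that("integrated scores add across the partner group", {
  m <- toy_map(n_bins = 200, seed = 5)
  pr <- expected_profile(m)
  a <- toy_sites(c(10L, 60L), "A")
  b <- toy_sites(c(30L, 100L), "B")
  cc <- toy_sites(c(50L, 150L), "C")
  hb <- ccl_heterotypic(a, b, m, pr)
  hc <- ccl_heterotypic(a, cc, m, pr)
  int1 <- ccl_integrated(a, list(b, cc), m, pr)
  expect_equal(int1$ccl, hb$ccl + hc$ccl, tolerance = 1e-12)
  # order of the group does not matter
  int2 <- ccl_integrated(a, list(cc, b), m, pr)
  expect_equal(int2$ccl, int1$ccl)
  # singleton group reduces to the heterotypic score
  expect_equal(ccl_integrated(a, list(b), m, pr)$ccl, hb$ccl)
  expect_error(ccl_integrated(a, list(), m, pr), "empty")
})

test_that("rank normalization groups scores as quantiles", {
  r <- rank_normalize(c(1, 2, 3, 4), 2)
  expect_equal(r$group, c(0L, 0L, 1L, 1L))
  # ties collapse to one average rank
  r2 <- rank_normalize(rep(5, 10), 2)
  expect_equal(length(unique(r2$rank)), 1)
  expect_equal(length(unique(r2$group)), 1)
  # 100 distinct scores split 10 per decile
  r3 <- rank_normalize(sample(seq_len(100)), 10)
  expect_equal(unname(table(r3$group)), rep(10L, 10), ignore_attr = TRUE)
  expect_error(rank_normalize(c(1, 2), 3), "groups")
})
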