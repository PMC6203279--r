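# Putative-site construction, marker categorization, linear density and
# conservation mapping.

test_that("putative sites need a passing p-value and a DHS center", {
  mm <- site_set(data.frame(
    chrom = "chr1",
    start = c(1000L, 2000L, 3000L, 4000L),
    end = c(1012L, 2012L, 3012L, 4012L),
    motif_pvalue = c(5e-5, 5e-5, 2e-4, 1e-6)), "TF")
  dhs <- data.frame(chrom = "chr1", start = c(900L, 2900L),
                    end = c(1100L, 3100L))
  ps <- putative_sites(mm, dhs, 1e-4)
  # 1000: p ok, in DHS -> kept; 2000: p ok, outside -> dropped;
  # 3000: p too large -> dropped; 4000: p ok, outside -> dropped
  expect_equal(ps$start, 1000L)
  expect_false(any(ps$bound))
  # empty DHS set drops everything
  expect_equal(nrow(putative_sites(mm, dhs[0, ], 1e-4)), 0)
  # missing p-values are an error
  mm2 <- site_set(data.frame(chrom = "chr1", start = 1L, end = 12L), "TF")
  expect_error(putative_sites(mm2, dhs), "motif_pvalue")
})

test_that("peaks map to their best-scoring overlapping motif", {
  peaks <- site_set(data.frame(chrom = "chr1", start = c(100L, 900L),
                               end = c(300L, 950L),
                               signal_value = c(7, 3)), "TF")
  mm <- site_set(data.frame(
    chrom = "chr1",
    start = c(120L, 200L, 2000L),
    end = c(132L, 212L, 2012L),
    motif_pvalue = c(1e-5, 1e-6, 1e-9)), "TF")
  res <- map_peaks_to_motifs(peaks, mm)
  # first peak takes the 1e-6 match; second overlaps nothing
  expect_equal(nrow(res), 1)
  expect_equal(res$start, 200L)
  expect_equal(res$signal_value, 7)
  expect_true(res$bound)
  # equal p-values: leftmost match wins
  mm2 <- site_set(data.frame(chrom = "chr1", start = c(120L, 200L),
                             end = c(132L, 212L),
                             motif_pvalue = 1e-5), "TF")
  expect_equal(map_peaks_to_motifs(peaks, mm2)$start, 120L)
})

make_marks <- function() {
  iv <- function(s, e) data.frame(chrom = "chr1", start = s, end = e)
  list(H3K4me1 = iv(5000, 6000),
       H3K4me3 = iv(c(900, 1900), c(1100, 2100)),
       H3K27ac = iv(c(900, 1900, 5000, 7000), c(1100, 2100, 6000, 7100)),
       H3K27me3 = iv(c(5500, 7000), c(6500, 7100)),
       H3K9me = iv(8000, 8100),
       H3K9ac = iv(8000, 8100),
       H3K36me3 = iv(1500, 1900))
}

test_that("marker categorization implements the promoter/enhancer rules", {
  marks <- make_marks()
  tss <- data.frame(chrom = "chr1", pos = c(2000L, 3000L), strand = "+")
  state <- data.frame(chrom = "chr1", start = 4800L, end = 6200L)
  meth <- data.frame(chrom = "chr1", start = 9000L, end = 9200L)
  sites <- site_set(data.frame(
    chrom = "chr1",
    start = c(1000L, 2900L, 5000L, 5600L, 7000L, 8050L, 9100L, 400L),
    end = c(1020L, 2920L, 5020L, 5620L, 7020L, 8070L, 9120L, 420L)), "TF")
  lab <- categorize_sites(sites, marks, tss, state, meth)
  # 1000: upstream of TSS 2000, H3K4me3+H3K27ac, H3K36me3 (1500-1900)
  # overlaps the TSS +/- 1000 window by 400 bp -> strong promoter
  expect_equal(lab[sites$start == 1000], "strong_promoter")
  # 2900: upstream of TSS 3000 but no H3K4me3 at center -> other
  expect_equal(lab[sites$start == 2900], "other")
  # 5000: state enhancer, H3K4me1 + H3K27ac -> active
  expect_equal(lab[sites$start == 5000], "active_enhancer")
  # 5600: in H3K27ac? no (ac ends 6000? 5600 is inside 5000-6000) ->
  # ambiguous: H3K27ac and H3K27me3 both cover 5600
  expect_equal(lab[sites$start == 5600], "excluded_ambiguous")
  # 7000: H3K27ac + H3K27me3 -> ambiguous
  expect_equal(lab[sites$start == 7000], "excluded_ambiguous")
  # 8050: H3K9ac + H3K9me -> ambiguous
  expect_equal(lab[sites$start == 8050], "excluded_ambiguous")
  # 9100: methylated region
  expect_equal(lab[sites$start == 9100], "excluded_methylated")
  # 400: nothing applies
  expect_equal(lab[sites$start == 400], "other")
  expect_error(categorize_sites(sites, marks[-3], tss, state, meth),
               "H3K27ac")
})

test_that("inactive enhancers need H3K27me3 without H3K27ac", {
  marks <- make_marks()
  marks$H3K27ac <- data.frame(chrom = "chr1", start = 1L, end = 2L)
  tss <- data.frame(chrom = "chr1", pos = 99000L)
  state <- data.frame(chrom = "chr1", start = 4800L, end = 6200L)
  sites <- site_set(data.frame(chrom = "chr1", start = 5600L,
                               end = 5620L), "TF")
  expect_equal(categorize_sites(sites, marks, tss, state),
               "inactive_enhancer")
})

test_that("promoter windows honor gene strand", {
  marks <- make_marks()
  marks$H3K4me3 <- data.frame(chrom = "chr1", start = 2050, end = 3000)
  marks$H3K27ac <- marks$H3K4me3
  marks$H3K36me3 <- data.frame(chrom = "chr1", start = 90000, end = 91000)
  state <- data.frame(chrom = "chr1", start = 1, end = 2)
  # minus-strand gene: upstream is to the right of the TSS
  tss <- data.frame(chrom = "chr1", pos = 2000L, strand = "-")
  sites <- site_set(data.frame(chrom = "chr1", start = 2100L,
                               end = 2120L), "TF")
  expect_equal(categorize_sites(sites, marks, tss, state),
               "weak_promoter")
  tss$strand <- "+"
  expect_equal(categorize_sites(sites, marks, tss, state), "other")
})

test_that("flank-based structure categories follow the mark logic", {
  marks <- list(H3K4me1 = data.frame(chrom = "c", start = 10000,
                                     end = 10500),
                H3K4me3 = data.frame(chrom = "c", start = 30000,
                                     end = 30500))
  tss <- data.frame(chrom = "c", pos = 30100L)
  mk <- function(s) site_set(data.frame(chrom = "c", start = s,
                                        end = s + 20L), "TF")
  expect_equal(categorize_structure_flanks(mk(10800L), marks, tss),
               "enhancer")
  expect_equal(categorize_structure_flanks(mk(29500L), marks, tss),
               "promoter")
  # both marks in the flank: neither rule fires
  marks$H3K4me3 <- rbind(marks$H3K4me3,
                         data.frame(chrom = "c", start = 10000,
                                    end = 10500))
  expect_equal(categorize_structure_flanks(mk(10800L), marks, tss),
               "other")
})

test_that("linear density spreads each site by window overlap", {
  mk <- function(ctr) site_set(data.frame(chrom = "chr1",
                                          start = ctr - 10L,
                                          end = ctr + 10L), "TF")
  # site at a region center: full weight to that region
  tr <- linear_density(mk(150000L), region_size = 1e5)
  expect_equal(tr$value[tr$start == 1e5], 1.0)
  # site on a region boundary: half weight each side
  tr2 <- linear_density(mk(100000L), region_size = 1e5)
  expect_equal(tr2$value[tr2$start == 0], 0.5)
  expect_equal(tr2$value[tr2$start == 1e5], 0.5)
  # site 25 kb left of a boundary: 0.75 / 0.25 split
  tr3 <- linear_density(mk(175000L), region_size = 1e5)
  expect_equal(tr3$value[tr3$start == 1e5], 0.75)
  expect_equal(tr3$value[tr3$start == 2e5], 0.25)
})

test_that("linear density conserves total site mass for interior sites", {
  set.seed(4)
  ctr <- sample(200000:800000, 40)
  ss <- site_set(data.frame(chrom = "chr1", start = ctr - 5L,
                            end = ctr + 5L), "TF")
  tr <- linear_density(ss, region_size = 1e5)
  expect_equal(sum(tr$value), 40, tolerance = 1e-12)
})

test_that("conservation uses the strict 300-bp center rule", {
  a <- site_set(data.frame(chrom = "chr1",
                           start = c(1000L, 5000L, 9000L),
                           end = c(1400L, 5400L, 9400L)), "TF", "lineA")
  # centers at 1200, 5200, 9200
  b <- site_set(data.frame(chrom = "chr1",
                           start = c(1100L, 5350L),
                           end = c(1700L, 5950L)), "TF", "lineB")
  # centers at 1400 (dist 200, overlaps 1200) and 5650 (dist 450)
  res <- conservation_map(a, b, 300)
  expect_equal(res$matches$conserved, c(TRUE, FALSE, FALSE))
  expect_equal(res$fraction, 1 / 3)
  # empty partner set: zero conserved fraction
  expect_equal(conservation_map(a, b[0, ])$fraction, 0)
  # nearest center wins among several qualifying matches
  b3 <- site_set(data.frame(chrom = "chr1", start = c(1140L, 1100L),
                            end = c(1360L, 1500L)), "TF")
  # centers 1250 (dist 50) and 1300 (dist 100)
  res3 <- conservation_map(a, b3, 300)
  expect_equal(res3$matches$match[1], which(b3$start == 1140L))
})
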