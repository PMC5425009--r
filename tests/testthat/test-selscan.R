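test_that("Weir-Cockerham components match hand-evaluated values", {
  # fixed difference, 3 vs 3 diploids
  fixed <- wc_fst_site(c(3, 0, 0), c(0, 0, 3))
  expect_equal(fixed$fst, 1, tolerance = 1e-12)

  # A: (1 hom-ref, 1 het, 1 hom-alt), B: (3 hom-ref, 0, 0); evaluating the
  # two-population formulas by hand gives a = b = c = 1/12, ratio 1/3
  mixed <- wc_fst_site(c(1, 1, 1), c(3, 0, 0))
  expect_equal(mixed$a, 1 / 12, tolerance = 1e-12)
  expect_equal(mixed$b, 1 / 12, tolerance = 1e-12)
  expect_equal(mixed$c, 1 / 12, tolerance = 1e-12)
  expect_equal(mixed$fst, 1 / 3, tolerance = 1e-12)

  # identical genotype counts in both groups: no differentiation, raw
  # estimate non-positive
  same <- wc_fst_site(c(1, 1, 1), c(1, 1, 1))
  expect_lte(same$fst, 0)

  # monomorphic across both groups: all components zero, ratio undefined
  mono <- wc_fst_site(c(3, 0, 0), c(3, 0, 0))
  expect_equal(mono$a + mono$b + mono$c, 0)
  expect_true(is.na(mono$fst))
})

test_that("per-site scan flags monomorphic sites and respects the estimator flag", {
  a <- toy_matrix(rbind(c(0L, 0L, 2L), c(0L, 1L, 2L), c(0L, 2L, 2L)))
  b <- toy_matrix(rbind(c(0L, 0L, 0L), c(0L, 0L, 0L), c(0L, 0L, 0L)))
  fs <- fst_scan(a, b)
  expect_true(fs$monomorphic[1])
  expect_true(is.na(fs$fst[1]))
  expect_equal(fs$fst[2], 1 / 3, tolerance = 1e-12)
  expect_equal(fs$fst[3], 1, tolerance = 1e-12)

  hs <- fst_scan(a, b, estimator = "hudson")
  expect_equal(hs$fst[3], 1, tolerance = 1e-12)  # fixed difference
})

test_that("window grid enumerates starts by the stated rule", {
  sites <- data.frame(chrom = "1", pos = c(5000L, 25000L),
                      den = c(1, 1), num = c(0.5, 0.5), fst = c(0.5, 0.5))
  w <- window_fst(sites, c("1" = 150000), window = 100000, step = 10000,
                  min_snps = 1)
  expect_identical(nrow(w), 15L)                 # starts 0, 10k, ..., 140k
  expect_identical(w$start, seq(0, 140000, by = 10000))
  expect_identical(w$end[15], 150000)            # truncated at chrom end

  expect_error(window_fst(sites, c("2" = 1e6)), "missing from")
})

test_that("window F_st is a ratio of sums with single-site consistency", {
  a <- toy_matrix(rbind(c(0L, 0L), c(0L, 1L), c(0L, 1L)),
                  pos = c(1000L, 3000L))
  b <- toy_matrix(rbind(c(2L, 0L), c(2L, 0L), c(2L, 0L)),
                  pos = c(1000L, 3000L))
  fs <- fst_scan(a, b)
  # one-site window: ratio-of-sums equals the per-site ratio
  w1 <- window_fst(fs, c("1" = 4000), window = 2000, step = 2000,
                   min_snps = 1)
  expect_equal(w1$fst_raw[1], fs$fst[1], tolerance = 1e-12)
  # two-site window: sum(a) / sum(a+b+c), not the mean of ratios
  w2 <- window_fst(fs, c("1" = 4000), window = 4000, step = 4000,
                   min_snps = 1)
  expect_equal(w2$fst_raw[1], sum(fs$num) / sum(fs$den), tolerance = 1e-12)
  wm <- window_fst(fs, c("1" = 4000), window = 4000, step = 4000,
                   min_snps = 1, per_site_mean = TRUE)
  expect_equal(wm$fst_raw[1], mean(fs$fst), tolerance = 1e-12)
})

test_that("all-fixed-difference windows reach 1 and empty chromosomes drop out", {
  cfg <- small_backcross_config()
  pan <- simulate_divergent_panels(cfg)
  fs <- fst_scan(pan$poly, pan$normal)
  swp <- fs$chrom == cfg$causal_chrom &
    abs(fs$pos - cfg$causal_pos) <= cfg$sweep_halfwidth
  w <- window_fst(fs, cfg$chrom_lengths, min_snps = 1)
  full <- w$chrom == cfg$causal_chrom &
    w$start >= cfg$causal_pos - cfg$sweep_halfwidth &
    w$end <= cfg$causal_pos + cfg$sweep_halfwidth & w$n_snps > 0
  expect_true(all(w$fst[full] == 1))

  empty <- data.frame(chrom = character(), pos = integer(),
                      num = numeric(), den = numeric(), fst = numeric())
  we <- window_fst(empty, c("7" = 50000))
  expect_true(all(we$n_snps == 0))
  expect_true(all(!we$qualifies))
})

test_that("the outlier threshold is the lower bound of the top fraction", {
  w <- data.frame(chrom = "1", start = 0:999 * 10000,
                  end = 0:999 * 10000 + 100000, n_snps = 20,
                  fst = 0.001 * (1:1000), qualifies = TRUE)
  ot <- outlier_threshold(w, top_fraction = 0.001)
  expect_equal(ot$threshold, 1.000)       # ceil(0.001 * 1000) = 1 window
  expect_identical(nrow(ot$outliers), 1L)

  w5 <- w[1:5, ]
  ot5 <- outlier_threshold(w5, top_fraction = 0.001)
  expect_equal(ot5$threshold, max(w5$fst))  # ceil(0.005) = 1 -> the max

  weq <- data.frame(chrom = "1", start = 0, end = 1, n_snps = 20,
                    fst = rep(0.4, 2000), qualifies = TRUE)
  expect_warning(oteq <- outlier_threshold(weq), "degenerate")
  expect_equal(oteq$threshold, 0.4)
  expect_identical(nrow(oteq$outliers), 2000L)
  expect_true(oteq$degenerate)
})

test_that("outlier windows merge into maximal regions", {
  w <- data.frame(chrom = c("1", "1"), start = c(8300000, 8350000),
                  end = c(8400000, 8450000), fst = c(0.9, 0.95))
  m <- merge_outliers(w)
  expect_identical(nrow(m), 1L)
  expect_identical(m$start, 8300000)
  expect_identical(m$end, 8450000)
  expect_equal(m$peak_fst, 0.95)

  w2 <- data.frame(chrom = c("1", "2"), start = c(0, 0),
                   end = c(100000, 100000), fst = c(0.8, 0.9))
  expect_identical(nrow(merge_outliers(w2)), 2L)

  # 31 step-adjacent 100 kb windows at 10 kb step span 400 kb when merged
  chain <- data.frame(chrom = "1", start = (0:30) * 10000,
                      end = (0:30) * 10000 + 100000, fst = 1)
  mc <- merge_outliers(chain)
  expect_identical(nrow(mc), 1L)
  expect_identical(mc$end - mc$start, 400000)
  expect_identical(mc$n_windows, 31L)
})

test_that("opposite homozygotes require complete fixed differences", {
  a <- toy_matrix(rbind(c(0L, 0L, 2L), c(0L, 1L, 2L), c(0L, 0L, 2L)))
  b <- toy_matrix(rbind(c(2L, 0L, 0L), c(2L, 0L, 0L), c(2L, 0L, 0L)))
  oh <- opposite_homozygotes(a, b)
  expect_identical(oh$id, c("s1", "s3"))   # s2 has a het in group A
  expect_identical(oh$allele_a[1], "A")
  expect_identical(oh$allele_b[1], "T")

  # missing call: disqualifies under require_complete, tolerated otherwise
  am <- toy_matrix(rbind(c(0L), c(NA_integer_), c(0L)))
  bm <- toy_matrix(rbind(c(2L), c(2L), c(2L)))
  expect_identical(nrow(opposite_homozygotes(am, bm)), 0L)
  expect_identical(nrow(opposite_homozygotes(am, bm,
                                             require_complete = FALSE)), 1L)
})

test_that("opposite-homozygote scan matches a brute-force per-site check", {
  set.seed(19)
  n <- 4
  m <- 10
  codes_a <- matrix(sample(0:2, n * m, replace = TRUE), n, m)
  codes_b <- matrix(sample(0:2, n * m, replace = TRUE), n, m)
  # engineer three opposite-homozygous sites
  codes_a[, c(2, 5, 9)] <- 0L
  codes_b[, c(2, 5)] <- 2L
  codes_a[, 9] <- 2L
  codes_b[, 9] <- 0L
  # and spoil any accidental ones deterministically via the oracle below
  a <- toy_matrix(codes_a)
  b <- toy_matrix(codes_b)
  oracle <- vapply(seq_len(m), function(j) {
    ga <- codes_a[, j]; gb <- codes_b[, j]
    (all(ga == 0) && all(gb == 2)) || (all(ga == 2) && all(gb == 0))
  }, logical(1))
  oh <- opposite_homozygotes(a, b)
  expect_identical(oh$id, a$sites$id[oracle])
  expect_true(all(c("s2", "s5", "s9") %in% oh$id))
})

test_that("per-chromosome densities rank short dense chromosomes first", {
  d <- chrom_density(c("1" = 100, "2" = 100),
                     c("1" = 20e6, "2" = 10e6))
  expect_identical(d$chrom[1], "2")
  expect_equal(d$density, c(10, 5))

  z <- chrom_density(character(0), c("1" = 1e6))
  expect_equal(z$density, 0)
  expect_error(chrom_density(c("77" = 5), c("1" = 1e6)), "77")
})

test_that("the sweep chromosome carries the highest opposite-homozygote density", {
  cfg <- sim_config(n_sites_per_chrom = 300L, seed = 2)
  pan <- simulate_divergent_panels(cfg)
  oh <- opposite_homozygotes(pan$poly, pan$normal)
  snp_d <- chrom_density(oh$chrom[oh$vtype == "SNP"], cfg$chrom_lengths)
  expect_identical(snp_d$chrom[1], cfg$causal_chrom)
  expect_gt(snp_d$count[1], 0)
})
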