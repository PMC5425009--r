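
test_that("logistic odds ratio equals the 2x2 contingency odds ratio", {
  d <- make_2x2_matrix(30, 10, 10, 30)
  res <- logistic_assoc(d$gm, d$y)
  expect_equal(res$or_, (30 * 30) / (10 * 10), tolerance = 1e-8)
  expect_false(res$firth_used)
  expect_true(res$converged)
})

test_that("logistic OR matches the sample OR across many non-degenerate tables", {
  # exhaustive sweep over small tables, plus random larger ones up to n = 40
  tabs <- list()
  for (n in 4:12) {
    parts <- expand.grid(a = 1:n, b = 1:n, c = 1:n)
    parts <- parts[parts$a + parts$b + parts$c <= n - 1, ]
    for (r in seq_len(nrow(parts))) {
      tabs[[length(tabs) + 1]] <-
        c(parts$a[r], parts$b[r], parts$c[r],
          n - parts$a[r] - parts$b[r] - parts$c[r])
    }
  }
  set.seed(1)
  for (i in 1:150) {
    repeat {
      t4 <- as.vector(stats::rmultinom(1, sample(8:40, 1), rep(0.25, 4)))
      if (all(t4 >= 1)) break
    }
    tabs[[length(tabs) + 1]] <- t4
  }
  for (t4 in tabs) {
    d <- make_2x2_matrix(t4[1], t4[2], t4[3], t4[4])
    res <- logistic_assoc(d$gm, d$y)
    expect_equal(res$or_, (t4[1] * t4[4]) / (t4[2] * t4[3]),
                 tolerance = 1e-6)
  }
})

test_that("null sites give small effects and uniform p-values", {
  set.seed(30)
  n <- 200
  m <- 250
  codes <- sapply(seq_len(m), function(j) rbinom(n, 2, runif(1, 0.2, 0.8)))
  gm <- toy_matrix(codes)
  y <- rbinom(n, 1, 0.4)
  res <- logistic_assoc(gm, y)
  expect_lt(mean(abs(res$beta), na.rm = TRUE), 0.3)
  ks <- stats::ks.test(stats::na.omit(res$p_logistic), "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("perfect separation triggers a finite Firth fit", {
  d <- make_2x2_matrix(20, 0, 0, 20)  # all cases carriers, all controls not
  res <- logistic_assoc(d$gm, d$y)
  expect_true(res$firth_used)
  expect_true(is.finite(res$beta))
  expect_true(res$converged)
  expect_lt(res$p_logistic, 1e-8)
  expect_gt(res$beta, 0)
})

test_that("constant phenotypes and misaligned covariates are rejected", {
  gm <- toy_matrix(cbind(c(0L, 1L, 2L, 1L)))
  expect_error(logistic_assoc(gm, rep(1L, 4)), "constant")
  expect_error(logistic_assoc(gm, c(0L, 1L, 0L, 1L),
                              covariates = matrix(0, 2, 1)), "mismatch")
})

test_that("GRM matches direct evaluation of the standardized-dosage formula", {
  gm <- toy_matrix(rbind(c(0L, 2L), c(2L, 0L)))
  G <- compute_grm(gm)
  # p = (0.5, 0.5); z = (x - 1) / sqrt(0.5); G = ZZ'/2
  expect_equal(unname(G), rbind(c(2, -2), c(-2, 2)), tolerance = 1e-12)

  expect_error(compute_grm(toy_matrix(cbind(c(0L, 0L), c(2L, 2L)))),
               "polymorphic")
})

test_that("GRM of an unstructured population standardizes correctly", {
  set.seed(41)
  n <- 100
  m <- 10000
  codes <- sapply(seq_len(m), function(j) rbinom(n, 2, runif(1, 0.1, 0.9)))
  G <- compute_grm(toy_matrix(codes))
  off <- G[upper.tri(G)]
  expect_lt(abs(mean(off)), 3 / sqrt(m) + 1 / (n - 1))
  expect_lt(abs(mean(diag(G)) - 1), 0.05)
})

test_that("REML finds no genetic variance in pure noise", {
  # the null ratio is clamped at zero, so average a few phenotype draws
  set.seed(52)
  n <- 300
  codes <- sapply(1:400, function(j) rbinom(n, 2, runif(1, 0.1, 0.9)))
  G <- compute_grm(toy_matrix(codes))
  ratios <- sapply(1:5, function(i) {
    fit <- reml_fit(rnorm(n), G)
    fit$sigma_g2 / (fit$sigma_g2 + fit$sigma_e2)
  })
  expect_lt(mean(ratios), 0.1)
})

test_that("REML optimum beats an exhaustive grid of the restricted likelihood", {
  set.seed(63)
  codes <- sapply(1:30, function(j) rbinom(5, 2, runif(1, 0.2, 0.8)))
  G <- compute_grm(toy_matrix(codes))
  y <- c(0.3, -1.1, 0.8, 2.0, -0.4)
  fit <- suppressWarnings(reml_fit(y, G))
  X <- cbind(rep(1, 5))
  restricted_ll <- function(sg, se) {
    V <- sg * G + se * diag(5)
    ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < 1e-10) return(-Inf)
    Vi <- solve(V)
    XtViX <- t(X) %*% Vi %*% X
    P <- Vi - Vi %*% X %*% solve(XtViX) %*% t(X) %*% Vi
    -0.5 * (determinant(V)$modulus + determinant(XtViX)$modulus +
              drop(t(y) %*% P %*% y))
  }
  grid <- expand.grid(sg = c(1e-8, exp(seq(log(0.001), log(10), length = 200))),
                      se = exp(seq(log(0.001), log(10), length = 200)))
  lls <- mapply(restricted_ll, grid$sg, grid$se)
  ll_fit <- restricted_ll(max(fit$sigma_g2, 1e-8), max(fit$sigma_e2, 1e-8))
  expect_gte(ll_fit, max(lls) - 1e-6)
})

test_that("with an identity GRM the MLM collapses to linear regression", {
  set.seed(74)
  n <- 400
  codes <- cbind(rbinom(n, 2, 0.5), rbinom(n, 2, 0.3))
  gm <- toy_matrix(codes)
  y <- rbinom(n, 1, 0.5)
  fit <- reml_fit(y, diag(n))
  res <- mlm_assoc(gm, fit)
  for (j in 1:2) {
    lmfit <- summary(lm(y ~ codes[, j]))
    expect_equal(res$beta_mlm[j], lmfit$coefficients[2, 1],
                 tolerance = 1e-8)
    expect_equal(res$p_mlm[j], lmfit$coefficients[2, 4], tolerance = 5e-3)
  }
})

test_that("MLM p-values are uniform under the null", {
  set.seed(85)
  n <- 300
  codes <- sapply(1:400, function(j) rbinom(n, 2, runif(1, 0.15, 0.85)))
  gm <- toy_matrix(codes)
  y <- rnorm(n)
  fit <- reml_fit(y, compute_grm(gm))
  res <- mlm_assoc(gm, fit)
  ks <- stats::ks.test(stats::na.omit(res$p_mlm), "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("Bonferroni threshold is alpha over the number of tests", {
  expect_equal(bonferroni_threshold(500000), 1e-7)
  expect_equal(bonferroni_threshold(476239), 0.05 / 476239)
  expect_equal(bonferroni_threshold(476239), 1.0499e-7, tolerance = 1e-4)
  expect_equal(bonferroni_threshold(1), 0.05)
  expect_error(bonferroni_threshold(0), "n_tests")
})

test_that("nearest-gene distances follow the flank-gap convention", {
  genes <- data.frame(chrom = c("1", "1", "2"),
                      start = c(100L, 400L, 50L),
                      end = c(200L, 500L, 80L),
                      name = c("geneA", "geneB", "geneC"),
                      strand = "*", stringsAsFactors = FALSE)
  hits <- nearest_gene(data.frame(chrom = "1", pos = 150), genes)
  expect_identical(hits$nearest_gene, "geneA")
  expect_identical(hits$distance, 0)

  gap <- nearest_gene(data.frame(chrom = "1", pos = 250), genes)
  expect_identical(gap$nearest_gene, "geneA")
  expect_identical(gap$distance, 50)

  # 300 is 100 bp from geneA's end and 100 bp from geneB's start: tie
  # breaks to the first-listed gene
  tie <- nearest_gene(data.frame(chrom = "1", pos = 300), genes)
  expect_identical(tie$nearest_gene, "geneA")
  expect_identical(tie$distance, 100)

  expect_warning(
    miss <- nearest_gene(data.frame(chrom = "9", pos = 5), genes),
    "no gene")
  expect_true(is.na(miss$distance))
})

test_that("association output is position-sorted and deterministic", {
  cfg <- small_backcross_config(seed = 6)
  co <- simulate_backcross(cfg)
  y <- co$pedigree$phenotype
  a <- logistic_assoc(co$genotypes, y)
  b <- logistic_assoc(co$genotypes, y)
  expect_identical(a, b)
  expect_false(is.unsorted(order(a$chrom, a$pos)))
  ml1 <- mlm_assoc(co$genotypes, reml_fit(y, compute_grm(co$genotypes)))
  expect_false(is.unsorted(ml1$pos[ml1$chrom == "1"]))
})
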