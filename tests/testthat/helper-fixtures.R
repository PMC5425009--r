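# Small hand-built genotype matrices used across tests.

toy_matrix <- function(codes, chrom = "1", pos = NULL, ref = "A", alt = "T") {
  codes <- as.matrix(codes)
  m <- ncol(codes)
  if (is.null(pos)) pos <- seq_len(m) * 100L
  sites <- data.frame(chrom = rep_len(chrom, m), pos = pos,
                      id = paste0("s", seq_len(m)),
                      ref = rep_len(ref, m), alt = rep_len(alt, m),
                      stringsAsFactors = FALSE)
  genotype_matrix(codes, sites)
}

# Independent exact-HWE oracle: absolute conditional probabilities from the
# closed-form expression with full factorial normalization.
hwe_oracle <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  na <- 2 * n0 + n1
  nb <- 2 * n2 + n1
  hs <- seq(min(na, nb) %% 2, min(na, nb), by = 2)
  logp <- lfactorial(n) + lfactorial(na) + lfactorial(nb) + hs * log(2) -
    lfactorial((na - hs) / 2) - lfactorial(hs) - lfactorial((nb - hs) / 2) -
    lfactorial(2 * n)
  probs <- exp(logp)
  obs <- probs[match(n1, hs)]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Independent Fisher oracle: full hypergeometric enumeration for a 2x2 table.
fisher_oracle <- function(a, b, c, d) {
  m1 <- a + b
  k <- a + c
  n <- a + b + c + d
  xs <- max(0, k - (c + d)):min(m1, k)
  probs <- stats::dhyper(xs, m1, n - m1, k)
  obs <- stats::dhyper(a, m1, n - m1, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

small_backcross_config <- function(seed = 1, ...) {
  sim_config(chrom_lengths = c("1" = 2e6, "2" = 2e6),
             n_sites_per_chrom = 60L, causal_chrom = "2",
             causal_pos = 1e6, sweep_halfwidth = 2e5,
             n_f2 = 24L, n_families = 4L, seed = seed, ...)
}

make_2x2_matrix <- function(case_carrier, case_non, ctrl_carrier, ctrl_non) {
  dose <- c(rep(1L, case_carrier), rep(0L, case_non),
            rep(1L, ctrl_carrier), rep(0L, ctrl_non))
  y <- rep(c(1L, 0L), c(case_carrier + case_non, ctrl_carrier + ctrl_non))
  list(gm = toy_matrix(cbind(dose)), y = y)
}
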