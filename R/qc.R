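#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact conditional test on one site's genotype counts: given
#' the allele counts, the probability of every possible heterozygote count
#' is computed and the p-value is the sum of probabilities not exceeding
#' that of the observed configuration.
#'
#' @param n_hom_ref,n_het,n_hom_alt Genotype counts.
#' @return Exact two-sided p-value in (0, 1].
#' @export
hwe_exact_p <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  if (n == 0) return(NA_real_)
  rare <- min(2 * n_hom_ref + n_het, 2 * n_hom_alt + n_het)
  if (rare == 0) return(1)
  hs <- seq(rare %% 2, rare, by = 2)
  logw <- hs * log(2) - lfactorial(hs) - lfactorial((rare - hs) / 2) -
    lfactorial(n - (rare + hs) / 2)
  logw <- logw - max(logw)
  probs <- exp(logw) / sum(exp(logw))
  p_obs <- probs[match(n_het, hs)]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

#' Per-site quality-control statistics
#'
#' Computes, per site, the minor allele frequency (on non-missing alleles),
#' the missing-call rate across samples and the exact Hardy-Weinberg
#' p-value from the genotype counts of non-missing samples.
#'
#' @param x A [genotype_matrix()].
#' @return Data frame with one row per site: `chrom`, `pos`, `id`, `maf`,
#'   `missing_rate`, `hwe_p`. Sites with no non-missing call get `NA` maf.
#' @export
site_stats <- function(x) {
  stopifnot(inherits(x, "genotype_matrix"))
  if (n_samples(x) < 1) stop("need at least one sample")
  codes <- x$codes
  n_ok <- colSums(!is.na(codes))
  alt <- colSums(codes, na.rm = TRUE)
  p_alt <- ifelse(n_ok > 0, alt / (2 * n_ok), NA_real_)
  maf <- pmin(p_alt, 1 - p_alt)
  miss <- 1 - n_ok / nrow(codes)
  n0 <- colSums(codes == 0L, na.rm = TRUE)
  n1 <- colSums(codes == 1L, na.rm = TRUE)
  n2 <- colSums(codes == 2L, na.rm = TRUE)
  hwe <- vapply(seq_len(ncol(codes)),
                function(j) hwe_exact_p(n0[j], n1[j], n2[j]), numeric(1))
  data.frame(chrom = x$sites$chrom, pos = x$sites$pos, id = x$sites$id,
             maf = maf, missing_rate = miss, hwe_p = hwe,
             stringsAsFactors = FALSE)
}

#' Filter sites on MAF, missingness and Hardy-Weinberg
#'
#' A site is retained iff `maf >= maf_min` and `missing_rate <= miss_max`
#' and `hwe_p >= hwe_min` (the complements of the discard rules
#' MAF < 0.05, missing rate > 0.5, HWE p < 1e-6). Sites where every call
#' is missing fail with reason `MISS`.
#'
#' @param x A [genotype_matrix()].
#' @param maf_min,miss_max,hwe_min Thresholds.
#' @return List with `matrix` (the filtered [genotype_matrix()]), `stats`
#'   (per-site stats plus `pass` flag and `fail_reasons` string), and
#'   `report`: named counts of sites failing each rule (non-exclusive),
#'   sites removed and retained.
#' @export
filter_sites <- function(x, maf_min = 0.05, miss_max = 0.5, hwe_min = 1e-6) {
  stopifnot(maf_min >= 0, maf_min <= 0.5, miss_max >= 0, miss_max <= 1,
            hwe_min >= 0, hwe_min <= 1)
  st <- site_stats(x)
  fail_maf <- !is.na(st$maf) & st$maf < maf_min
  fail_miss <- st$missing_rate > miss_max | is.na(st$maf)
  fail_hwe <- !is.na(st$hwe_p) & st$hwe_p < hwe_min
  pass <- !(fail_maf | fail_miss | fail_hwe)
  reasons <- character(nrow(st))
  reasons[fail_maf] <- "MAF"
  reasons <- ifelse(fail_miss, paste0(reasons, ifelse(reasons == "", "", ","), "MISS"), reasons)
  reasons <- ifelse(fail_hwe, paste0(reasons, ifelse(reasons == "", "", ","), "HWE"), reasons)
  st$pass <- pass
  st$fail_reasons <- reasons
  list(matrix = x[, pass],
       stats = st,
       report = c(n_input = nrow(st),
                  fail_MAF = sum(fail_maf),
                  fail_MISS = sum(fail_miss),
                  fail_HWE = sum(fail_hwe),
                  removed = sum(!pass),
                  retained = sum(pass)))
}

# Pairwise dosage r^2 on pairwise-complete observations.
dosage_r2 <- function(codes) {
  suppressWarnings(stats::cor(codes, use = "pairwise.complete.obs"))^2
}

#' Greedy LD pruning to an independent marker set
#'
#' Within each sliding window of `window_snps` consecutive sites (per
#' chromosome), while any retained pair has squared dosage correlation
#' above `r2_max`, the member of the worst pair with the lower MAF is
#' dropped (tie: the later site). The window then advances by `step_snps`.
#'
#' @param x A QC-passed [genotype_matrix()].
#' @param window_snps,step_snps Window size and step in number of sites.
#' @param r2_max Maximum allowed pairwise r-squared.
#' @return List with `matrix` (pruned [genotype_matrix()]) and `keep`
#'   (logical vector over input sites).
#' @export
ld_prune <- function(x, window_snps = 50, step_snps = 5, r2_max = 0.2) {
  stopifnot(inherits(x, "genotype_matrix"))
  st <- site_stats(x)
  keep <- rep(TRUE, n_sites(x))
  for (ch in unique(x$sites$chrom)) {
    idx <- which(x$sites$chrom == ch)
    start <- 1
    while (start <= length(idx)) {
      win <- idx[start:min(start + window_snps - 1, length(idx))]
      act <- win[keep[win]]
      if (length(act) > 1) {
        r2 <- dosage_r2(x$codes[, act, drop = FALSE])
        diag(r2) <- 0
        r2[is.na(r2)] <- 0
        while (any(r2 > r2_max)) {
          worst <- which(r2 == max(r2), arr.ind = TRUE)[1, ]
          i <- act[worst[1]]; j <- act[worst[2]]
          drop <- if (st$maf[i] < st$maf[j]) i
                  else if (st$maf[j] < st$maf[i]) j
                  else max(i, j)
          keep[drop] <- FALSE
          k <- match(drop, act)
          r2[k, ] <- 0
          r2[, k] <- 0
        }
      }
      if (start + window_snps - 1 >= length(idx)) break
      start <- start + step_snps
    }
  }
  list(matrix = x[, keep], keep = keep)
}
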