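#' Weir-Cockerham variance components for one site, two populations
#'
#' Two-population form of the Weir & Cockerham (1984) estimator with
#' sample-size correction, computed from genotype counts (so observed
#' heterozygosity enters component b and c). The per-site estimate is
#' `a / (a + b + c)`, undefined when the denominator is zero (site
#' monomorphic across both groups).
#'
#' @param counts_a,counts_b Genotype counts `c(hom_ref, het, hom_alt)` for
#'   each group; each group needs at least one called diploid.
#' @return List with components `a`, `b`, `c` and `fst` (raw ratio, `NA`
#'   when undefined).
#' @export
wc_fst_site <- function(counts_a, counts_b) {
  stopifnot(length(counts_a) == 3, length(counts_b) == 3)
  n1 <- sum(counts_a); n2 <- sum(counts_b)
  if (n1 < 1 || n2 < 1) stop("each group needs at least one genotype")
  comp <- wc_components(n1, (2 * counts_a[3] + counts_a[2]) / (2 * n1),
                        counts_a[2] / n1,
                        n2, (2 * counts_b[3] + counts_b[2]) / (2 * n2),
                        counts_b[2] / n2)
  den <- comp$a + comp$b + comp$c
  list(a = comp$a, b = comp$b, c = comp$c,
       fst = if (abs(den) < 1e-300) NA_real_ else comp$a / den)
}

# Vectorized two-population Weir-Cockerham components from per-site sample
# sizes (diploids), alt-allele frequencies and observed het fractions.
wc_components <- function(n1, p1, h1, n2, p2, h2) {
  nbar <- (n1 + n2) / 2
  nc <- 2 * nbar - (n1^2 + n2^2) / (2 * nbar)
  pbar <- (n1 * p1 + n2 * p2) / (2 * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / nbar
  hbar <- (n1 * h1 + n2 * h2) / (2 * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 / 2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 / 2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  c_ <- hbar / 2
  bad <- nbar <= 1 | nc <= 0
  a[bad] <- NA_real_; b[bad] <- NA_real_; c_[bad] <- NA_real_
  list(a = a, b = b, c = c_)
}

# Hudson's two-population estimator (numerator/denominator form), offered
# for comparison with the default Weir-Cockerham components.
hudson_components <- function(n1, p1, n2, p2) {
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (2 * n1 - 1) -
    p2 * (1 - p2) / (2 * n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  list(num = num, den = den)
}

#' Per-site F_st scan between two genotype matrices
#'
#' Computes per-site differentiation components between two groups typed
#' at the same sites. The default Weir-Cockerham estimator uses genotype
#' counts; the Hudson estimator (allele frequencies only) is available for
#' comparison. Column `num`/`den` hold the ratio-of-sums ingredients used
#' by [window_fst()].
#'
#' @param x_a,x_b [genotype_matrix()] objects over the same site table.
#' @param estimator `"wc"` (default) or `"hudson"`.
#' @return Data frame with site columns, per-group sample sizes, `num`,
#'   `den`, `fst` (raw per-site ratio, `NA` where undefined) and
#'   `monomorphic` flag.
#' @export
fst_scan <- function(x_a, x_b, estimator = c("wc", "hudson")) {
  estimator <- match.arg(estimator)
  stopifnot(inherits(x_a, "genotype_matrix"), inherits(x_b, "genotype_matrix"))
  if (!identical(x_a$sites[c("chrom", "pos")], x_b$sites[c("chrom", "pos")])) {
    stop("the two matrices must share the same site list")
  }
  stats_of <- function(g) {
    n <- colSums(!is.na(g))
    p <- ifelse(n > 0, colSums(g, na.rm = TRUE) / (2 * n), NA_real_)
    h <- ifelse(n > 0, colSums(g == 1L, na.rm = TRUE) / n, NA_real_)
    list(n = n, p = p, h = h)
  }
  sa <- stats_of(x_a$codes)
  sb <- stats_of(x_b$codes)
  ok <- sa$n >= 1 & sb$n >= 1
  if (estimator == "wc") {
    comp <- wc_components(sa$n, sa$p, sa$h, sb$n, sb$p, sb$h)
    num <- comp$a
    den <- comp$a + comp$b + comp$c
  } else {
    comp <- hudson_components(sa$n, sa$p, sb$n, sb$p)
    num <- comp$num
    den <- comp$den
  }
  num[!ok] <- NA_real_
  den[!ok] <- NA_real_
  mono <- ok & !is.na(den) & abs(den) < 1e-300
  fst <- ifelse(!is.na(den) & abs(den) >= 1e-300, num / den, NA_real_)
  cbind(x_a$sites,
        data.frame(n_a = sa$n, n_b = sb$n, num = num, den = den,
                   fst = fst, monomorphic = mono))
}

#' Sliding-window F_st
#'
#' Aggregates per-site components into windows anchored at position 0 of
#' each chromosome (0-based half-open), advancing by `step` while the
#' window start is inside the chromosome; trailing windows are truncated
#' at the chromosome end. The window estimate is the ratio of sums
#' (sum of numerators over sum of denominators), the standard low-bias
#' choice; `per_site_mean = TRUE` averages the per-site ratios instead.
#' Windows with fewer than `min_snps` usable sites are reported but
#' flagged non-qualifying and excluded from the empirical outlier
#' distribution.
#'
#' @param site_fst Output of [fst_scan()].
#' @param chrom_lengths Named vector of chromosome lengths in bp; every
#'   chromosome appearing in `site_fst` must be present.
#' @param window,step Window and step size in bp.
#' @param min_snps Minimum usable sites for a window to qualify.
#' @param per_site_mean Average per-site ratios instead of ratio of sums.
#' @return Data frame of windows: `chrom`, `start`, `end` (0-based
#'   half-open), `n_snps`, `fst_raw`, `fst` (clipped to `[0, 1]`),
#'   `qualifies`.
#' @export
window_fst <- function(site_fst, chrom_lengths, window = 100000,
                       step = 10000, min_snps = 10,
                       per_site_mean = FALSE) {
  unknown <- setdiff(unique(site_fst$chrom), names(chrom_lengths))
  if (length(unknown)) {
    stop("chromosome(s) missing from `chrom_lengths`: ",
         paste(unknown, collapse = ", "))
  }
  out <- lapply(names(chrom_lengths), function(ch) {
    L <- chrom_lengths[[ch]]
    starts <- seq(0, by = step, length.out = ceiling(L / step))
    ends <- pmin(starts + window, L)
    s <- site_fst[site_fst$chrom == ch & !is.na(site_fst$den), , drop = FALSE]
    usable <- s[abs(s$den) >= 1e-300, , drop = FALSE]
    n_snps <- fr <- numeric(length(starts))
    for (w in seq_along(starts)) {
      inw <- usable$pos > starts[w] & usable$pos <= ends[w]
      n_snps[w] <- sum(inw)
      if (n_snps[w] == 0) {
        fr[w] <- NA_real_
      } else if (per_site_mean) {
        fr[w] <- mean(usable$fst[inw])
      } else {
        fr[w] <- sum(usable$num[inw]) / sum(usable$den[inw])
      }
    }
    data.frame(chrom = ch, start = starts, end = ends, n_snps = n_snps,
               fst_raw = fr, fst = pmin(pmax(fr, 0), 1),
               qualifies = n_snps >= min_snps & !is.na(fr),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Empirical outlier threshold for windowed F_st
#'
#' The threshold is the lower bound of the highest `top_fraction` of the
#' empirical distribution over qualifying windows (those with at least
#' `min_snps` sites): the minimum F_st among the top
#' `ceiling(top_fraction * N)` of the N qualifying windows. Outliers are
#' then all windows with data reaching `fst >= threshold`: sparse windows
#' never shape the threshold, but a sparse window inside a swept interval
#' may still join an outlier region (isolated sparse windows are kept in
#' check downstream, where regions are ranked by peak F_st and then by
#' the number of merged windows).
#'
#' @param windows Output of [window_fst()].
#' @param top_fraction Fraction of windows in the outlier tail (default
#'   0.001, the 99.9 percent level).
#' @param include_sparse Allow non-qualifying windows (with at least one
#'   usable site) into the outlier set. Default `TRUE`.
#' @return List with `threshold`, `n_windows` (qualifying count), `n_top`,
#'   `outliers` (windows at or above the threshold) and `degenerate`
#'   (TRUE when every qualifying window ties the threshold).
#' @export
outlier_threshold <- function(windows, top_fraction = 0.001,
                              include_sparse = TRUE) {
  q <- windows[windows$qualifies, , drop = FALSE]
  if (nrow(q) == 0) stop("no qualifying windows")
  k <- ceiling(top_fraction * nrow(q))
  sorted <- sort(q$fst, decreasing = TRUE)
  thr <- sorted[k]
  pool <- if (include_sparse) {
    windows[windows$n_snps > 0 & !is.na(windows$fst), , drop = FALSE]
  } else {
    q
  }
  outliers <- pool[pool$fst >= thr, , drop = FALSE]
  degenerate <- sum(q$fst >= thr) == nrow(q)
  if (degenerate) {
    warning("all qualifying windows reach the outlier threshold; ",
            "the empirical distribution is degenerate")
  }
  list(threshold = thr, n_windows = nrow(q), n_top = k,
       outliers = outliers, degenerate = degenerate)
}

#' Merge outlier windows into candidate regions
#'
#' Overlapping or bookended windows on one chromosome are merged into
#' maximal regions; each region records its peak window F_st and the
#' number of windows merged.
#'
#' @param windows Data frame of outlier windows (`chrom`, `start`, `end`,
#'   `fst`).
#' @return Data frame of regions: `chrom`, `start`, `end`, `peak_fst`,
#'   `n_windows`, sorted by chromosome and start.
#' @export
merge_outliers <- function(windows) {
  if (nrow(windows) == 0) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), peak_fst = numeric(),
                      n_windows = integer(), stringsAsFactors = FALSE))
  }
  windows <- windows[order(windows$chrom, windows$start), , drop = FALSE]
  regions <- list()
  cur <- windows[1, ]
  cur_peak <- cur$fst
  cur_n <- 1L
  flush <- function() {
    data.frame(chrom = cur$chrom, start = cur$start, end = cur$end,
               peak_fst = cur_peak, n_windows = cur_n,
               stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(windows))[-1]) {
    w <- windows[i, ]
    if (w$chrom == cur$chrom && w$start <= cur$end) {
      cur$end <- max(cur$end, w$end)
      cur_peak <- max(cur_peak, w$fst)
      cur_n <- cur_n + 1L
    } else {
      regions[[length(regions) + 1]] <- flush()
      cur <- w; cur_peak <- w$fst; cur_n <- 1L
    }
  }
  regions[[length(regions) + 1]] <- flush()
  do.call(rbind, regions)
}

#' Opposite-homozygote scan
#'
#' A site qualifies when every sample of group A is homozygous for one
#' allele and every sample of group B homozygous for the other. With
#' `require_complete = TRUE` (default) any missing call disqualifies the
#' site; otherwise missing calls are ignored as long as each group retains
#' at least one call. SNPs and InDels are both scanned and distinguished
#' by the `vtype` column of the result.
#'
#' @param x_a,x_b [genotype_matrix()] objects over the same site table.
#' @param require_complete Disqualify sites with any missing call.
#' @return Data frame of qualifying sites with columns `allele_a` and
#'   `allele_b` (the homozygous allele of each group).
#' @export
opposite_homozygotes <- function(x_a, x_b, require_complete = TRUE) {
  stopifnot(inherits(x_a, "genotype_matrix"), inherits(x_b, "genotype_matrix"))
  if (!identical(x_a$sites[c("chrom", "pos")], x_b$sites[c("chrom", "pos")])) {
    stop("the two matrices must share the same site list")
  }
  fixed_code <- function(g) {
    n_na <- colSums(is.na(g))
    n <- nrow(g) - n_na
    all0 <- colSums(g == 0L, na.rm = TRUE) == n & n >= 1
    all2 <- colSums(g == 2L, na.rm = TRUE) == n & n >= 1
    code <- ifelse(all0, 0L, ifelse(all2, 2L, NA_integer_))
    if (require_complete) code[n_na > 0] <- NA_integer_
    code
  }
  ca <- fixed_code(x_a$codes)
  cb <- fixed_code(x_b$codes)
  hit <- !is.na(ca) & !is.na(cb) & ca != cb
  out <- x_a$sites[hit, , drop = FALSE]
  out$allele_a <- ifelse(ca[hit] == 0L, out$ref, out$alt)
  out$allele_b <- ifelse(cb[hit] == 0L, out$ref, out$alt)
  rownames(out) <- NULL
  out
}

#' Per-chromosome site counts and densities
#'
#' @param chroms Character vector of chromosome assignments, one entry per
#'   site (e.g. the `chrom` column of an [opposite_homozygotes()] result),
#'   or a pre-tabulated named count vector.
#' @param chrom_lengths Named vector of chromosome lengths in bp; all
#'   counted chromosomes must be present.
#' @return Data frame with `chrom`, `count` and `density` (count per Mb),
#'   sorted by density, highest first. Chromosomes with no site get
#'   density 0.
#' @export
chrom_density <- function(chroms, chrom_lengths) {
  counts <- if (is.numeric(chroms)) chroms else table(chroms)
  unknown <- setdiff(names(counts), names(chrom_lengths))
  if (length(unknown)) {
    stop("no length for chromosome(s): ", paste(unknown, collapse = ", "))
  }
  all_counts <- stats::setNames(numeric(length(chrom_lengths)),
                                names(chrom_lengths))
  all_counts[names(counts)] <- as.numeric(counts)
  out <- data.frame(chrom = names(chrom_lengths),
                    count = as.numeric(all_counts),
                    density = as.numeric(all_counts) /
                      (as.numeric(chrom_lengths) / 1e6),
                    stringsAsFactors = FALSE)
  out[order(-out$density), , drop = FALSE]
}
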