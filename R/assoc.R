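#' @importFrom stats plogis pnorm pchisq optimize glm.fit binomial
NULL

# Firth-penalized logistic regression (Jeffreys-prior score correction).
# Used when the ordinary ML fit shows (quasi-)separation, where the MLE
# diverges; the penalized estimate is always finite.
firth_logistic <- function(X, y, maxit = 100, tol = 1e-8) {
  p <- ncol(X)
  beta <- rep(0, p)
  pen_ll <- function(beta) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    info <- crossprod(X * sqrt(w))
    ld <- determinant(info, logarithm = TRUE)$modulus
    sum(y * eta - log1p(exp(eta))) + 0.5 * as.numeric(ld)
  }
  ll_old <- pen_ll(beta)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    XW <- X * sqrt(w)
    info <- crossprod(XW)
    inv <- tryCatch(solve(info), error = function(e) NULL)
    if (is.null(inv)) break
    h <- rowSums((XW %*% inv) * XW)
    score <- drop(crossprod(X, y - mu + h * (0.5 - mu)))
    delta <- drop(inv %*% score)
    step <- 1
    repeat {
      cand <- beta + step * delta
      ll_new <- pen_ll(cand)
      if (is.finite(ll_new) && ll_new >= ll_old - 1e-12) break
      step <- step / 2
      if (step < 1e-6) break
    }
    beta <- beta + step * delta
    ll_new <- pen_ll(beta)
    if (max(abs(step * delta)) < tol || abs(ll_new - ll_old) < 1e-10) {
      converged <- TRUE
      ll_old <- ll_new
      break
    }
    ll_old <- ll_new
  }
  eta <- drop(X %*% beta)
  mu <- plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-12)
  info <- crossprod(X * sqrt(w))
  se <- sqrt(diag(solve(info)))
  list(beta = beta, se = se, converged = converged, pen_loglik = pen_ll(beta))
}

# Penalized likelihood-ratio p-value for the dose term of a Firth fit:
# the Wald statistic is unreliable under separation, so the fit is
# compared against the Firth fit of the model without the dose column.
firth_plr_p <- function(X, y, full) {
  red <- firth_logistic(X[, -2, drop = FALSE], y)
  chi <- max(0, 2 * (full$pen_loglik - red$pen_loglik))
  pchisq(chi, df = 1, lower.tail = FALSE)
}

as_binary_phenotype <- function(phenotypes) {
  if (is.factor(phenotypes)) {
    y <- as.integer(phenotypes == "case")
    y[is.na(phenotypes)] <- NA_integer_
  } else {
    y <- as.integer(phenotypes)
    if (!all(y %in% c(0L, 1L, NA_integer_))) {
      stop("numeric phenotypes must be coded 0/1")
    }
  }
  y
}

#' Per-site logistic case/control association
#'
#' Fits, for each site, a maximum-likelihood logistic regression of case
#' status on alt-allele dosage plus optional covariates (typically the
#' first two MDS components), reporting the Wald p-value and the odds
#' ratio per alt allele. Samples with a missing genotype are dropped for
#' that site. When the fit shows (quasi-)separation or fails to converge,
#' the site is refit with Firth penalization and flagged `firth_used`;
#' for those sites the reported p-value is the penalized likelihood-ratio
#' p (the Wald statistic degenerates under separation).
#'
#' @param x A [genotype_matrix()].
#' @param phenotypes Factor `control`/`case` (or 0/1 vector) aligned with
#'   samples.
#' @param covariates Optional numeric matrix/data frame (samples x c).
#' @return Data frame, one row per site, sorted by chromosome and
#'   position: site columns plus `beta`, `or_`, `se`, `p_logistic`,
#'   `converged`, `firth_used`.
#' @export
logistic_assoc <- function(x, phenotypes, covariates = NULL) {
  stopifnot(inherits(x, "genotype_matrix"))
  y_all <- as_binary_phenotype(phenotypes)
  if (length(y_all) != n_samples(x)) stop("phenotype length mismatch")
  if (length(unique(stats::na.omit(y_all))) < 2) {
    stop("phenotype is constant; association is undefined")
  }
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n_samples(x)) stop("covariate rows mismatch")
  }
  m <- n_sites(x)
  beta <- se <- rep(NA_real_, m)
  pval <- rep(NA_real_, m)
  conv <- firth <- logical(m)
  for (j in seq_len(m)) {
    g <- x$codes[, j]
    keep <- !is.na(g) & !is.na(y_all)
    y <- y_all[keep]
    X <- cbind(`(Intercept)` = 1, dose = as.numeric(g[keep]))
    if (!is.null(covariates)) X <- cbind(X, covariates[keep, , drop = FALSE])
    if (length(unique(y)) < 2 || stats::var(X[, 2]) == 0) next
    fit <- suppressWarnings(glm.fit(X, y, family = binomial()))
    cf <- fit$coefficients
    mu <- fit$fitted.values
    sep <- !fit$converged || anyNA(cf) ||
      any(mu < 1e-8 | mu > 1 - 1e-8) || abs(cf[2]) > 10
    if (sep) {
      ff <- firth_logistic(X, y)
      beta[j] <- ff$beta[2]
      se[j] <- ff$se[2]
      conv[j] <- ff$converged
      firth[j] <- TRUE
      if (conv[j]) pval[j] <- firth_plr_p(X, y, ff)
      next
    } else {
      w <- mu * (1 - mu)
      vc <- tryCatch(solve(crossprod(X * sqrt(w))), error = function(e) NULL)
      if (is.null(vc)) next
      beta[j] <- cf[2]
      se[j] <- sqrt(vc[2, 2])
      conv[j] <- TRUE
    }
    if (conv[j]) pval[j] <- 2 * pnorm(-abs(beta[j] / se[j]))
  }
  out <- cbind(x$sites,
               data.frame(beta = beta, or_ = exp(beta), se = se,
                          p_logistic = pval, converged = conv,
                          firth_used = firth))
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' Genomic relationship matrix
#'
#' Standard GRM from alt-allele dosages: missing calls are mean-imputed
#' per site, and over the m sites with allele frequency strictly between
#' 0 and 1,
#' \deqn{G_{jk} = \frac{1}{m}\sum_i \frac{(x_{ij}-2p_i)(x_{ik}-2p_i)}{2p_i(1-p_i)}.}
#'
#' @param x A [genotype_matrix()].
#' @return Samples x samples numeric matrix.
#' @export
compute_grm <- function(x) {
  stopifnot(inherits(x, "genotype_matrix"))
  codes <- x$codes
  cm <- colMeans(codes, na.rm = TRUE)
  idx <- which(is.na(codes), arr.ind = TRUE)
  if (nrow(idx)) codes[idx] <- cm[idx[, 2]]
  p <- cm / 2
  poly <- which(p > 0 & p < 1)
  if (length(poly) == 0) stop("no polymorphic sites for GRM")
  Z <- sweep(codes[, poly, drop = FALSE], 2, 2 * p[poly])
  Z <- sweep(Z, 2, sqrt(2 * p[poly] * (1 - p[poly])), "/")
  G <- tcrossprod(Z) / length(poly)
  dimnames(G) <- list(x$samples, x$samples)
  G
}

# Restricted log-likelihood profiled over the total variance, for
# heritability ratio h2, in the rotated (eigen) basis of the GRM.
reml_profile_ll <- function(h2, D, yt, Xt) {
  n <- length(yt)
  p <- ncol(Xt)
  v <- h2 * D + (1 - h2)
  if (any(v <= 0)) return(-Inf)
  Xv <- Xt / v
  XtVX <- crossprod(Xt, Xv)
  bhat <- tryCatch(solve(XtVX, crossprod(Xv, yt)),
                   error = function(e) NULL)
  if (is.null(bhat)) return(-Inf)
  r <- yt - Xt %*% bhat
  quad <- sum(r^2 / v)
  phi <- quad / (n - p)
  ld <- determinant(XtVX, logarithm = TRUE)$modulus
  -0.5 * ((n - p) * log(phi) + sum(log(v)) + as.numeric(ld) + (n - p))
}

#' REML variance components for the GRM mixed model
#'
#' Fits `y = X b + g + e` with `g ~ N(0, sigma_g^2 G)` and
#' `e ~ N(0, sigma_e^2 I)` by restricted maximum likelihood. The binary
#' phenotype enters as a 0/1 quantitative trait, as mixed-model
#' association tools do for case/control data. The two components are
#' profiled to a one-dimensional likelihood in the heritability ratio
#' using the eigendecomposition of G, then maximized by a coarse grid
#' plus golden-section refinement; components are clamped at zero.
#'
#' @param phenotypes Factor `control`/`case` or numeric vector.
#' @param grm Relatedness matrix from [compute_grm()]. If not positive
#'   semi-definite it is shifted by its smallest eigenvalue with a
#'   warning.
#' @param covariates Optional numeric matrix (samples x c); an intercept
#'   is always included.
#' @return An object of class `grm_model`: `sigma_g2`, `sigma_e2`, `h2`,
#'   `loglik` (profiled restricted log-likelihood at the optimum, up to a
#'   constant), `grm`, plus cached rotation terms reused by
#'   [mlm_assoc()].
#' @export
reml_fit <- function(phenotypes, grm, covariates = NULL) {
  if (is.factor(phenotypes) || all(stats::na.omit(phenotypes) %in% 0:1)) {
    y <- as.numeric(as_binary_phenotype(phenotypes))
  } else {
    y <- as.numeric(phenotypes)
  }
  n <- length(y)
  if (anyNA(y)) stop("missing phenotypes are not supported in the MLM")
  stopifnot(nrow(grm) == n, ncol(grm) == n)
  X <- cbind(rep(1, n))
  if (!is.null(covariates)) X <- cbind(X, as.matrix(covariates))
  e <- eigen((grm + t(grm)) / 2, symmetric = TRUE)
  D <- e$values
  if (min(D) < -1e-8) {
    warning("GRM is not positive semi-definite; shifting by ",
            signif(-min(D), 3))
    D <- D - min(D)
  }
  D <- pmax(D, 0)
  U <- e$vectors
  yt <- drop(crossprod(U, y))
  Xt <- crossprod(U, X)
  grid <- seq(0, 0.999, length.out = 101)
  ll <- vapply(grid, reml_profile_ll, numeric(1), D = D, yt = yt, Xt = Xt)
  best <- which.max(ll)
  lo <- grid[max(1, best - 1)]
  hi <- grid[min(length(grid), best + 1)]
  opt <- optimize(reml_profile_ll, c(lo, hi), D = D, yt = yt, Xt = Xt,
                  maximum = TRUE, tol = 1e-9)
  h2 <- if (opt$objective > ll[best]) opt$maximum else grid[best]
  # recover the profiled total variance at the optimum
  v <- h2 * D + (1 - h2)
  Xv <- Xt / v
  XtVX <- crossprod(Xt, Xv)
  bhat <- solve(XtVX, crossprod(Xv, yt))
  phi <- sum((yt - Xt %*% bhat)^2 / v) / (n - ncol(X))
  structure(list(grm = grm,
                 sigma_g2 = phi * h2,
                 sigma_e2 = phi * (1 - h2),
                 h2 = h2,
                 loglik = max(opt$objective, ll[best]),
                 beta = drop(bhat),
                 eigenvalues = D, eigenvectors = U,
                 X = X, y = y),
            class = "grm_model")
}

#' @export
print.grm_model <- function(x, ...) {
  cat("grm_model: sigma_g2 =", signif(x$sigma_g2, 4),
      " sigma_e2 =", signif(x$sigma_e2, 4),
      " h2 =", signif(x$h2, 4), "\n")
  invisible(x)
}

#' Mixed-linear-model association
#'
#' Per-site generalized-least-squares test of the alt dosage with the
#' phenotypic covariance `V = sigma_g^2 G + sigma_e^2 I` held fixed at the
#' null-model REML estimates from [reml_fit()] (no per-site refit).
#' Missing dosages are mean-imputed per site. The Wald statistic uses the
#' exact GLS variance of the effect under the fitted V.
#'
#' @param x A [genotype_matrix()].
#' @param model A `grm_model` from [reml_fit()] (fitted with the same
#'   samples and covariates).
#' @return Data frame, one row per site, sorted by chromosome and
#'   position: site columns plus `beta_mlm`, `se_mlm`, `p_mlm`.
#' @export
mlm_assoc <- function(x, model) {
  stopifnot(inherits(x, "genotype_matrix"), inherits(model, "grm_model"))
  v <- model$sigma_g2 * model$eigenvalues + model$sigma_e2
  if (any(v < 1e-12)) stop("fitted covariance V is singular")
  U <- model$eigenvectors
  codes <- x$codes
  cm <- colMeans(codes, na.rm = TRUE)
  idx <- which(is.na(codes), arr.ind = TRUE)
  if (nrow(idx)) codes[idx] <- cm[idx[, 2]]
  sv <- sqrt(v)
  yt <- drop(crossprod(U, model$y)) / sv
  Xt <- crossprod(U, model$X) / sv
  St <- crossprod(U, codes) / sv
  qx <- qr(Xt)
  ry <- qr.resid(qx, yt)
  RS <- qr.resid(qx, St)
  xx <- colSums(RS^2)
  beta <- ifelse(xx > 1e-12, colSums(RS * ry) / xx, NA_real_)
  se <- ifelse(xx > 1e-12, 1 / sqrt(xx), NA_real_)
  p <- pchisq((beta / se)^2, df = 1, lower.tail = FALSE)
  out <- cbind(x$sites,
               data.frame(beta_mlm = beta, se_mlm = se, p_mlm = p))
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' Bonferroni-corrected per-test significance threshold
#'
#' @param n_tests Number of tests (sites).
#' @param alpha Family-wise error rate (default 0.05).
#' @return `alpha / n_tests`. A site is called significant when its
#'   p-value is strictly below this threshold.
#' @export
bonferroni_threshold <- function(n_tests, alpha = 0.05) {
  if (n_tests < 1) stop("`n_tests` must be >= 1")
  alpha / n_tests
}

#' Nearest gene and distance for variant sites
#'
#' For each site, reports the gene whose interval contains it (distance
#' 0), or otherwise the closest gene on the same chromosome by gap to
#' either interval end (3' or 5' flank). Ties are broken by gene order in
#' the input; chromosomes with no gene yield `NA` with a warning. Gene
#' intervals are 0-based half-open (BED); site positions are 1-based.
#'
#' @param sites Data frame with `chrom` and `pos` columns (e.g. the
#'   `sites` element of a [genotype_matrix()] or an association table).
#' @param genes Gene table from [read_genes()].
#' @return Data frame with columns `nearest_gene` and `distance`, row-
#'   aligned with `sites`.
#' @export
nearest_gene <- function(sites, genes) {
  if (nrow(genes) == 0) stop("gene list is empty")
  res_gene <- rep(NA_character_, nrow(sites))
  res_dist <- rep(NA_real_, nrow(sites))
  warned <- character(0)
  for (i in seq_len(nrow(sites))) {
    g <- genes[genes$chrom == sites$chrom[i], , drop = FALSE]
    if (nrow(g) == 0) {
      warned <- union(warned, sites$chrom[i])
      next
    }
    pos <- sites$pos[i]
    first1 <- g$start + 1  # first covered 1-based position
    d <- ifelse(pos < first1, first1 - pos,
                ifelse(pos > g$end, pos - g$end, 0))
    j <- which.min(d)
    res_gene[i] <- g$name[j]
    res_dist[i] <- d[j]
  }
  if (length(warned)) {
    warning("no gene on chromosome(s): ", paste(warned, collapse = ", "))
  }
  data.frame(nearest_gene = res_gene, distance = res_dist,
             stringsAsFactors = FALSE)
}

#' Combined association table
#'
#' Runs the logistic and mixed-model scans on the same matrix and merges
#' them into one table (chr, position, alleles, OR, mlm and logistic
#' p-values), optionally annotated with the nearest gene of each
#' significant site.
#'
#' @param x A [genotype_matrix()].
#' @param phenotypes Factor `control`/`case` aligned with samples.
#' @param covariates Optional covariate matrix (e.g. MDS components).
#' @param genes Optional gene table from [read_genes()] for nearest-gene
#'   annotation.
#' @param alpha Family-wise error rate for the Bonferroni threshold.
#' @return List with `results` (full per-site table), `threshold` (the
#'   Bonferroni per-test threshold) and `significant` (subset where both
#'   p-values fall strictly below the threshold).
#' @export
association_scan <- function(x, phenotypes, covariates = NULL,
                             genes = NULL, alpha = 0.05) {
  lg <- logistic_assoc(x, phenotypes, covariates)
  model <- reml_fit(phenotypes, compute_grm(x), covariates)
  ml <- mlm_assoc(x, model)
  res <- cbind(lg, ml[match(paste(lg$chrom, lg$pos),
                            paste(ml$chrom, ml$pos)),
                      c("beta_mlm", "se_mlm", "p_mlm")])
  thr <- bonferroni_threshold(sum(!is.na(res$p_logistic)), alpha)
  sig <- res[!is.na(res$p_logistic) & !is.na(res$p_mlm) &
               res$p_logistic < thr & res$p_mlm < thr, , drop = FALSE]
  if (!is.null(genes) && nrow(sig)) {
    sig <- cbind(sig, nearest_gene(sig, genes))
  }
  list(results = res, threshold = thr, significant = sig, model = model)
}
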