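# Single-variant linear mixed-model association scan with a genomic
# relationship matrix, using the spectral (one-eigendecomposition) REML
# trick popularised by FaST-LMM.

#' REML variance components of the null mixed model
#'
#' Fits `y = W b + u + e` with `u ~ N(0, K sigma_u^2)` and
#' `e ~ N(0, I sigma_e^2)` by restricted maximum likelihood. After one
#' eigendecomposition `K = U L U'`, the model is rotated so the covariance
#' is diagonal and the REML log-likelihood is profiled down to a 1-D
#' optimisation over `delta = sigma_e^2 / sigma_u^2`.
#'
#' @param y numeric response vector (e.g. dEBV of the training set).
#' @param K genomic relationship matrix for the same individuals.
#' @param covariates optional data frame / factor / matrix of fixed
#'   covariates (an intercept is always added). A factor is expanded via
#'   treatment contrasts.
#' @return an object of class `null_vc`: `sigma_u2`, `sigma_e2`, `delta`,
#'   `log_likelihood` (full REML log-likelihood including constants), plus
#'   the cached eigendecomposition for reuse by [association_scan()].
#' @export
estimate_null_vc <- function(y, K, covariates = NULL) {
  if (any(!is.finite(y))) stop_seqgp("`y` must be finite", "input_error")
  n <- length(y)
  if (n != nrow(K)) stop_seqgp("length(y) must match dim(K)", "input_error")
  if (n < 30) warning("fewer than 30 individuals: variance components will be unstable")

  eg <- eigen(K, symmetric = TRUE)
  lam <- eg$values
  if (min(lam) < -1e-6 * max(abs(lam))) {
    stop_seqgp("K is not positive semidefinite beyond tolerance",
               "matrix_error")
  }
  lam <- pmax(lam, 0)
  U <- eg$vectors

  W <- build_covariate_matrix(covariates, n)
  p <- ncol(W)
  yt <- drop(crossprod(U, y))
  Wt <- crossprod(U, W)

  reml_ll <- function(log_delta) {
    d <- lam + exp(log_delta)
    w <- 1 / d
    WtW <- crossprod(Wt, Wt * w)
    b <- solve(WtW, crossprod(Wt, yt * w))
    r <- yt - drop(Wt %*% b)
    rss <- sum(w * r^2)
    s2 <- rss / (n - p)
    -0.5 * ((n - p) * log(2 * pi) + (n - p) * log(s2) + sum(log(d)) +
              determinant(WtW, logarithm = TRUE)$modulus[1] + (n - p))
  }

  grid <- seq(-10, 10, length.out = 21)
  ll <- vapply(grid, reml_ll, numeric(1))
  i0 <- which.max(ll)
  lo <- grid[max(1L, i0 - 1L)]
  hi <- grid[min(length(grid), i0 + 1L)]
  opt <- stats::optimize(reml_ll, c(lo, hi), maximum = TRUE, tol = 1e-8)
  delta <- exp(opt$maximum)

  d <- lam + delta
  w <- 1 / d
  WtW <- crossprod(Wt, Wt * w)
  b <- solve(WtW, crossprod(Wt, yt * w))
  rss <- sum(w * (yt - drop(Wt %*% b))^2)
  sigma_u2 <- rss / (n - p)
  structure(list(
    sigma_u2 = sigma_u2,
    sigma_e2 = sigma_u2 * delta,
    delta = delta,
    log_likelihood = opt$objective,
    reml_loglik = reml_ll,
    U = U, lambda = lam, n = n
  ), class = "null_vc")
}

#' @noRd
build_covariate_matrix <- function(covariates, n) {
  W <- matrix(1, n, 1)
  if (is.null(covariates)) return(W)
  if (is.factor(covariates) || is.character(covariates)) {
    f <- factor(covariates)
    if (nlevels(f) > 1L) W <- cbind(W, stats::model.matrix(~f)[, -1, drop = FALSE])
    return(W)
  }
  cv <- as.matrix(covariates)
  if (nrow(cv) != n) stop_seqgp("covariates must have one row per individual",
                                "input_error")
  cbind(W, cv)
}

#' Single-variant association scan
#'
#' For each variant, fits `y = W b + x beta + u + e` by generalised least
#' squares with the covariance `sigma_u^2 K + sigma_e^2 I` held fixed at
#' the null-model REML estimates (the FaST-LMM-style approximation), and
#' reports the Wald test of `beta` against the standard normal. The
#' per-variant residual variance is rescaled from the per-variant fit, so
#' that with `sigma_u2 = 0` the scan reduces exactly to ordinary least
#' squares. Variants with no genotypic variance after covariate projection
#' are flagged `tested = FALSE` with missing statistics.
#'
#' @param y numeric response for the scanned individuals.
#' @param genotypes a `geno_matrix` whose rows match `y`, or a plain dosage
#'   matrix.
#' @param vc a `null_vc` object from [estimate_null_vc()] fitted on the
#'   same `y` and individuals.
#' @param covariates as in [estimate_null_vc()] (use the line factor for
#'   multi-line scans).
#' @param variant_mask optional selection of variants to scan.
#' @return a data frame (`variant_id`, `chrom`, `pos`, `beta`, `se`, `p`,
#'   `n_used`, `tested`) of class `gwas_result`.
#' @export
association_scan <- function(y, genotypes, vc, covariates = NULL,
                             variant_mask = NULL) {
  stopifnot(inherits(vc, "null_vc"))
  if (inherits(genotypes, "geno_matrix")) {
    ci <- variant_mask %||% seq_len(ncol(genotypes$dosages))
    if (is.character(ci)) ci <- match(ci, genotypes$map$variant_id)
    X <- genotypes$dosages[, ci, drop = FALSE]
    map <- genotypes$map[ci, , drop = FALSE]
  } else {
    X <- genotypes
    map <- data.frame(variant_id = colnames(X) %||% as.character(seq_len(ncol(X))),
                      chrom = NA_integer_, pos = NA_integer_,
                      stringsAsFactors = FALSE)
  }
  n <- length(y)
  if (nrow(X) != n || vc$n != n) {
    stop_seqgp("y, genotypes and vc must cover the same individuals",
               "input_error")
  }
  if (anyNA(X)) stop_seqgp("dosages must be complete (impute first)",
                           "input_error")
  storage.mode(X) <- "double"

  w <- 1 / (vc$sigma_u2 * vc$lambda + vc$sigma_e2)
  sw <- sqrt(w)
  W <- build_covariate_matrix(covariates, n)
  p <- ncol(W)
  yt <- drop(crossprod(vc$U, y)) * sw
  Wt <- crossprod(vc$U, W) * sw
  Xt <- crossprod(vc$U, X) * sw

  qrW <- qr(Wt)
  yr <- qr.resid(qrW, yt)
  Xr <- qr.resid(qrW, Xt)
  Sxx <- colSums(Xr^2)
  Sxy <- colSums(Xr * yr)
  Syy <- sum(yr^2)

  tested <- Sxx > 1e-10
  beta <- ifelse(tested, Sxy / Sxx, NA_real_)
  rss <- pmax(Syy - ifelse(tested, Sxy^2 / Sxx, 0), 0)
  df <- n - p - 1L
  s2 <- rss / df
  se <- ifelse(tested, sqrt(s2 / Sxx), NA_real_)
  z <- beta / se
  pv <- ifelse(tested, pmax(2 * stats::pnorm(-abs(z)), .Machine$double.xmin),
               NA_real_)

  out <- data.frame(
    variant_id = map$variant_id, chrom = map$chrom, pos = map$pos,
    beta = beta, se = se, p = pv, n_used = n, tested = tested,
    stringsAsFactors = FALSE
  )
  class(out) <- c("gwas_result", "data.frame")
  out
}
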