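# BayesR mixture-prior genomic prediction: configuration, fitting (via the
# compiled Gibbs sampler) and GEBV prediction.

#' BayesR sampler configuration
#'
#' @param n_iterations total Gibbs iterations (default 10000).
#' @param burn_in iterations discarded before summarising (default 5000).
#' @param thin keep every `thin`-th post-burn-in sample (default 10).
#' @param mixture_variance_fractions component variances as fractions of
#'   the total genetic variance; the first must be exactly 0 (the null
#'   component) and the fractions must be strictly increasing. Default
#'   `c(0, 1e-4, 1e-3, 1e-2)`.
#' @param dirichlet_alpha Dirichlet prior for the mixture proportions;
#'   default all 1 (uniform, almost uninformative).
#' @param seed integer seed for the chain.
#' @param vg_start_frac starting value of the genetic-variance anchor, as a
#'   fraction of `var(y)` (default 0.5).
#' @param vg_floor_frac lower bound of the anchor as a fraction of
#'   `var(y)` (default 0.05); keeps the mixture components identifiable
#'   when the chain is at or near the empty model.
#' @param sigma_g_rule how the genetic variance is re-estimated each
#'   iteration: `"empirical"` (variance of the current genetic values
#'   `X beta` over training individuals, default) or `"sumvar"`
#'   (`sum(2 p (1-p) beta^2)` computed from the centred dosages).
#' @return an object of class `bayesr_config`.
#' @export
bayesr_config <- function(n_iterations = 10000L, burn_in = 5000L,
                          thin = 10L,
                          mixture_variance_fractions = c(0, 1e-4, 1e-3, 1e-2),
                          dirichlet_alpha = rep(1, length(mixture_variance_fractions)),
                          seed = 1L,
                          vg_start_frac = 0.5,
                          vg_floor_frac = 0.05,
                          sigma_g_rule = c("empirical", "sumvar")) {
  if (burn_in >= n_iterations) {
    stop_seqgp("burn_in must be smaller than n_iterations", "config_error")
  }
  f <- mixture_variance_fractions
  if (f[1] != 0 || any(f < 0) || any(diff(f) <= 0)) {
    stop_seqgp("mixture_variance_fractions must start at 0 and be strictly increasing",
               "config_error")
  }
  if (length(dirichlet_alpha) != length(f) || any(dirichlet_alpha <= 0)) {
    stop_seqgp("dirichlet_alpha must be positive, one entry per component",
               "config_error")
  }
  structure(list(
    n_iterations = as.integer(n_iterations),
    burn_in = as.integer(burn_in),
    thin = as.integer(thin),
    mixture_variance_fractions = f,
    dirichlet_alpha = dirichlet_alpha,
    seed = as.integer(seed),
    vg_start_frac = vg_start_frac,
    vg_floor_frac = vg_floor_frac,
    sigma_g_rule = match.arg(sigma_g_rule)
  ), class = "bayesr_config")
}

#' Fit the BayesR model
#'
#' Runs the single-site Gibbs sampler for
#' `y = 1 mu + X beta + e` (plus a categorical line effect in multi-line
#' mode, reference line absorbed in the intercept), with a four-component
#' normal mixture prior on each variant effect whose variances are
#' `c(0, 1e-4, 1e-3, 1e-2) * sigma_g^2` and the total genetic variance
#' `sigma_g^2` re-estimated every iteration. Dosages are centred by their
#' training-set column means (stored in the fit for prediction); they are
#' not variance-standardised, since the component variances already scale
#' with `sigma_g^2`. The chain starts at the empty model (all effects in
#' the null component).
#'
#' @param y numeric response (dEBV or simulated phenotype).
#' @param X dosage matrix, individuals x variants, with column names.
#' @param line_labels optional character/factor of line labels for
#'   multi-line fits.
#' @param config a [bayesr_config()].
#' @return an object of class `bayesr_fit` with posterior summaries:
#'   `effect_means`, `comp_probs` (per-variant component membership
#'   proportions), `mu`, `line_effects`, `sigma_g2`, `sigma_e2`,
#'   `mixture_proportions`, `samples_kept`, and the kept-sample `trace` of
#'   variances and proportions.
#' @export
fit_bayesr <- function(y, X, line_labels = NULL, config = bayesr_config()) {
  stopifnot(inherits(config, "bayesr_config"))
  if (any(!is.finite(y))) stop_seqgp("`y` must be finite", "input_error")
  n <- length(y)
  if (nrow(X) != n) stop_seqgp("nrow(X) must equal length(y)", "input_error")
  if (n < 50) warning("fewer than 50 training individuals")

  line_levels <- "all"
  line_idx <- rep(0L, n)
  if (!is.null(line_labels)) {
    f <- factor(line_labels)
    line_levels <- levels(f)
    line_idx <- as.integer(f) - 1L
  }

  col_means <- colMeans(X)
  vary <- popvar(y)
  if (vary == 0) {
    warning("constant response: returning degenerate null fit")
    m <- ncol(X)
    K <- length(config$mixture_variance_fractions)
    cp <- matrix(0, m, K); cp[, 1] <- 1
    return(structure(list(
      variant_ids = colnames(X), effect_means = rep(0, m),
      comp_probs = cp, mu = y[1],
      line_effects = stats::setNames(rep(0, length(line_levels)), line_levels),
      sigma_g2 = 0, sigma_e2 = 0,
      mixture_proportions = c(1, rep(0, K - 1L)),
      samples_kept = 0L, col_means = col_means,
      line_levels = line_levels, config = config, trace = NULL
    ), class = "bayesr_fit"))
  }

  Xc <- sweep(matrix(as.double(X), n, ncol(X)), 2L, col_means)
  set.seed(config$seed)
  res <- bayesr_gibbs_cpp(
    Xc, as.double(y), line_idx, length(line_levels),
    config$n_iterations, config$burn_in, config$thin,
    config$mixture_variance_fractions, config$dirichlet_alpha,
    config$vg_start_frac * vary, config$vg_floor_frac * vary,
    as.integer(config$sigma_g_rule == "sumvar")
  )

  structure(list(
    variant_ids = colnames(X),
    effect_means = res$effect_means,
    comp_probs = res$comp_probs,
    mu = res$mu,
    line_effects = stats::setNames(res$line_effects, line_levels),
    sigma_g2 = res$sigma_g2,
    sigma_e2 = res$sigma_e2,
    mixture_proportions = res$mixture_proportions,
    samples_kept = res$samples_kept,
    col_means = col_means,
    line_levels = line_levels,
    config = config,
    trace = res$trace
  ), class = "bayesr_fit")
}

#' @export
print.bayesr_fit <- function(x, ...) {
  cat(sprintf(
    "bayesr_fit: %d variants, %d kept samples\n  sigma_g2 = %.4g, sigma_e2 = %.4g\n  mixture proportions: %s\n",
    length(x$variant_ids), x$samples_kept, x$sigma_g2, x$sigma_e2,
    paste(sprintf("%.3f", x$mixture_proportions), collapse = " ")))
  invisible(x)
}

#' Predict genomic breeding values
#'
#' `GEBV = mu + line effect + X_new beta`, with the new dosages centred by
#' the training-set column means stored in the fit.
#'
#' @param fit a `bayesr_fit`.
#' @param X_new dosage matrix whose columns match the fit's variant set.
#' @param line_labels optional line labels of the new individuals; lines
#'   unseen in training get the reference (zero) line effect.
#' @return named numeric vector of GEBV.
#' @export
predict_gebv <- function(fit, X_new, line_labels = NULL) {
  stopifnot(inherits(fit, "bayesr_fit"))
  if (!is.null(fit$variant_ids) && !is.null(colnames(X_new)) &&
      !identical(colnames(X_new), fit$variant_ids)) {
    stop_seqgp("columns of X_new do not match the fitted variant set",
               "schema_error")
  }
  if (ncol(X_new) != length(fit$effect_means)) {
    stop_seqgp("X_new has the wrong number of variants", "schema_error")
  }
  Xc <- sweep(matrix(as.double(X_new), nrow(X_new), ncol(X_new)), 2L,
              fit$col_means)
  g <- drop(Xc %*% fit$effect_means) + fit$mu
  if (!is.null(line_labels)) {
    eff <- fit$line_effects[as.character(line_labels)]
    eff[is.na(eff)] <- 0
    g <- g + unname(eff)
  }
  names(g) <- rownames(X_new)
  g
}
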