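# Animal-model BLUP and VanRaden-style deregression of breeding values.

#' Animal-model BLUP via Henderson's mixed-model equations
#'
#' Fits `y = W b + Z u + e` with `u ~ N(0, A * sigma_u^2)` and i.i.d.
#' residuals, where A is the numerator relationship matrix and the variance
#' ratio is `lambda = (1 - h2) / h2`. The phenotypic variance is anchored at
#' `var(y)`, so `sigma_u^2 = h2 * var(y)`. Breeding values are predicted for
#' every individual in A (individuals without records or informative
#' relatives get EBV 0 and reliability 0). Reliability is
#' `1 - PEV / sigma_u^2`, with the prediction error variance taken from the
#' inverse of the MME coefficient matrix.
#'
#' @param phenotypes named numeric vector of records; names must be
#'   individual ids present in `A`.
#' @param A numerator relationship matrix from [pedigree_A()].
#' @param h2 assumed heritability in (0, 1).
#' @param fixed optional named factor of a non-genetic batch effect for the
#'   phenotyped individuals; an overall mean is always included.
#' @return a data frame (`id`, `ebv`, `reliability`) covering all ids in A.
#' @export
animal_model_blup <- function(phenotypes, A, h2, fixed = NULL) {
  assert_scalar_number(h2, "h2", 0, 1, strict_lower = TRUE)
  if (h2 >= 1) stop_seqgp("`h2` must be strictly below 1", "config_error")
  ids <- rownames(A)
  if (is.null(names(phenotypes)) || !all(names(phenotypes) %in% ids)) {
    stop_seqgp("phenotyped individuals must appear in A", "config_error")
  }
  if (any(!is.finite(phenotypes))) {
    stop_seqgp("phenotypes must be finite", "input_error")
  }
  lambda <- (1 - h2) / h2
  y <- unname(phenotypes)
  n <- length(y)
  q <- length(ids)

  W <- matrix(1, n, 1)
  if (!is.null(fixed)) {
    f <- factor(fixed[names(phenotypes)])
    if (nlevels(f) > 1L) {
      W <- cbind(W, stats::model.matrix(~f)[, -1, drop = FALSE])
    }
  }
  p <- ncol(W)
  if (qr(W)$rank < p) {
    stop_seqgp("fixed-effect design is rank deficient", "rank_error")
  }
  Z <- matrix(0, n, q)
  Z[cbind(seq_len(n), match(names(phenotypes), ids))] <- 1

  Ainv <- solve(A)
  C <- rbind(
    cbind(crossprod(W), crossprod(W, Z)),
    cbind(crossprod(Z, W), crossprod(Z) + lambda * Ainv)
  )
  rhs <- c(crossprod(W, y), crossprod(Z, y))
  Cinv <- solve(C)
  sol <- drop(Cinv %*% rhs)
  u <- sol[p + seq_len(q)]

  var_y <- stats::var(y)
  sigma_u2 <- h2 * var_y
  sigma_e2 <- (1 - h2) * var_y
  pev <- diag(Cinv)[p + seq_len(q)] * sigma_e2
  rel <- pmin(pmax(1 - pev / sigma_u2, 0), 1 - 1e-8)

  data.frame(id = ids, ebv = u, reliability = rel,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Deregress estimated breeding values
#'
#' Removes the parent average (PA) from each EBV and unshrinks the
#' Mendelian-sampling part:
#' `dEBV = PA + (EBV - PA) / r2_MS`, with
#' `PA = (EBV_sire + EBV_dam) / 2`,
#' `r2_PA = (r2_sire + r2_dam) / 4`, and
#' `r2_MS = max(eps, r2 - r2_PA)` (eps = 0.01). This is a simplified,
#' closed-form variant of the VanRaden deregression; a record weight
#' `w = r2_MS / (1 - r2_MS)` is stored but not used by the default
#' prediction model, which is unweighted.
#'
#' Missing parents are treated as having EBV 0 and reliability 0.
#' Individuals whose Mendelian-sampling reliability falls below
#' `min_reliability` are dropped.
#'
#' @param ebvs data frame from [animal_model_blup()].
#' @param pedigree pedigree providing sire/dam links and line labels.
#' @param min_reliability minimum `r2_MS` for retention (default 0.05).
#' @return a data frame (`id`, `line`, `ebv`, `reliability`,
#'   `parent_average`, `r2_ms`, `debv`, `weight`).
#' @export
deregress <- function(ebvs, pedigree, min_reliability = 0.05) {
  stopifnot(all(c("id", "ebv", "reliability") %in% names(ebvs)))
  eps <- 0.01
  idx <- match(pedigree$id, ebvs$id)
  if (anyNA(idx)) {
    stop_seqgp("every pedigree individual needs an EBV record",
               "integrity_error")
  }
  ebv <- ebvs$ebv[idx]
  rel <- ebvs$reliability[idx]

  get_parent <- function(par) {
    j <- match(par, ebvs$id)
    list(ebv = ifelse(is.na(j), 0, ebvs$ebv[j]),
         rel = ifelse(is.na(j), 0, ebvs$reliability[j]))
  }
  s <- get_parent(pedigree$sire)
  d <- get_parent(pedigree$dam)
  pa <- (s$ebv + d$ebv) / 2
  r2_pa <- (s$rel + d$rel) / 4
  r2_ms <- pmax(eps, rel - r2_pa)
  debv <- pa + (ebv - pa) / r2_ms

  out <- data.frame(
    id = pedigree$id, line = pedigree$line,
    ebv = ebv, reliability = rel,
    parent_average = pa, r2_ms = r2_ms, debv = debv,
    weight = r2_ms / (1 - pmin(r2_ms, 0.999)),
    stringsAsFactors = FALSE
  )
  dropped <- out$r2_ms < min_reliability
  if (any(dropped)) {
    message(sprintf("deregress: dropped %d individual(s) with r2_MS < %g",
                    sum(dropped), min_reliability))
  }
  out[!dropped, , drop = FALSE]
}

#' Build the response table for GWAS and prediction
#'
#' Either runs the full BLUP + deregression path or (the bypass used in
#' simulation experiments, where the deregression machinery would only add
#' noise of its own) uses the simulated phenotype directly as the response.
#' Only individuals with an own phenotype are retained.
#'
#' @param phenotypes named numeric vector of records.
#' @param pedigree the pedigree.
#' @param h2 assumed heritability for the BLUP step.
#' @param bypass_deregression if `TRUE`, the response is the raw phenotype.
#' @param min_reliability passed to [deregress()].
#' @return a data frame (`id`, `line`, `y`).
#' @export
trait_response <- function(phenotypes, pedigree, h2 = 0.3,
                           bypass_deregression = FALSE,
                           min_reliability = 0.05) {
  ids <- names(phenotypes)
  if (bypass_deregression) {
    keep <- match(ids, pedigree$id)
    return(data.frame(id = ids, line = pedigree$line[keep],
                      y = unname(phenotypes), stringsAsFactors = FALSE))
  }
  A <- pedigree_A(pedigree)
  ebvs <- animal_model_blup(phenotypes, A, h2)
  der <- deregress(ebvs, pedigree, min_reliability)
  der <- der[der$id %in% ids, , drop = FALSE]  # own phenotype required
  data.frame(id = der$id, line = der$line, y = der$debv,
             stringsAsFactors = FALSE)
}
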