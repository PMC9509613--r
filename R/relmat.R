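# Pedigree (numerator) and genomic relationship matrices.

#' Numerator relationship matrix from a pedigree
#'
#' Computes Wright's numerator relationship matrix A by the recursive
#' tabular method: individuals are processed parents-first;
#' `a(i, j) = (a(sire_i, j) + a(dam_i, j)) / 2` for j preceding i, and
#' `a(i, i) = 1 + F_i` with the inbreeding coefficient
#' `F_i = a(sire_i, dam_i) / 2`. Unknown parents contribute zero.
#'
#' @param pedigree a valid pedigree (see [validate_pedigree()]); parents
#'   must belong to earlier generations.
#' @return a symmetric matrix with dimnames equal to the individual ids
#'   (in pedigree order), of class `relationship_matrix` with attribute
#'   `kind = "pedigree_A"`.
#' @export
pedigree_A <- function(pedigree) {
  validate_pedigree(pedigree)
  ord <- order(pedigree$generation, pedigree$birth_order)
  ped <- pedigree[ord, ]
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$id
  si <- ifelse(is.na(ped$sire), 0L, idx[ped$sire])
  di <- ifelse(is.na(ped$dam), 0L, idx[ped$dam])

  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    if (si[i] == 0L) {
      A[i, i] <- 1
    } else {
      if (i > 1L) {
        j <- seq_len(i - 1L)
        aij <- (A[si[i], j] + A[di[i], j]) / 2
        A[i, j] <- aij
        A[j, i] <- aij
      }
      A[i, i] <- 1 + A[si[i], di[i]] / 2
    }
  }
  # return in the caller's order
  back <- match(pedigree$id, ped$id)
  A <- A[back, back, drop = FALSE]
  structure(A, class = c("relationship_matrix", "matrix", "array"),
            kind = "pedigree_A")
}

#' Genomic relationship matrix (VanRaden method 1)
#'
#' `K = Z Z' / c` where `Z` is the dosage matrix centred per variant by
#' twice the observed allele frequency and `c = sum(2 p (1 - p))` over the
#' variants used. Missing dosages are imputed to the variant mean before
#' centring. Built from column-centred dosages, every row of K sums to
#' (numerically) zero.
#'
#' @param genotypes a `geno_matrix`.
#' @param variant_mask optional logical/integer/character selection of the
#'   variants to use (e.g. the chip panel). Default: all variants.
#' @return a symmetric positive semidefinite matrix of class
#'   `relationship_matrix` with attribute `kind = "genomic_K"`.
#' @export
genomic_K <- function(genotypes, variant_mask = NULL) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  ci <- variant_mask %||% seq_len(ncol(genotypes$dosages))
  if (is.character(ci)) ci <- match(ci, genotypes$map$variant_id)
  M <- genotypes$dosages[, ci, drop = FALSE]
  storage.mode(M) <- "double"
  if (anyNA(M)) {
    mu <- colMeans(M, na.rm = TRUE)
    na <- which(is.na(M), arr.ind = TRUE)
    M[na] <- mu[na[, 2L]]
  }
  p <- colMeans(M) / 2
  poly <- p > 0 & p < 1
  if (sum(poly) < 2L) {
    stop_seqgp("fewer than two polymorphic variants in the mask",
               "degenerate_input_error")
  }
  M <- M[, poly, drop = FALSE]
  p <- p[poly]
  Z <- sweep(M, 2L, 2 * p)
  c0 <- sum(2 * p * (1 - p))
  K <- tcrossprod(Z) / c0
  structure(K, class = c("relationship_matrix", "matrix", "array"),
            kind = "genomic_K")
}
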