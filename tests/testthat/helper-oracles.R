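# Independent oracle implementations used by the tests. These deliberately
# use different algorithms from the package code paths they check.

# Wright-style relationship by recursive kinship (coancestry) with
# memoisation: f(i,i) = (1 + f(s_i, d_i)) / 2, f(i,j) = (f(s_i,j) + f(d_i,j)) / 2
# for i not an ancestor of j (taking the younger of the pair). A = 2f.
oracle_A_kinship <- function(ped) {
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$id
  gen <- ped$generation
  si <- ifelse(is.na(ped$sire), 0L, idx[ped$sire])
  di <- ifelse(is.na(ped$dam), 0L, idx[ped$dam])
  memo <- new.env(hash = TRUE)
  f <- function(i, j) {
    if (i == 0L || j == 0L) return(0)
    if (i < j) { tmp <- i; i <- j; j <- tmp }
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- if (i == j) {
      (1 + f(si[i], di[i])) / 2
    } else {
      # recurse on the individual from the later generation (or larger
      # index at equal generation, which cannot be an ancestor)
      a <- if (gen[i] >= gen[j]) i else j
      b <- if (gen[i] >= gen[j]) j else i
      (f(si[a], b) + f(di[a], b)) / 2
    }
    memo[[key]] <- val
    val
  }
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) for (j in seq_len(i)) {
    A[i, j] <- A[j, i] <- 2 * f(i, j)
  }
  A
}

# dense profiled REML log-likelihood at a given delta = sigma_e2/sigma_u2:
# sigma_u2 is profiled out as (r' H^-1 r)/(n-p) with H = K + delta I, then
# -1/2 [ (n-p) log 2pi + log|V| + log|W'V^-1 W| + y' P y ] is evaluated at
# V = sigma_u2_hat * H by direct dense inversion.
oracle_reml_ll <- function(y, K, W, delta) {
  n <- length(y)
  p <- ncol(W)
  H <- K + delta * diag(n)
  Hi <- solve(H)
  b <- solve(t(W) %*% Hi %*% W, t(W) %*% Hi %*% y)
  r <- drop(y - W %*% b)
  s2 <- drop(t(r) %*% Hi %*% r) / (n - p)
  V <- s2 * H
  Vi <- Hi / s2
  WtVIW <- t(W) %*% Vi %*% W
  -0.5 * ((n - p) * log(2 * pi) +
            determinant(V, logarithm = TRUE)$modulus[1] +
            determinant(WtVIW, logarithm = TRUE)$modulus[1] +
            drop(t(r) %*% Vi %*% r))
}

# per-variant OLS by explicit normal equations, normal-based p-value
oracle_ols_scan <- function(y, X, W = matrix(1, length(y), 1)) {
  n <- length(y)
  p <- ncol(W)
  t(apply(X, 2, function(x) {
    D <- cbind(W, x)
    XtX <- crossprod(D)
    if (abs(det(XtX)) < 1e-10) return(c(NA, NA, NA))
    co <- solve(XtX, crossprod(D, y))
    r <- y - D %*% co
    s2 <- sum(r^2) / (n - p - 1)
    se <- sqrt(s2 * solve(XtX)[p + 1, p + 1])
    beta <- co[p + 1]
    c(beta, se, 2 * pnorm(-abs(beta / se)))
  }))
}

# dense GLS/BLUP oracle: b = (W'V^-1 W)^-1 W'V^-1 y,
# u = sigma_u2 A Z' V^-1 (y - W b), V = Z A Z' sigma_u2 + I sigma_e2
oracle_blup <- function(y, W, Z, A, sigma_u2, sigma_e2) {
  V <- Z %*% A %*% t(Z) * sigma_u2 + diag(length(y)) * sigma_e2
  Vi <- solve(V)
  b <- solve(t(W) %*% Vi %*% W, t(W) %*% Vi %*% y)
  u <- sigma_u2 * A %*% t(Z) %*% Vi %*% (y - W %*% b)
  list(b = drop(b), u = drop(u))
}

# exhaustive per-window argmin-p selection (ties: pos then id)
oracle_top_per_window <- function(gw, window_size) {
  gw <- gw[gw$tested & !is.na(gw$p), , drop = FALSE]
  win <- (gw$pos - 1) %/% window_size
  out <- character(0)
  for (key in unique(paste(gw$chrom, win))) {
    rows <- gw[paste(gw$chrom, win) == key, , drop = FALSE]
    rows <- rows[order(rows$p, rows$pos, rows$variant_id), , drop = FALSE]
    out <- c(out, rows$variant_id[1])
  }
  sort(out)
}
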