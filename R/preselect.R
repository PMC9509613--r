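# Construction of predictor variant sets: QC filters, genomic windows,
# top-per-window preselection, chip-plus-significant merging, and the
# multi-line variant universe.

#' Construct a variant set
#'
#' @param name set label (e.g. "Chip", "Top40k", "ChipPlusSign").
#' @param variant_ids ordered unique variant ids.
#' @param provenance character vector (same length) with values `"chip"`,
#'   `"wgs_significant"` or `"wgs_topwindow"`.
#' @param window_size_bp window size used during construction, if any.
#' @param p_threshold significance threshold used, if any.
#' @return an object of class `variant_set`.
#' @export
new_variant_set <- function(name, variant_ids, provenance,
                            window_size_bp = NA_integer_,
                            p_threshold = NA_real_) {
  if (anyDuplicated(variant_ids)) {
    stop_seqgp("variant set contains duplicate ids", "integrity_error")
  }
  if (length(provenance) != length(variant_ids)) {
    stop_seqgp("provenance must be assigned to every member",
               "integrity_error")
  }
  structure(list(name = name,
                 variant_ids = as.character(variant_ids),
                 provenance = provenance,
                 window_size_bp = window_size_bp,
                 p_threshold = p_threshold),
            class = "variant_set")
}

#' @export
print.variant_set <- function(x, ...) {
  cat(sprintf("variant_set '%s': %d variants (%s)\n", x$name,
              length(x$variant_ids),
              paste(sprintf("%s=%d", names(table(x$provenance)),
                            table(x$provenance)), collapse = ", ")))
  invisible(x)
}

#' Chip variant set of a genotype panel
#'
#' @param genotypes a `geno_matrix` with chip flags set.
#' @param qc_mask optional logical mask of variants passing QC.
#' @return a `variant_set` named "Chip".
#' @export
chip_set <- function(genotypes, qc_mask = NULL) {
  keep <- genotypes$map$is_chip
  if (!is.null(qc_mask)) keep <- keep & qc_mask
  ids <- genotypes$map$variant_id[keep]
  new_variant_set("Chip", ids, rep("chip", length(ids)))
}

# per-variant QC of one line's genotypes; returns logical mask
qc_mask_one_line <- function(dos, maf_min, call_rate_min, hwe_alpha) {
  n <- nrow(dos)
  nobs <- n - colSums(is.na(dos))
  call_rate <- nobs / n
  p <- colMeans(dos, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  # Hardy-Weinberg chi-square goodness of fit, 1 df
  n2 <- colSums(dos == 2L, na.rm = TRUE)
  n1 <- colSums(dos == 1L, na.rm = TRUE)
  n0 <- nobs - n1 - n2
  e2 <- nobs * p^2
  e1 <- nobs * 2 * p * (1 - p)
  e0 <- nobs * (1 - p)^2
  x2 <- ifelse(p > 0 & p < 1,
               (n2 - e2)^2 / pmax(e2, 1e-12) +
                 (n1 - e1)^2 / pmax(e1, 1e-12) +
                 (n0 - e0)^2 / pmax(e0, 1e-12),
               0)
  hwe_p <- stats::pchisq(x2, df = 1, lower.tail = FALSE)
  ok <- (maf >= maf_min) & (call_rate >= call_rate_min) & (hwe_p >= hwe_alpha)
  unname(ok & !is.na(ok))
}

#' Marker quality-control filter
#'
#' Flags variants passing the array-style QC: minor allele frequency at
#' least `maf_min`, call rate at least `call_rate_min`, and no significant
#' deviation from Hardy-Weinberg equilibrium (chi-square goodness of fit
#' with 1 df at level `hwe_alpha`). Filters are applied separately within
#' each line present; a variant passes only if it passes in every line.
#' Defaults follow the usual practice: `maf_min` 0.01 for the chip panel
#' and 0.023 for imputed sequence variants (the point below which imputed
#' dosages become unreliable), call rate 0.80, and `hwe_alpha` 1e-6.
#'
#' @param genotypes a `geno_matrix`.
#' @param panel `"chip"` or `"wgs"`; sets the default `maf_min`.
#' @param maf_min,call_rate_min,hwe_alpha QC thresholds.
#' @return logical mask over the variants of `genotypes`.
#' @export
qc_filter <- function(genotypes, panel = c("chip", "wgs"),
                      maf_min = NULL, call_rate_min = 0.80,
                      hwe_alpha = 1e-6) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  panel <- match.arg(panel)
  maf_min <- maf_min %||% if (panel == "chip") 0.01 else 0.023
  assert_scalar_number(maf_min, "maf_min", 0, 1)
  assert_scalar_number(call_rate_min, "call_rate_min", 0, 1)
  lines <- unique(genotypes$line)
  mask <- rep(TRUE, ncol(genotypes$dosages))
  for (l in lines) {
    dos <- genotypes$dosages[genotypes$line == l, , drop = FALSE]
    mask <- mask & qc_mask_one_line(dos, maf_min, call_rate_min, hwe_alpha)
  }
  if (panel == "chip") mask <- mask & genotypes$map$is_chip
  names(mask) <- genotypes$map$variant_id
  mask
}

#' Assign variants to consecutive non-overlapping genomic windows
#'
#' Windows are anchored at position 1 on each chromosome and are half-open
#' on the left in ordinal terms: with the default 55-kb windows, positions
#' 1..55000 fall in window 0 and position 55001 starts window 1.
#'
#' @param variants data frame with columns `variant_id`, `chrom`, `pos`
#'   (e.g. a `geno_matrix$map` or a `gwas_result`).
#' @param window_size_bp window size in bp (default 55000).
#' @return data frame (`variant_id`, `chrom`, `window`).
#' @export
window_index <- function(variants, window_size_bp = 55000L) {
  assert_scalar_number(window_size_bp, "window_size_bp", 1)
  if (any(variants$pos < 1)) {
    stop_seqgp("positions must be >= 1", "input_error")
  }
  data.frame(variant_id = variants$variant_id,
             chrom = variants$chrom,
             window = (variants$pos - 1L) %/% as.integer(window_size_bp),
             stringsAsFactors = FALSE)
}

# order a gwas result so that the per-window best variant comes first:
# by increasing p, ties by smaller position, then lexicographic id
order_for_selection <- function(gw) {
  order(gw$p, gw$pos, gw$variant_id)
}

#' Top-per-window variant preselection
#'
#' Selects, in each non-empty window, the tested variant with the lowest
#' p-value (not necessarily significant), with ties broken by smaller
#' position and then by id. When `target_count` is given, the window size
#' is rescaled as `55000 * 40000 / target_count` so that the expected
#' number of non-empty windows matches the target (mirroring the 10k to
#' 100k density variants of the 40k-per-55kb rule); alternatively
#' `method = "rank"` takes the `target_count` globally smallest p-values.
#'
#' @param gwas a `gwas_result` covering the sequence panel.
#' @param window_size_bp base window size (default 55000).
#' @param target_count optional target number of selected variants.
#' @param method `"window"` (default, window rescaling) or `"rank"`.
#' @param name optional set name; defaults to `"Top<k>k"` style.
#' @return a `variant_set` with provenance `"wgs_topwindow"`.
#' @export
select_top_per_window <- function(gwas, window_size_bp = 55000L,
                                  target_count = NULL,
                                  method = c("window", "rank"),
                                  name = NULL) {
  method <- match.arg(method)
  gw <- gwas[gwas$tested & !is.na(gwas$p), , drop = FALSE]
  if (!is.null(target_count) && method == "window") {
    window_size_bp <- as.integer(round(55000 * 40000 / target_count))
  }
  if (method == "rank") {
    if (is.null(target_count)) {
      stop_seqgp("method = \"rank\" requires target_count", "config_error")
    }
    gw <- gw[order_for_selection(gw), , drop = FALSE]
    ids <- gw$variant_id[seq_len(min(target_count, nrow(gw)))]
  } else {
    win <- window_index(gw, window_size_bp)
    key <- paste(win$chrom, win$window)
    o <- order_for_selection(gw)
    first <- o[!duplicated(key[o])]
    first <- sort(first)  # keep genome order
    ids <- gw$variant_id[first]
  }
  name <- name %||% sprintf("Top%dk", round(length(ids) / 1000))
  new_variant_set(name, ids, rep("wgs_topwindow", length(ids)),
                  window_size_bp = window_size_bp)
}

#' Chip-plus-significant variant preselection
#'
#' From the sequence panel, keeps variants with `p <= p_threshold`; within
#' each window only the lowest-p significant variant is retained as a proxy
#' for the local association; the proxies are merged with the chip set. A
#' significant variant already on the chip is counted once (it keeps its
#' chip provenance). Lowering the threshold can never grow the set, and the
#' result always contains every chip variant.
#'
#' @param gwas a `gwas_result` covering the sequence panel.
#' @param chip a `variant_set` of chip variants (non-empty).
#' @param window_size_bp window size (default 55000).
#' @param p_threshold significance threshold (default 1e-6).
#' @return a `variant_set` named `"ChipPlusSign"`.
#' @export
select_chip_plus_sign <- function(gwas, chip, window_size_bp = 55000L,
                                  p_threshold = 1e-6) {
  stopifnot(inherits(chip, "variant_set"))
  if (!length(chip$variant_ids)) {
    stop_seqgp("chip set must be non-empty", "config_error")
  }
  sig <- gwas[gwas$tested & !is.na(gwas$p) & gwas$p <= p_threshold, ,
              drop = FALSE]
  if (nrow(sig)) {
    win <- window_index(sig, window_size_bp)
    key <- paste(win$chrom, win$window)
    o <- order_for_selection(sig)
    first <- o[!duplicated(key[o])]
    proxies <- sig$variant_id[sort(first)]
  } else {
    proxies <- character(0)
  }
  added <- setdiff(proxies, chip$variant_ids)
  ids <- c(chip$variant_ids, added)
  prov <- c(rep("chip", length(chip$variant_ids)),
            rep("wgs_significant", length(added)))
  new_variant_set("ChipPlusSign", ids, prov,
                  window_size_bp = window_size_bp,
                  p_threshold = p_threshold)
}

#' Multi-line variant universe
#'
#' Computes the two variant masks of the multi-line design over a list of
#' per-line genotype panels sharing one variant map: the intersection mask
#' (variants segregating and passing sequence QC in every line, the
#' candidate universe for ML-Top40k / ML-ChipPlusSign) and the chip union
#' mask (chip variants passing chip QC in at least one line, the ML-Chip
#' benchmark panel).
#'
#' @param genos_by_line list of `geno_matrix`, one per line, with
#'   identical variant maps.
#' @param maf_min_wgs,maf_min_chip MAF thresholds for the two panels.
#' @param call_rate_min,hwe_alpha shared QC thresholds.
#' @return list with logical masks `intersection` and `union_chip`.
#' @export
ml_variant_universe <- function(genos_by_line, maf_min_wgs = 0.023,
                                maf_min_chip = 0.01, call_rate_min = 0.80,
                                hwe_alpha = 1e-6) {
  stopifnot(length(genos_by_line) >= 1L)
  map0 <- genos_by_line[[1L]]$map
  inter <- rep(TRUE, nrow(map0))
  uni <- rep(FALSE, nrow(map0))
  for (g in genos_by_line) {
    if (!identical(g$map$variant_id, map0$variant_id)) {
      stop_seqgp("per-line panels must share one variant map",
                 "integrity_error")
    }
    m_wgs <- qc_mask_one_line(g$dosages, maf_min_wgs, call_rate_min,
                              hwe_alpha)
    m_chip <- qc_mask_one_line(g$dosages, maf_min_chip, call_rate_min,
                               hwe_alpha) & g$map$is_chip
    inter <- inter & m_wgs
    uni <- uni | m_chip
  }
  list(intersection = inter, union_chip = uni)
}

#' Predictor dosages for a variant set, resolving chip/WGS discordance
#'
#' Builds the dosage matrix for the variants of a set. When a separate chip
#' genotype source is supplied (relevant only when genotype noise has made
#' the two sources disagree), entries of shared variants on which the two
#' sources disagree are replaced by the mean dosage of the individual's
#' line.
#'
#' @param genotypes the sequence-panel `geno_matrix`.
#' @param set a `variant_set`.
#' @param chip_genotypes optional `geno_matrix` holding the array dosages.
#' @return numeric dosage matrix, individuals x set variants.
#' @export
set_dosages <- function(genotypes, set, chip_genotypes = NULL) {
  stopifnot(inherits(set, "variant_set"))
  ci <- match(set$variant_ids, genotypes$map$variant_id)
  if (anyNA(ci)) {
    stop_seqgp("variant set contains ids absent from the panel",
               "schema_error")
  }
  X <- genotypes$dosages[, ci, drop = FALSE]
  storage.mode(X) <- "double"
  if (!is.null(chip_genotypes)) {
    shared <- intersect(set$variant_ids, chip_genotypes$map$variant_id)
    if (length(shared)) {
      Xc <- chip_genotypes$dosages[rownames(X),
                                   match(shared, chip_genotypes$map$variant_id),
                                   drop = FALSE]
      storage.mode(Xc) <- "double"
      cols <- match(shared, set$variant_ids)
      Xs <- X[, cols, drop = FALSE]
      disc <- !is.na(Xs) & !is.na(Xc) & Xs != Xc
      if (any(disc)) {
        lines <- genotypes$line[rownames(X)]
        for (l in unique(lines)) {
          inl <- lines == l
          mu <- colMeans(Xs[inl, , drop = FALSE], na.rm = TRUE)
          repl <- disc & inl  # recycles inl down the columns
          Xs[repl] <- mu[col(Xs)[repl]]
        }
        X[, cols] <- Xs
      }
    }
  }
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    na <- which(is.na(X), arr.ind = TRUE)
    X[na] <- mu[na[, 2L]]
  }
  X
}
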