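# The study design: family-based test sets, relationship-pruned training
# sets, training-set reduction, family-exclusive replicate splits, and the
# accuracy / bias / accuracy-difference analyses.

#' Define the full-sib family test set
#'
#' The testing set consists of individuals of the last generation of their
#' line that have no progeny of their own, grouped into full-sib families
#' (same sire and same dam); only families with at least `min_family_size`
#' members are kept. This mimics evaluating the selection candidates
#' available in a nucleus at a given time.
#'
#' @param pedigree a valid pedigree.
#' @param min_family_size minimum number of full sibs per family
#'   (default 5).
#' @return a data frame (`id`, `family`, `line`); `family` is
#'   `"<sire>x<dam>"`. Signals `seqgp_empty_test_error` if no family
#'   qualifies.
#' @export
define_test_set <- function(pedigree, min_family_size = 5L) {
  validate_pedigree(pedigree)
  has_progeny <- pedigree$id %in% c(pedigree$sire, pedigree$dam)
  out <- list()
  for (l in unique(pedigree$line)) {
    inl <- pedigree$line == l
    last_gen <- max(pedigree$generation[inl])
    cand <- inl & pedigree$generation == last_gen & !has_progeny &
      !is.na(pedigree$sire)
    if (!any(cand)) next
    fam <- paste0(pedigree$sire[cand], "x", pedigree$dam[cand])
    sizes <- table(fam)
    keep <- fam %in% names(sizes)[sizes >= min_family_size]
    if (!any(keep)) next
    out[[l]] <- data.frame(id = pedigree$id[cand][keep],
                           family = fam[keep], line = l,
                           stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    stop_seqgp(sprintf("no full-sib family of size >= %d without progeny",
                       min_family_size), "empty_test_error")
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Define the relationship-pruned training set
#'
#' The training set contains the phenotyped individuals whose pedigree
#' relationship with every test individual is below `rel_threshold`
#' (default 0.5, which excludes full sibs, parents and progeny of test
#' individuals, and the test individuals themselves since `a(i,i) >= 1`).
#'
#' @param A numerator relationship matrix covering all individuals.
#' @param test_ids ids of the test individuals.
#' @param phenotyped_ids ids with a usable response for the trait.
#' @param rel_threshold strict upper bound on the relationship.
#' @return character vector of training ids.
#' @export
define_training_set <- function(A, test_ids, phenotyped_ids,
                                rel_threshold = 0.5) {
  ids <- rownames(A)
  if (!all(test_ids %in% ids) || !all(phenotyped_ids %in% ids)) {
    stop_seqgp("A must cover all test and phenotyped individuals",
               "input_error")
  }
  cand <- union(phenotyped_ids, character(0))
  rel <- A[cand, test_ids, drop = FALSE]
  maxrel <- apply(rel, 1L, max)
  # a(i,i) >= 1 for test members themselves, so they are excluded by the
  # threshold automatically
  train <- cand[maxrel < rel_threshold]
  train <- setdiff(train, test_ids)
  if (!length(train)) {
    stop_seqgp("training set is empty after relationship pruning",
               "infeasible_design_error")
  }
  train
}

#' Reduce a training set to the most recent records
#'
#' Emulates shrinking the training data by removing the oldest animals:
#' keeps the `target_n` individuals with the largest `birth_order` (ties
#' broken by id for determinism).
#'
#' @param train_ids current training ids.
#' @param pedigree pedigree providing `birth_order`.
#' @param target_n number of records to keep; a no-op if it is at least
#'   the current training size.
#' @return character vector of retained ids (sorted by id).
#' @export
reduce_training <- function(train_ids, pedigree, target_n) {
  assert_scalar_number(target_n, "target_n", 1)
  if (target_n >= length(train_ids)) return(sort(train_ids))
  bo <- pedigree$birth_order[match(train_ids, pedigree$id)]
  if (anyNA(bo)) stop_seqgp("train ids missing from pedigree", "input_error")
  o <- order(-bo, train_ids)
  sort(train_ids[o[seq_len(target_n)]])
}

#' Family-exclusive replicate split of the test set
#'
#' Randomly assigns full-sib families to `k` replicate subsets, balancing
#' the number of families per subset to within one, so that every family
#' appears in exactly one replicate.
#'
#' @param test_set data frame from [define_test_set()].
#' @param k number of replicates (default 5).
#' @param seed integer seed.
#' @return list of `k` data frames partitioning `test_set`.
#' @export
replicate_split <- function(test_set, k = 5L, seed = 1L) {
  fams <- unique(test_set$family)
  if (length(fams) < k) {
    stop_seqgp(sprintf("%d families cannot fill %d replicates",
                       length(fams), k), "config_error")
  }
  set.seed(seed)
  assign <- sample(rep_len(seq_len(k), length(fams)))
  names(assign) <- sample(fams)  # decouple assignment from input order
  lapply(seq_len(k), function(r) {
    sub <- test_set[assign[test_set$family] == r, , drop = FALSE]
    rownames(sub) <- NULL
    sub
  })
}

#' Prediction accuracy
#'
#' Pearson correlation between predicted genomic breeding values and the
#' evaluation response (dEBV, or true breeding values in simulations).
#' Returns `NA` with a warning when either vector is constant, rather than
#' zero, so undefined scenarios cannot silently deflate averages.
#'
#' @param gebv,response numeric vectors over the same test individuals.
#' @return Pearson correlation in \[-1, 1\], or `NA_real_` if undefined.
#' @export
accuracy <- function(gebv, response) {
  if (length(gebv) != length(response) || length(gebv) < 3L) {
    stop_seqgp("accuracy needs >= 3 paired values", "input_error")
  }
  if (stats::sd(gebv) == 0 || stats::sd(response) == 0) {
    warning("constant vector: accuracy undefined")
    return(NA_real_)
  }
  stats::cor(gebv, response)
}

#' Prediction bias
#'
#' Slope of the ordinary least-squares regression of the response on the
#' GEBV; 1 indicates neither inflation nor deflation of the predictions.
#'
#' @param gebv,response numeric vectors over the same test individuals.
#' @return regression slope, or `NA_real_` when `var(gebv)` is zero.
#' @export
bias <- function(gebv, response) {
  if (length(gebv) != length(response)) {
    stop_seqgp("bias needs paired vectors", "input_error")
  }
  if (stats::sd(gebv) == 0) {
    warning("zero-variance GEBV: bias undefined")
    return(NA_real_)
  }
  stats::cov(response, gebv) / stats::var(gebv)
}

#' Regression analysis of accuracy differences
#'
#' Given an evaluation table with one row per scenario (columns
#' `variant_set`, `accuracy`, `n_train`, plus optional `trait`, `line`,
#' `replicate`), computes the per-scenario difference between each
#' sequence-derived set and the chip benchmark (matched on trait, line,
#' training size and replicate) and fits the ordinary least-squares model
#' `difference ~ n_train (+ trait + line)`. Reported are the regression
#' coefficient of training-set size, its p-value, and the model R-squared.
#'
#' @param reports evaluation data frame.
#' @param benchmark name of the benchmark set (default "Chip").
#' @return list with `differences` (data frame) and, per comparison set,
#'   `slope`, `p_value`, `r_squared` and the fitted `lm` object.
#' @export
compare_scenarios <- function(reports, benchmark = "Chip") {
  req <- c("variant_set", "accuracy", "n_train")
  if (!all(req %in% names(reports))) {
    stop_seqgp(paste("reports must have columns:", paste(req, collapse = ", ")),
               "input_error")
  }
  keys <- intersect(c("trait", "line", "n_train", "replicate"),
                    names(reports))
  key_of <- function(df) do.call(paste, c(df[keys], sep = "\r"))
  bench <- reports[reports$variant_set == benchmark, , drop = FALSE]
  if (!nrow(bench)) {
    stop_seqgp(sprintf("no '%s' benchmark rows", benchmark), "input_error")
  }
  others <- reports[reports$variant_set != benchmark, , drop = FALSE]
  idx <- match(key_of(others), key_of(bench))
  if (anyNA(idx)) {
    stop_seqgp("every scenario needs a matching benchmark row", "input_error")
  }
  diffs <- others
  diffs$difference <- others$accuracy - bench$accuracy[idx]

  fits <- list()
  for (vs in unique(diffs$variant_set)) {
    sub <- diffs[diffs$variant_set == vs & !is.na(diffs$difference), ,
                 drop = FALSE]
    if (nrow(sub) < 3L) next
    terms <- "n_train"
    for (fx in c("trait", "line")) {
      if (fx %in% names(sub) && length(unique(sub[[fx]])) > 1L) {
        terms <- c(terms, fx)
      }
    }
    fml <- stats::as.formula(paste("difference ~", paste(terms, collapse = " + ")))
    fit <- stats::lm(fml, data = sub)
    if (stats::var(sub$difference) == 0) {
      # degenerate: nothing to explain
      fits[[vs]] <- list(slope = 0, p_value = 1, r_squared = 0, fit = fit)
      next
    }
    sm <- summary(fit)
    co <- stats::coef(sm)
    fits[[vs]] <- list(
      slope = co["n_train", "Estimate"],
      p_value = co["n_train", "Pr(>|t|)"],
      r_squared = sm$r.squared,
      fit = fit
    )
  }
  list(differences = diffs, fits = fits)
}
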