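# Simulation of multi-line pedigreed populations: pedigree structure,
# founder haplotypes with markovian LD, gene dropping with recombination,
# nested chip panels, and additive traits.

#' Genome configuration
#'
#' Describes the synthetic genome used by the founder-haplotype generator and
#' the gene-dropping engine. Coordinates are 1-based.
#'
#' @param n_chromosomes number of chromosomes.
#' @param chromosome_length_bp physical length of each chromosome in bp.
#' @param variants_per_chromosome number of variants simulated per chromosome.
#' @param recombination_rate recombination rate in Morgan per bp. The default
#'   1e-8 corresponds to the usual 1 cM/Mb.
#' @param founder_ld_decay decay constant of the correlation between adjacent
#'   founder alleles: the correlation between alleles at distance `d` bp is
#'   `exp(-founder_ld_decay * d)`. The default 2e-5 (decay length 50 kb)
#'   yields chip-tags-sequence LD comparable to dense livestock panels.
#' @return an object of class `genome_config`.
#' @export
genome_config <- function(n_chromosomes = 5,
                          chromosome_length_bp = 1e8,
                          variants_per_chromosome = 2000,
                          recombination_rate = 1e-8,
                          founder_ld_decay = 2e-5) {
  assert_scalar_number(n_chromosomes, "n_chromosomes", 1)
  assert_scalar_number(chromosome_length_bp, "chromosome_length_bp", 1)
  assert_scalar_number(variants_per_chromosome, "variants_per_chromosome", 1)
  assert_scalar_number(recombination_rate, "recombination_rate", 0)
  assert_scalar_number(founder_ld_decay, "founder_ld_decay", 0)
  structure(list(
    n_chromosomes = as.integer(n_chromosomes),
    chromosome_length_bp = as.integer(chromosome_length_bp),
    variants_per_chromosome = as.integer(variants_per_chromosome),
    recombination_rate = recombination_rate,
    founder_ld_decay = founder_ld_decay
  ), class = "genome_config")
}

#' Validate a pedigree table
#'
#' Checks the structural invariants of a pedigree: parents of non-founders
#' are present with strictly smaller generation, founders have both parents
#' missing, no individual is its own ancestor, and litters (same sire, dam
#' and generation) are coherent.
#'
#' @param pedigree a data frame with columns `id`, `sire`, `dam`, `line`,
#'   `generation`, `birth_order` (and optionally `sex`).
#' @return the pedigree, invisibly; signals a `seqgp_integrity_error`
#'   otherwise.
#' @export
validate_pedigree <- function(pedigree) {
  req <- c("id", "sire", "dam", "line", "generation", "birth_order")
  if (!all(req %in% names(pedigree))) {
    stop_seqgp(paste0("pedigree must have columns: ",
                      paste(req, collapse = ", ")), "integrity_error")
  }
  if (anyDuplicated(pedigree$id)) {
    stop_seqgp("duplicated individual ids in pedigree", "integrity_error")
  }
  gen <- pedigree$generation
  idx <- seq_len(nrow(pedigree))
  names(idx) <- pedigree$id
  for (col in c("sire", "dam")) {
    par <- pedigree[[col]]
    known <- !is.na(par)
    if (any(known & !(par %in% pedigree$id))) {
      stop_seqgp(sprintf("pedigree references unknown %ss", col),
                 "integrity_error")
    }
    if (any(gen[idx[par[known]]] >= gen[known])) {
      stop_seqgp(sprintf("%s of a non-founder must have a smaller generation",
                         col), "integrity_error")
    }
  }
  founder <- is.na(pedigree$sire) & is.na(pedigree$dam)
  half <- xor(is.na(pedigree$sire), is.na(pedigree$dam))
  if (any(half)) {
    stop_seqgp("individuals must have both or neither parent recorded",
               "integrity_error")
  }
  # generation monotonicity along parent links already implies acyclicity
  invisible(pedigree)
}

#' Simulate a closed-line pedigree
#'
#' Builds a multi-generation pedigree for one closed line: a founder
#' generation with no parents, followed by discrete generations in which a
#' fixed number of sires and dams is selected at random from the previous
#' generation and each selected dam produces one full-sib litter by a
#' randomly assigned selected sire. The last generation therefore consists
#' of full-sib families, as required by the family-based testing design.
#'
#' @param n_founders number of founders (generation 0), split roughly
#'   half male / half female.
#' @param n_generations number of descendant generations (0 gives a
#'   founders-only pedigree).
#' @param n_sires,n_dams number of sires and dams selected as parents in
#'   each generation.
#' @param litter_size litter-size distribution: a list with elements
#'   `dist` (`"fixed"` or `"poisson"`), `mean`, and for `"poisson"` an
#'   optional truncation `min` (default 2). The distribution must be able to
#'   produce litters of at least five full sibs.
#' @param line line label attached to every individual.
#' @param seed integer seed; the same seed and configuration reproduce the
#'   pedigree exactly.
#' @return a data frame with columns `id`, `sire`, `dam`, `line`,
#'   `generation`, `birth_order`, `sex`. `birth_order` is a strict total
#'   order within the line (the simulated birth sequence).
#' @export
simulate_pedigree <- function(n_founders,
                              n_generations,
                              n_sires,
                              n_dams,
                              litter_size = list(dist = "poisson", mean = 10),
                              line = "A",
                              seed = 1L) {
  assert_scalar_number(n_founders, "n_founders", 2)
  assert_scalar_number(n_generations, "n_generations", 0)
  assert_scalar_number(n_sires, "n_sires", 1)
  assert_scalar_number(n_dams, "n_dams", 1)
  if (!is.list(litter_size) || is.null(litter_size$dist)) {
    stop_seqgp("`litter_size` must be a list with elements dist and mean",
               "config_error")
  }
  if (litter_size$dist == "fixed" && litter_size$mean < 5 && n_generations > 0) {
    stop_seqgp("fixed litter size must be at least 5 so that full-sib test families can exist",
               "config_error")
  }

  set.seed(seed)
  draw_litter_sizes <- function(k) {
    if (litter_size$dist == "fixed") {
      rep(as.integer(litter_size$mean), k)
    } else if (litter_size$dist == "poisson") {
      pmax(litter_size$min %||% 2L, stats::rpois(k, litter_size$mean))
    } else {
      stop_seqgp("unknown litter size distribution", "config_error")
    }
  }

  counter <- 0L
  make_ids <- function(k) {
    ids <- sprintf("%s_%06d", line, counter + seq_len(k))
    counter <<- counter + k
    ids
  }

  founder_ids <- make_ids(n_founders)
  founder_sex <- rep_len(c("M", "F"), n_founders)
  recs <- list(data.frame(
    id = founder_ids, sire = NA_character_, dam = NA_character_,
    line = line, generation = 0L,
    birth_order = seq_len(n_founders), sex = founder_sex,
    stringsAsFactors = FALSE
  ))

  prev <- recs[[1L]]
  for (g in seq_len(n_generations)) {
    males <- prev$id[prev$sex == "M"]
    females <- prev$id[prev$sex == "F"]
    if (length(males) < n_sires || length(females) < n_dams) {
      stop_seqgp(sprintf(
        "generation %d: %d sires and %d dams requested but only %d males and %d females available",
        g, n_sires, n_dams, length(males), length(females)),
        "infeasible_design_error")
    }
    sires <- sample(males, n_sires)
    dams <- sample(females, n_dams)
    sizes <- draw_litter_sizes(length(dams))
    litter_sire <- sample(sires, length(dams), replace = TRUE)
    n_off <- sum(sizes)
    ids <- make_ids(n_off)
    off <- data.frame(
      id = ids,
      sire = rep(litter_sire, sizes),
      dam = rep(dams, sizes),
      line = line,
      generation = g,
      birth_order = max(prev$birth_order) + seq_len(n_off),
      sex = sample(c("M", "F"), n_off, replace = TRUE),
      stringsAsFactors = FALSE
    )
    recs[[g + 1L]] <- off
    prev <- off
  }
  ped <- do.call(rbind, recs)
  # birth_order restarts at 1 per call; make it globally strict within line
  ped$birth_order <- seq_len(nrow(ped))
  rownames(ped) <- NULL
  validate_pedigree(ped)
}

#' Generate a variant map
#'
#' Draws sorted unique variant positions per chromosome. Used internally by
#' [simulate_founders_and_drop()]; call it directly to share one map (the
#' common variant coordinate universe) across independently simulated
#' lines.
#'
#' @param genome a [genome_config()].
#' @param seed integer seed.
#' @return data frame (`variant_id`, `chrom`, `pos`, `is_chip`).
#' @export
make_variant_map <- function(genome, seed = 1L) {
  set.seed(seed)
  map <- do.call(rbind, lapply(seq_len(genome$n_chromosomes), function(cc) {
    pos <- sort(sample.int(genome$chromosome_length_bp,
                           genome$variants_per_chromosome))
    data.frame(variant_id = sprintf("%d_%d", cc, pos),
               chrom = cc, pos = pos, is_chip = FALSE,
               stringsAsFactors = FALSE)
  }))
  rownames(map) <- NULL
  map
}

# Founder haplotypes for one chromosome: first-order Markov chain over
# alleles with distance-dependent correlation, preserving per-variant
# marginal allele frequencies.  Returns an nh x m integer matrix.
founder_haplotypes_chr <- function(nh, p, pos, decay) {
  m <- length(p)
  h <- matrix(0L, nh, m)
  h[, 1L] <- stats::rbinom(nh, 1L, p[1L])
  if (m == 1L) return(h)
  q <- 1 - p
  sdp <- sqrt(p * q)
  for (k in 2:m) {
    rho <- exp(-decay * (pos[k] - pos[k - 1L]))
    lift <- rho * sdp[k] * sdp[k - 1L]
    c1 <- min(1, max(0, p[k] + lift / p[k - 1L]))
    c0 <- min(1, max(0, p[k] - lift / q[k - 1L]))
    prev <- h[, k - 1L]
    prob <- ifelse(prev == 1L, c1, c0)
    h[, k] <- as.integer(stats::runif(nh) < prob)
  }
  h
}

# One gamete from a parent's pair of haplotypes for one chromosome.
# Crossovers follow a Poisson process along the genetic map (Haldane, no
# interference).
gamete_chr <- function(h1, h2, pos, len_bp, rate) {
  n_xo <- stats::rpois(1L, len_bp * rate)
  start <- stats::runif(1) < 0.5
  if (n_xo == 0L) {
    return(if (start) h1 else h2)
  }
  xo <- sort(stats::runif(n_xo, 0, len_bp))
  seg <- findInterval(pos, xo)
  use1 <- (seg %% 2L == 0L) == start
  out <- h2
  out[use1] <- h1[use1]
  out
}

#' Simulate founder genotypes and gene-drop through a pedigree
#'
#' Draws founder haplotypes from a first-order Markov chain with
#' distance-dependent allele correlation (the stand-in for real linkage
#' disequilibrium), then drops genes through the pedigree: each gamete is
#' formed by recombining the parent's two haplotypes with crossovers from a
#' Poisson process along the genetic map (Haldane map function, no
#' interference). Every descendant genotype is Mendelian-consistent with its
#' parents' haplotypes by construction.
#'
#' @param pedigree a valid pedigree, see [simulate_pedigree()].
#' @param genome a [genome_config()].
#' @param seed integer seed.
#' @param keep_haplotypes if `TRUE`, the two haplotype matrices are retained
#'   in the result (memory heavy; intended for small toys and tests).
#' @param allele_freq_beta shape parameters of the Beta distribution from
#'   which founder allele frequencies are drawn (clamped to \[0.01, 0.99\]).
#' @param map optional precomputed variant map from [make_variant_map()];
#'   lets several independently simulated lines share one set of variant
#'   coordinates (the cross-line variant universe).
#' @return a `geno_matrix` object: integer dosage matrix (individuals x
#'   variants, entries 0/1/2), a variant map (`variant_id`, `chrom`, `pos`,
#'   `is_chip`), the per-individual line labels, and the genome
#'   configuration.
#' @export
simulate_founders_and_drop <- function(pedigree, genome, seed = 1L,
                                       keep_haplotypes = FALSE,
                                       allele_freq_beta = c(0.8, 0.8),
                                       map = NULL) {
  validate_pedigree(pedigree)
  if (!inherits(genome, "genome_config")) {
    stop_seqgp("`genome` must be a genome_config object", "config_error")
  }
  set.seed(seed)
  nc <- genome$n_chromosomes
  n <- nrow(pedigree)
  if (is.null(map)) map <- make_variant_map(genome, seed)
  m <- nrow(map)

  ord <- order(pedigree$generation, pedigree$birth_order)
  ped <- pedigree[ord, ]
  idx <- seq_len(n)
  names(idx) <- ped$id
  founder <- is.na(ped$sire)

  h1 <- matrix(0L, n, m)
  h2 <- matrix(0L, n, m)
  col_ranges <- split(seq_len(m), map$chrom)

  for (cc in seq_len(nc)) {
    cols <- col_ranges[[cc]]
    p <- pmin(0.99, pmax(0.01, stats::rbeta(length(cols),
                                            allele_freq_beta[1],
                                            allele_freq_beta[2])))
    nf <- sum(founder)
    hf <- founder_haplotypes_chr(2L * nf, p, map$pos[cols], genome$founder_ld_decay)
    h1[which(founder), cols] <- hf[seq_len(nf), , drop = FALSE]
    h2[which(founder), cols] <- hf[nf + seq_len(nf), , drop = FALSE]
  }

  pos_by_chr <- lapply(col_ranges, function(cols) map$pos[cols])
  for (i in which(!founder)) {
    si <- idx[[ped$sire[i]]]
    di <- idx[[ped$dam[i]]]
    for (cc in seq_len(nc)) {
      cols <- col_ranges[[cc]]
      h1[i, cols] <- gamete_chr(h1[si, cols], h2[si, cols], pos_by_chr[[cc]],
                                genome$chromosome_length_bp,
                                genome$recombination_rate)
      h2[i, cols] <- gamete_chr(h1[di, cols], h2[di, cols], pos_by_chr[[cc]],
                                genome$chromosome_length_bp,
                                genome$recombination_rate)
    }
  }

  dos <- h1 + h2
  # restore the caller's row order
  back <- match(pedigree$id, ped$id)
  dos <- dos[back, , drop = FALSE]
  rownames(dos) <- pedigree$id
  colnames(dos) <- map$variant_id
  line <- pedigree$line
  names(line) <- pedigree$id
  haps <- NULL
  if (keep_haplotypes) {
    haps <- list(h1 = h1[back, , drop = FALSE], h2 = h2[back, , drop = FALSE])
    dimnames(haps$h1) <- dimnames(haps$h2) <- dimnames(dos)
  }
  new_geno_matrix(dos, map, line, genome = genome, haplotypes = haps)
}

#' Flag a nested chip panel
#'
#' Marks `n_chip` variants as members of the marker-array ("chip") panel.
#' Eligible variants are those with minor allele frequency at least
#' `maf_min`; among them, variants are picked at evenly spaced ranks along
#' the genome map so that chip density is approximately uniform per
#' chromosome. The chip is always a subset of the full variant panel.
#'
#' @param genotypes a `geno_matrix`.
#' @param n_chip number of chip variants.
#' @param maf_min minimum minor allele frequency for chip membership
#'   (default 0.01, the usual array QC threshold).
#' @param seed accepted for interface symmetry; the even-spacing rule is
#'   deterministic and does not consume randomness.
#' @return the `geno_matrix` with `map$is_chip` set.
#' @export
designate_chip <- function(genotypes, n_chip, maf_min = 0.01, seed = NULL) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  assert_scalar_number(n_chip, "n_chip", 1)
  maf <- variant_maf(genotypes)
  eligible <- which(maf >= maf_min)
  if (length(eligible) < n_chip) {
    stop_seqgp(sprintf(
      "n_chip = %d but only %d variants have MAF >= %g",
      n_chip, length(eligible), maf_min), "infeasible_design_error")
  }
  picks <- unique(round(seq(1L, length(eligible), length.out = n_chip)))
  if (length(picks) < n_chip) {
    extra <- setdiff(seq_along(eligible), picks)
    picks <- sort(c(picks, extra[seq_len(n_chip - length(picks))]))
  }
  genotypes$map$is_chip <- FALSE
  genotypes$map$is_chip[eligible[picks]] <- TRUE
  genotypes
}

#' Simulate an additive trait
#'
#' Samples `n_qtn` causal variants (QTN) without replacement, draws their
#' allele substitution effects, computes centred true breeding values
#' (TBV) as the dosage-weighted sum of effects, and adds an independent
#' normal residual scaled so that the heritability
#' `var(TBV) / var(phenotype)` equals `h2` in expectation.
#'
#' @param genotypes a `geno_matrix`.
#' @param n_qtn number of causal variants.
#' @param h2 target narrow-sense heritability in (0, 1].
#' @param qtn_panel `"wgs_only"` restricts QTN to variants that are not on
#'   the chip (the premise that sequence data contain causal variants that
#'   arrays miss); `"any"` allows all polymorphic variants.
#' @param effect_dist either `"normal"` (standard normal effects, default)
#'   or a function `f(n)` returning `n` effect sizes.
#' @param seed integer seed.
#' @return an object of class `trait_sim`: `qtn_ids`, `qtn_effects`,
#'   `tbv`, `phenotype` (both named by individual), `target_h2`,
#'   `realized_h2`.
#' @export
simulate_trait <- function(genotypes, n_qtn, h2,
                           qtn_panel = c("wgs_only", "any"),
                           effect_dist = "normal",
                           seed = 1L) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  qtn_panel <- match.arg(qtn_panel)
  assert_scalar_number(h2, "h2", 0, 1, strict_lower = TRUE)
  assert_scalar_number(n_qtn, "n_qtn", 1)
  set.seed(seed)

  maf <- variant_maf(genotypes)
  eligible <- maf > 0
  if (qtn_panel == "wgs_only") eligible <- eligible & !genotypes$map$is_chip
  eligible <- which(eligible)
  if (length(eligible) < n_qtn) {
    stop_seqgp(sprintf("n_qtn = %d exceeds the %d eligible variants",
                       n_qtn, length(eligible)), "infeasible_design_error")
  }
  qtn <- sort(sample(eligible, n_qtn))
  eff <- if (is.function(effect_dist)) {
    effect_dist(n_qtn)
  } else if (identical(effect_dist, "normal")) {
    stats::rnorm(n_qtn)
  } else {
    stop_seqgp("`effect_dist` must be \"normal\" or a function", "config_error")
  }

  Xq <- genotypes$dosages[, qtn, drop = FALSE]
  storage.mode(Xq) <- "double"
  tbv <- as.vector(Xq %*% eff)
  tbv <- tbv - mean(tbv)
  vg <- popvar(tbv)
  if (vg == 0) {
    stop_seqgp("all sampled QTN are monomorphic in this population",
               "infeasible_design_error")
  }
  ve <- vg * (1 - h2) / h2
  phe <- tbv + if (ve > 0) stats::rnorm(length(tbv), 0, sqrt(ve)) else 0
  names(tbv) <- names(phe) <- rownames(genotypes$dosages)
  structure(list(
    qtn_ids = genotypes$map$variant_id[qtn],
    qtn_effects = eff,
    tbv = tbv,
    phenotype = phe,
    target_h2 = h2,
    realized_h2 = popvar(tbv) / popvar(phe)
  ), class = "trait_sim")
}

#' Inject random genotyping noise
#'
#' Optional stand-in for imputation error: each dosage is independently
#' replaced, with probability `flip_rate`, by one of the other two dosage
#' values, and set missing with probability `missing_rate`. Off by default
#' throughout the pipeline.
#'
#' @param genotypes a `geno_matrix`.
#' @param flip_rate per-entry probability of a dosage perturbation.
#' @param missing_rate per-entry probability of a missing dosage.
#' @param seed integer seed.
#' @return the perturbed `geno_matrix` (haplotypes, if present, are dropped
#'   because they no longer match the dosages).
#' @export
inject_genotype_noise <- function(genotypes, flip_rate = 0.01,
                                  missing_rate = 0, seed = 1L) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  set.seed(seed)
  d <- genotypes$dosages
  nm <- length(d)
  flip <- which(stats::runif(nm) < flip_rate)
  if (length(flip)) {
    shift <- sample(1:2, length(flip), replace = TRUE)
    d[flip] <- (d[flip] + shift) %% 3L
  }
  if (missing_rate > 0) {
    d[stats::runif(nm) < missing_rate] <- NA_integer_
  }
  genotypes$dosages <- d
  genotypes$haplotypes <- NULL
  genotypes
}

#' Check Mendelian consistency of dosages along a pedigree
#'
#' For every parent-offspring trio, verifies that each offspring dosage can
#' be formed from one allele of each parent (e.g. parents 0 and 0 can only
#' produce 0; parents 0 and 2 can only produce 1).
#'
#' @param genotypes a `geno_matrix`.
#' @param pedigree the pedigree of the genotyped individuals.
#' @return `TRUE` if no violation is found, otherwise a data frame of
#'   violations (`id`, `variant_id`).
#' @export
mendelian_check <- function(genotypes, pedigree) {
  d <- genotypes$dosages
  bad <- list()
  for (i in which(!is.na(pedigree$sire))) {
    kid <- d[pedigree$id[i], ]
    s <- d[pedigree$sire[i], ]
    dd <- d[pedigree$dam[i], ]
    lo <- (s >= 2) + (dd >= 2)        # minimum inheritable dosage
    hi <- 2 - ((s <= 0) + (dd <= 0))  # maximum inheritable dosage
    viol <- which(!is.na(kid) & (kid < lo | kid > hi))
    if (length(viol)) {
      bad[[length(bad) + 1L]] <- data.frame(
        id = pedigree$id[i],
        variant_id = colnames(d)[viol], stringsAsFactors = FALSE)
    }
  }
  if (!length(bad)) TRUE else do.call(rbind, bad)
}
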