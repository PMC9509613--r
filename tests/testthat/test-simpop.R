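test_that("pedigree simulation honours structure, degenerate cases and determinism", {
  ped <- simulate_pedigree(10, 1, 3, 2,
                           litter_size = list(dist = "fixed", mean = 5),
                           seed = 1)
  expect_silent(validate_pedigree(ped))
  expect_equal(sum(ped$generation == 0), 10)
  litters <- table(paste(ped$sire, ped$dam)[ped$generation == 1])
  expect_true(all(litters == 5))
  # litter members share sire, dam and generation by construction
  expect_equal(sort(unique(ped$generation)), c(0L, 1L))

  # founders only
  ped0 <- simulate_pedigree(8, 0, 1, 1, seed = 2)
  expect_true(all(is.na(ped0$sire)) && all(is.na(ped0$dam)))
  expect_equal(nrow(ped0), 8)

  # byte-identical reruns
  expect_identical(
    simulate_pedigree(10, 2, 3, 4, litter_size = list(dist = "poisson", mean = 6), seed = 9),
    simulate_pedigree(10, 2, 3, 4, litter_size = list(dist = "poisson", mean = 6), seed = 9))

  # infeasible designs and bad configs are rejected
  expect_error(simulate_pedigree(4, 1, 10, 2,
                                 litter_size = list(dist = "fixed", mean = 5)),
               class = "seqgp_infeasible_design_error")
  expect_error(simulate_pedigree(-1, 1, 1, 1), class = "seqgp_config_error")
  expect_error(simulate_pedigree(10, 1, 2, 2,
                                 litter_size = list(dist = "fixed", mean = 3)),
               class = "seqgp_config_error")
})

test_that("pedigree validation catches broken structures", {
  ped <- ped_inbred()
  bad <- ped; bad$sire[5] <- "nobody"
  expect_error(validate_pedigree(bad), class = "seqgp_integrity_error")
  bad <- ped; bad$generation[1] <- 3L  # parent no longer precedes child
  expect_error(validate_pedigree(bad), class = "seqgp_integrity_error")
  bad <- ped; bad$dam[5] <- NA  # half-recorded parents
  expect_error(validate_pedigree(bad), class = "seqgp_integrity_error")
})

test_that("gene dropping is Mendelian and reduces to intact haplotypes without recombination", {
  ped <- simulate_pedigree(6, 2, 2, 2,
                           litter_size = list(dist = "fixed", mean = 5),
                           seed = 5)
  g0 <- genome_config(n_chromosomes = 1, chromosome_length_bp = 1e6,
                      variants_per_chromosome = 20, recombination_rate = 0)
  geno <- simulate_founders_and_drop(ped, g0, seed = 6, keep_haplotypes = TRUE)
  expect_true(isTRUE(mendelian_check(geno, ped)))
  # zero recombination: each transmitted haplotype equals one parental
  # haplotype exactly (brute force over both choices)
  h1 <- geno$haplotypes$h1; h2 <- geno$haplotypes$h2
  for (i in which(!is.na(ped$sire))) {
    for (hp in list(list(h1[ped$id[i], ], ped$sire[i]),
                    list(h2[ped$id[i], ], ped$dam[i]))) {
      kid <- hp[[1]]; par <- hp[[2]]
      expect_true(identical(kid, h1[par, ]) || identical(kid, h2[par, ]),
                  label = sprintf("haplotype of %s from %s", ped$id[i], par))
    }
  }

  # with recombination, trios stay Mendelian-consistent
  g1 <- genome_config(n_chromosomes = 2, chromosome_length_bp = 1e7,
                      variants_per_chromosome = 50, recombination_rate = 1e-7)
  geno1 <- simulate_founders_and_drop(ped, g1, seed = 7)
  expect_true(isTRUE(mendelian_check(geno1, ped)))

  # homozygous x homozygous forcing at dosage 2
  par_dos <- geno1$dosages[ped$sire[!is.na(ped$sire)], , drop = FALSE] == 2 &
    geno1$dosages[ped$dam[!is.na(ped$dam)], , drop = FALSE] == 2
  kid_dos <- geno1$dosages[ped$id[!is.na(ped$sire)], , drop = FALSE]
  expect_true(all(kid_dos[par_dos] == 2))

  # unknown parents are an integrity error
  bad <- ped; bad$sire[7] <- "ghost"
  expect_error(simulate_founders_and_drop(bad, g1, seed = 1),
               class = "seqgp_integrity_error")

  # determinism
  expect_identical(simulate_founders_and_drop(ped, g1, seed = 8)$dosages,
                   simulate_founders_and_drop(ped, g1, seed = 8)$dosages)
})

test_that("offspring allele frequencies drift only within the binomial bound", {
  ped <- simulate_pedigree(200, 1, 50, 100,
                           litter_size = list(dist = "fixed", mean = 10),
                           seed = 11)
  g <- genome_config(n_chromosomes = 2, chromosome_length_bp = 1e7,
                     variants_per_chromosome = 250)
  geno <- simulate_founders_and_drop(ped, g, seed = 12)
  founders <- ped$id[ped$generation == 0]
  offspring <- ped$id[ped$generation == 1]
  expect_gte(length(offspring), 1000)
  pf <- colMeans(geno$dosages[founders, ]) / 2
  po <- colMeans(geno$dosages[offspring, ]) / 2
  expect_gte(mean(abs(po - pf) <= 0.05), 0.95)
})

test_that("chip designation nests, respects MAF and spreads over chromosomes", {
  geno <- small_pop()
  maf <- variant_maf(geno)
  expect_true(all(maf[geno$map$is_chip] >= 0.01))
  expect_equal(sum(geno$map$is_chip), 160)
  # chip is a subset of the panel by construction
  expect_true(all(geno$map$variant_id[geno$map$is_chip] %in%
                    geno$map$variant_id))

  # rare variants are never flagged
  rare <- which(maf < 0.01)
  expect_true(all(!geno$map$is_chip[rare]))

  # exhaustion: flag all eligible variants
  n_elig <- sum(maf >= 0.01)
  all_chip <- designate_chip(geno, n_elig)
  expect_equal(sum(all_chip$map$is_chip), n_elig)
  expect_error(designate_chip(geno, n_elig + 1),
               class = "seqgp_infeasible_design_error")

  # even spreading: 10 chromosomes, 100 chip variants -> 10 +/- 2 each
  ped <- simulate_pedigree(150, 0, 1, 1, seed = 31)
  g10 <- genome_config(n_chromosomes = 10, chromosome_length_bp = 1e7,
                       variants_per_chromosome = 120)
  geno10 <- designate_chip(
    simulate_founders_and_drop(ped, g10, seed = 32), 100)
  per_chr <- table(geno10$map$chrom[geno10$map$is_chip])
  expect_true(all(per_chr >= 8 & per_chr <= 12))
})

test_that("trait simulation hits its heritability and honours the QTN panel", {
  geno <- small_pop()

  tr1 <- simulate_trait(geno, 20, 1, seed = 1)
  expect_equal(tr1$phenotype, tr1$tbv)
  expect_equal(tr1$realized_h2, 1)

  # TBV is the centred dosage-weighted effect sum
  Xq <- geno$dosages[, match(tr1$qtn_ids, geno$map$variant_id)]
  tbv <- drop(Xq %*% tr1$qtn_effects)
  expect_equal(unname(tr1$tbv), unname(tbv - mean(tbv)))

  # single QTN: var(TBV) ~ 2 p (1-p) a^2 under random mating
  tr2 <- simulate_trait(geno, 1, 0.5, qtn_panel = "any",
                        effect_dist = function(n) rep(1.5, n), seed = 22)
  p <- allele_freq(geno)[match(tr2$qtn_ids, geno$map$variant_id)]
  expect_lt(abs(var(tr2$tbv) / (2 * p * (1 - p) * 1.5^2) - 1), 0.25)

  # wgs_only keeps causal variants off the chip
  tr3 <- simulate_trait(geno, 50, 0.5, qtn_panel = "wgs_only", seed = 3)
  expect_false(any(tr3$qtn_ids %in% geno$map$variant_id[geno$map$is_chip]))

  # realized h2 concentrates on the target over replicates
  h2s <- vapply(1:50, function(s)
    simulate_trait(geno, 100, 0.3, seed = s)$realized_h2, numeric(1))
  expect_gt(mean(h2s), 0.27)
  expect_lt(mean(h2s), 0.33)

  expect_error(simulate_trait(geno, 10, 0), class = "seqgp_config_error")
  expect_error(simulate_trait(geno, 1e6, 0.5),
               class = "seqgp_infeasible_design_error")
})

test_that("genotype noise injection perturbs at the configured rate", {
  geno <- small_pop()
  noisy <- inject_genotype_noise(geno, flip_rate = 0.05,
                                 missing_rate = 0.01, seed = 4)
  frac_changed <- mean(noisy$dosages != geno$dosages, na.rm = TRUE)
  expect_gt(frac_changed, 0.03); expect_lt(frac_changed, 0.07)
  expect_gt(mean(is.na(noisy$dosages)), 0.005)
  expect_lt(mean(is.na(noisy$dosages)), 0.02)
  expect_true(all(noisy$dosages %in% c(0L, 1L, 2L, NA)))
})
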