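# Shared fixtures, built in code. Heavier populations are cached in this
# environment so several test files can reuse them within one run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# hand-written pedigree: 2 founder couples, full sibs, an inbred mating
# (offspring of two full sibs), 9 individuals
ped_inbred <- function() {
  data.frame(
    id   = c("s1", "d1", "s2", "d2", "a", "b", "c", "d", "x"),
    sire = c(NA, NA, NA, NA, "s1", "s1", "s2", "s2", "a"),
    dam  = c(NA, NA, NA, NA, "d1", "d1", "d2", "d2", "b"),
    line = "A",
    generation = c(0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L, 2L),
    birth_order = 1:9,
    stringsAsFactors = FALSE
  )
}

# three-generation pedigree with multiple litters (15 individuals)
ped_three_gen <- function() {
  simulate_pedigree(6, 2, 2, 2, litter_size = list(dist = "fixed", mean = 5),
                    line = "B", seed = 42)[1:15, ]
}

# pedigree whose last generation has full-sib families of sizes 6, 5, 3
ped_families <- function() {
  founders <- data.frame(
    id = sprintf("f%d", 1:6),
    sire = NA_character_, dam = NA_character_, line = "A",
    generation = 0L, birth_order = 1:6, stringsAsFactors = FALSE)
  kids <- data.frame(
    id = sprintf("k%02d", 1:14),
    sire = rep(c("f1", "f2", "f3"), c(6, 5, 3)),
    dam = rep(c("f4", "f5", "f6"), c(6, 5, 3)),
    line = "A", generation = 1L, birth_order = 6 + 1:14,
    stringsAsFactors = FALSE)
  rbind(founders, kids)
}

# small founder population with dense genotypes and a chip panel
small_pop <- function() {
  cached("small_pop", {
    ped <- simulate_pedigree(400, 0, 1, 1, seed = 101)
    g <- genome_config(n_chromosomes = 2, chromosome_length_bp = 2e7,
                       variants_per_chromosome = 400)
    geno <- simulate_founders_and_drop(ped, g, seed = 102)
    designate_chip(geno, 160)
  })
}

# a null_vc object with fixed variance components (no eigen step), used to
# probe the scan's GLS reduction against plain OLS
fixed_vc <- function(n, sigma_u2, sigma_e2) {
  structure(list(sigma_u2 = sigma_u2, sigma_e2 = sigma_e2,
                 delta = sigma_e2 / max(sigma_u2, 1e-300),
                 log_likelihood = NA_real_, U = diag(n),
                 lambda = rep(1, n), n = n), class = "null_vc")
}

# synthetic gwas_result table for preselection tests
fake_gwas <- function(n = 1000, n_chrom = 4, chrom_len = 5e5, seed = 7) {
  set.seed(seed)
  chrom <- sort(rep_len(seq_len(n_chrom), n))
  pos <- unlist(lapply(split(chrom, chrom), function(cc)
    sort(sample.int(chrom_len, length(cc)))), use.names = FALSE)
  out <- data.frame(
    variant_id = sprintf("%d_%d", chrom, pos),
    chrom = chrom, pos = pos,
    beta = rnorm(n), se = runif(n, 0.5, 1.5),
    p = runif(n)^3, n_used = 500L, tested = runif(n) > 0.02,
    stringsAsFactors = FALSE)
  out$p[!out$tested] <- NA
  out$beta[!out$tested] <- NA
  class(out) <- c("gwas_result", "data.frame")
  out
}
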