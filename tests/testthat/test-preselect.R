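test_that("qc_filter applies MAF, call-rate and HWE rules", {
  # 200 individuals, hand-built variants with known failure modes
  n <- 200
  set.seed(20)
  hwe_ok <- rbinom(n, 2, 0.5)
  rare <- c(rep(1L, 2), rep(0L, n - 2))                  # MAF 0.005
  maf02 <- c(rep(1L, 8), rep(0L, n - 8))                 # MAF 0.02
  het_excess <- rep(1L, n)                               # gross HWE violation
  lowcall <- rbinom(n, 2, 0.5); lowcall[1:60] <- NA      # call rate 0.7
  common <- rbinom(n, 2, 0.4)
  dos <- cbind(v1 = hwe_ok, v2 = rare, v3 = maf02, v4 = het_excess,
               v5 = lowcall, v6 = common)
  storage.mode(dos) <- "integer"
  rownames(dos) <- sprintf("i%03d", 1:n)
  map <- data.frame(variant_id = colnames(dos), chrom = 1L,
                    pos = seq(1000, 6000, 1000), is_chip = TRUE,
                    stringsAsFactors = FALSE)
  geno <- new_geno_matrix(dos, map, rep("A", n))

  chip_mask <- qc_filter(geno, "chip")
  expect_false(chip_mask[["v2"]])   # MAF 0.005 < 0.01
  expect_false(chip_mask[["v4"]])   # HWE
  expect_false(chip_mask[["v5"]])   # call rate 0.7 < 0.8
  expect_true(chip_mask[["v1"]] && chip_mask[["v6"]])

  wgs_mask <- qc_filter(geno, "wgs")
  expect_false(wgs_mask[["v3"]])    # MAF 0.02 < 0.023
  # complete, HWE-consistent common variants all pass
  expect_true(all(qc_filter(new_geno_matrix(
    dos[, c("v1", "v6")], map[c(1, 6), ], rep("A", n)), "wgs")))
})

test_that("window indexing follows the 1-anchored convention and a binning oracle", {
  v <- data.frame(variant_id = c("a", "b", "c"), chrom = 1L,
                  pos = c(1L, 55000L, 55001L), stringsAsFactors = FALSE)
  w <- window_index(v)
  expect_equal(w$window, c(0L, 0L, 1L))
  expect_error(window_index(data.frame(variant_id = "a", chrom = 1, pos = 0)),
               class = "seqgp_input_error")

  gw <- fake_gwas(1000)
  w2 <- window_index(gw, 37000L)
  # independent binning oracle
  expect_equal(w2$window, floor((gw$pos - 1) / 37000))
  expect_equal(anyDuplicated(paste(w2$variant_id)), 0)
})

test_that("top-per-window selection equals the exhaustive oracle, with ties and empty windows", {
  gw <- fake_gwas(100, n_chrom = 2, chrom_len = 5.5e5)  # 10 windows of 55kb
  # force a tie inside one window and an empty window
  gw$p[1:2] <- 1e-4
  gw <- gw[gw$pos < 4.4e5 | gw$chrom == 2, , drop = FALSE]  # empty windows on chr 1
  sel <- select_top_per_window(gw, 55000L)
  expect_equal(sort(sel$variant_ids), oracle_top_per_window(gw, 55000))
  expect_true(all(sel$provenance == "wgs_topwindow"))

  # idempotent and order-independent
  sel2 <- select_top_per_window(gw[sample(nrow(gw)), ], 55000L)
  expect_equal(sort(sel2$variant_ids), sort(sel$variant_ids))

  # exact tie on p: smaller position wins
  tie <- data.frame(variant_id = c("z", "a"), chrom = 1L,
                    pos = c(200L, 100L), beta = 0, se = 1,
                    p = c(1e-5, 1e-5), n_used = 10L, tested = TRUE,
                    stringsAsFactors = FALSE)
  expect_equal(select_top_per_window(tie, 55000L)$variant_ids, "a")

  # density targets rescale the window
  sel3 <- select_top_per_window(gw, target_count = 10000)
  expect_equal(sel3$window_size_bp, as.integer(round(55000 * 40000 / 10000)))
  sel4 <- select_top_per_window(gw, target_count = 20, method = "rank")
  expect_equal(length(sel4$variant_ids), 20)
  expect_equal(sort(sel4$variant_ids),
               sort(gw$variant_id[order(gw$p, gw$pos, gw$variant_id)][1:20]))
})

test_that("ChipPlusSign merges significant proxies onto the chip set", {
  gw <- fake_gwas(1000)
  gw$p <- pmax(gw$p, 1e-4)
  chip <- new_variant_set("Chip", gw$variant_id[seq(1, 1000, 10)],
                          rep("chip", 100))
  # plant significant variants: two in one window (chr 1), one on-chip
  gw$tested[c(5, 6, 501)] <- TRUE
  gw$p[5] <- 1e-7; gw$p[6] <- 1e-8                # same window
  gw$p[501] <- 1e-9                               # row 501 is a chip member
  w <- window_index(gw, 55000L)
  stopifnot(w$window[5] == w$window[6], w$chrom[5] == w$chrom[6])

  cps <- select_chip_plus_sign(gw, chip, 55000L, 1e-6)
  expect_true(all(chip$variant_ids %in% cps$variant_ids))
  added <- setdiff(cps$variant_ids, chip$variant_ids)
  # lowest-p proxy only: variant 6 beats variant 5
  expect_true(gw$variant_id[6] %in% cps$variant_ids)
  expect_false(gw$variant_id[5] %in% cps$variant_ids)
  # p = 1e-5 is not significant
  expect_false(any(gw$variant_id[gw$p > 1e-6 & gw$p < 1e-4] %in% added))
  # a significant variant already on the chip is counted once
  expect_equal(anyDuplicated(cps$variant_ids), 0)

  # no significant variants: output is exactly the chip
  gw0 <- gw; gw0$p <- pmax(gw0$p, 1e-3)
  cps0 <- select_chip_plus_sign(gw0, chip, 55000L, 1e-6)
  expect_identical(cps0$variant_ids, chip$variant_ids)

  # threshold monotonicity: lowering p never grows the set
  sizes <- vapply(c(1e-4, 1e-6, 1e-8, 1e-10), function(th)
    length(select_chip_plus_sign(gw, chip, 55000L, th)$variant_ids),
    numeric(1))
  expect_true(all(diff(sizes) <= 0))

  expect_error(select_chip_plus_sign(gw, new_variant_set("Chip", character(0),
                                                         character(0))),
               class = "seqgp_config_error")
})

test_that("selections are reproducible from persisted GWAS tables", {
  gw <- fake_gwas(500)
  path <- tempfile(fileext = ".tsv")
  write_gwas(gw, path, comments = "roundtrip")
  gw2 <- read_gwas(path)
  chip <- new_variant_set("Chip", gw$variant_id[1:50], rep("chip", 50))
  expect_identical(select_top_per_window(gw, 55000L)$variant_ids,
                   select_top_per_window(gw2, 55000L)$variant_ids)
  expect_identical(select_chip_plus_sign(gw, chip)$variant_ids,
                   select_chip_plus_sign(gw2, chip)$variant_ids)
})

test_that("multi-line variant universe distinguishes intersection and chip union", {
  n <- 150
  set.seed(30)
  mk <- function(p, line) {
    dos <- vapply(p, function(pp) rbinom(n, 2, pp), integer(n))
    colnames(dos) <- sprintf("1_%d", seq(1000, 1000 * length(p), 1000))
    rownames(dos) <- sprintf("%s%03d", line, 1:n)
    map <- data.frame(variant_id = colnames(dos), chrom = 1L,
                      pos = seq(1000, 1000 * length(p), 1000),
                      is_chip = c(TRUE, TRUE, FALSE, FALSE),
                      stringsAsFactors = FALSE)
    new_geno_matrix(dos, map, rep(line, n))
  }
  gA <- mk(c(0.5, 0.4, 0.3, 0.2), "A")
  gB <- mk(c(0.5, 0.0, 0.3, 0.2), "B")   # variant 2 monomorphic in B
  ml <- ml_variant_universe(list(gA, gB))
  expect_false(ml$intersection[2])       # not segregating in every line
  expect_true(ml$union_chip[2])          # chip variant passing QC in line A
  expect_true(ml$intersection[3] && ml$intersection[4])
  expect_false(ml$union_chip[3])         # not a chip variant

  # single line: masks reduce to that line's masks
  ml1 <- ml_variant_universe(list(gA))
  expect_equal(ml1$intersection,
               unname(qc_filter(gA, "wgs")))
  expect_equal(ml1$union_chip, unname(qc_filter(gA, "chip")))
})

test_that("set_dosages extracts panels and resolves injected discordance", {
  geno <- small_pop()
  chip <- chip_set(geno)
  X <- set_dosages(geno, chip)
  expect_equal(dim(X), c(nrow(geno$dosages), length(chip$variant_ids)))
  expect_equal(colnames(X), chip$variant_ids)

  # discordant chip copy: entries replaced by line-mean dosage
  chip_geno <- subset_geno(geno, variants = which(geno$map$is_chip))
  chip_geno$dosages[1, 1] <- (chip_geno$dosages[1, 1] + 1L) %% 3L
  X2 <- set_dosages(geno, chip, chip_genotypes = chip_geno)
  expect_equal(unname(X2[1, 1]), unname(mean(X[, 1])))
  expect_equal(X2[-1, ], X[-1, ])

  expect_error(set_dosages(geno, new_variant_set("bad", "nope", "chip")),
               class = "seqgp_schema_error")
})
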