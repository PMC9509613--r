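test_that("test-set definition keeps childless last-generation full-sib families", {
  ped <- ped_families()
  ts <- define_test_set(ped, 5)
  # families of 6 and 5 qualify, the family of 3 does not: 11 individuals
  expect_equal(nrow(ts), 11)
  expect_equal(length(unique(ts$family)), 2)
  expect_false(any(grepl("f3", ts$family)))

  # an individual with progeny is not eligible
  ped2 <- rbind(ped, data.frame(
    id = "gk1", sire = "k01", dam = "k07", line = "A", generation = 2L,
    birth_order = 21L, stringsAsFactors = FALSE))
  ts2 <- define_test_set(ped2, 1)
  expect_false(any(c("k01", "k07") %in% ts2$id))

  # family of 4 is excluded at the default threshold
  ped3 <- ped; ped3 <- ped3[!(ped3$id %in% c("k07", "k08")), ]  # family 2 -> 3 sibs
  ts3 <- define_test_set(ped3, 5)
  expect_equal(length(unique(ts3$family)), 1)

  expect_error(define_test_set(ped3, 10), class = "seqgp_empty_test_error")
})

test_that("training-set pruning matches a brute-force relationship scan", {
  ped <- ped_inbred()  # 9 individuals
  extra <- data.frame(id = c("u1", "u2", "u3"),
                      sire = NA_character_, dam = NA_character_, line = "A",
                      generation = 0L, birth_order = 10:12,
                      stringsAsFactors = FALSE)
  ped12 <- rbind(ped, extra)
  A <- pedigree_A(ped12)
  test_ids <- c("c", "d")
  phen <- setdiff(ped12$id, "x")
  train <- define_training_set(A, test_ids, phen)
  # brute force over the full matrix
  oracle <- phen[vapply(phen, function(i)
    max(A[i, test_ids]) < 0.5, logical(1))]
  expect_setequal(train, oracle)
  # full sibs and parents of test individuals are excluded
  expect_false(any(c("c", "d", "s2", "d2") %in% train))
  # unrelated founders are included
  expect_true(all(c("u1", "u2", "u3") %in% train))

  expect_error(define_training_set(A, test_ids, c("c", "d")),
               class = "seqgp_infeasible_design_error")
})

test_that("training reduction keeps the most recent records deterministically", {
  ped <- ped_families()
  ids <- sprintf("k%02d", 1:5)   # birth_order 7..11
  expect_setequal(reduce_training(ids, ped, 10), ids)
  expect_setequal(reduce_training(ids, ped, 2), c("k04", "k05"))
  expect_identical(reduce_training(sample(ids), ped, 3),
                   reduce_training(ids, ped, 3))
})

test_that("replicate splits are balanced family-exclusive partitions", {
  ped <- simulate_pedigree(40, 1, 10, 20,
                           litter_size = list(dist = "fixed", mean = 6),
                           seed = 50)
  ts <- define_test_set(ped, 5)
  expect_gte(length(unique(ts$family)), 15)
  sp <- replicate_split(ts, 5, seed = 3)
  expect_equal(length(sp), 5)
  all_ids <- unlist(lapply(sp, `[[`, "id"))
  expect_setequal(all_ids, ts$id)
  expect_equal(anyDuplicated(all_ids), 0)
  # no family across subsets
  fam_sub <- lapply(sp, function(s) unique(s$family))
  expect_equal(anyDuplicated(unlist(fam_sub)), 0)
  # balance within one family
  nf <- vapply(fam_sub, length, numeric(1))
  expect_lte(diff(range(nf)), 1)
  # determinism
  sp2 <- replicate_split(ts, 5, seed = 3)
  expect_identical(sp, sp2)
  # 5 families, k = 5: pigeonhole
  ts5 <- ts[ts$family %in% unique(ts$family)[1:5], ]
  sp5 <- replicate_split(ts5, 5, seed = 1)
  expect_true(all(vapply(sp5, function(s) length(unique(s$family)), numeric(1)) == 1))
  expect_error(replicate_split(ts5, 6, seed = 1),
               class = "seqgp_config_error")
})

test_that("accuracy and bias identities and transformation laws hold", {
  set.seed(60)
  d <- rnorm(20)
  expect_equal(accuracy(d, d), 1.0)
  expect_equal(accuracy(-d, d), -1.0)
  expect_equal(bias(d, d), 1.0)
  expect_equal(bias(2 * d, d), 0.5)

  # 5-pair hand-computed Pearson
  g <- c(1, 2, 3, 4, 5); r <- c(2, 1, 4, 3, 6)
  expect_equal(accuracy(g, r), sum((g - 3) * (r - 3.2)) /
                 sqrt(sum((g - 3)^2) * sum((r - 3.2)^2)))
  # 6-point closed-form OLS slope
  g6 <- c(0, 1, 2, 3, 4, 7); r6 <- c(1, 1, 3, 2, 6, 8)
  expect_equal(bias(g6, r6),
               sum((g6 - mean(g6)) * (r6 - mean(r6))) / sum((g6 - mean(g6))^2))

  # affine rescaling: accuracy invariant, bias scales as 1/a
  a <- 3.7; b <- -2
  expect_equal(accuracy(a * d + b, d), accuracy(d, d))
  expect_equal(bias(a * d + b, d), bias(d, d) / a)

  expect_warning(expect_true(is.na(accuracy(rep(1, 5), d[1:5]))))
  expect_warning(expect_true(is.na(bias(rep(1, 5), d[1:5]))))
  expect_error(accuracy(1:2, 1:2), class = "seqgp_input_error")
})

test_that("the accuracy-difference regression matches closed forms", {
  # all differences zero
  rep0 <- data.frame(
    variant_set = rep(c("Chip", "Top40k"), each = 4),
    trait = rep(c("t1", "t2"), 4), line = "A",
    n_train = rep(c(100, 200, 100, 200), 2),
    accuracy = rep(c(0.5, 0.6, 0.55, 0.65), 2))
  cmp0 <- compare_scenarios(rep0)
  expect_equal(cmp0$fits$Top40k$slope, 0)
  expect_equal(cmp0$fits$Top40k$r_squared, 0)

  # exact linear differences: slope recovered to machine precision
  rep1 <- rep0
  sel <- rep1$variant_set == "Top40k"
  rep1$accuracy[sel] <- rep1$accuracy[sel] + 1e-6 * rep1$n_train[sel]
  cmp1 <- compare_scenarios(rep1)
  expect_equal(cmp1$fits$Top40k$slope, 1e-6, tolerance = 1e-12)

  # randomized table equals the normal-equations oracle
  set.seed(61)
  tab <- expand.grid(trait = c("t1", "t2", "t3"), line = c("A", "B"),
                     n_train = c(500, 1000, 2000),
                     variant_set = c("Chip", "ChipPlusSign"),
                     stringsAsFactors = FALSE)
  tab$accuracy <- runif(nrow(tab), 0.3, 0.7)
  cmp <- compare_scenarios(tab)
  dd <- cmp$differences
  X <- model.matrix(~ n_train + trait + line, dd)
  co <- solve(crossprod(X), crossprod(X, dd$difference))
  expect_equal(cmp$fits$ChipPlusSign$slope, unname(co["n_train", 1]),
               tolerance = 1e-10)

  expect_error(compare_scenarios(tab[tab$variant_set != "Chip", ]),
               class = "seqgp_input_error")
})
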