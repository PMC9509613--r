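test_that("animal-model BLUP matches closed forms and the dense GLS oracle", {
  # unrelated single-record animals: EBV_i = h2 (y_i - mean(y)) exactly
  ped <- simulate_pedigree(30, 0, 1, 1, seed = 1)
  A <- pedigree_A(ped)
  set.seed(2); y <- rnorm(30, mean = 10)
  names(y) <- ped$id
  h2 <- 0.4
  res <- animal_model_blup(y, A, h2)
  expect_equal(res$ebv, h2 * (y[res$id] - mean(y)), ignore_attr = TRUE,
               tolerance = 1e-10)

  # strong shrinkage limit: h2 -> 0 sends every EBV to zero
  res0 <- animal_model_blup(y, A, 1e-6)
  expect_lt(max(abs(res0$ebv)), 1e-4)

  # structured pedigree (plus one unrelated founder): dense GLS oracle
  ped2 <- rbind(ped_inbred(), data.frame(
    id = "lone", sire = NA_character_, dam = NA_character_, line = "A",
    generation = 0L, birth_order = 10L, stringsAsFactors = FALSE))
  A2 <- pedigree_A(ped2)
  phen_ids <- c("a", "b", "c", "d", "x", "s1")
  set.seed(3); y2 <- rnorm(length(phen_ids)); names(y2) <- phen_ids
  h2 <- 0.35
  vy <- var(y2)
  res2 <- animal_model_blup(y2, A2, h2)
  Z <- matrix(0, length(y2), nrow(ped2))
  Z[cbind(seq_along(y2), match(phen_ids, ped2$id))] <- 1
  or <- oracle_blup(y2, matrix(1, length(y2), 1), Z, unclass(A2),
                    h2 * vy, (1 - h2) * vy)
  expect_equal(res2$ebv, unname(or$u[match(res2$id, ped2$id)]),
               tolerance = 1e-8)

  # MME residual identity via re-derivation: reliability in [0, 1)
  expect_true(all(res2$reliability >= 0 & res2$reliability < 1))
  # unphenotyped, unrelated individuals have EBV 0 and reliability 0
  i <- match("lone", res2$id)
  expect_equal(res2$ebv[i], 0, tolerance = 1e-10)
  expect_equal(res2$reliability[i], 0, tolerance = 1e-6)

  expect_error(animal_model_blup(y2, A2, 1.2), class = "seqgp_config_error")
  yy <- y2; yy[1] <- NA
  expect_error(animal_model_blup(yy, A2, 0.3), class = "seqgp_input_error")
})

test_that("deregression follows the stated parent-average formula", {
  # hand-computed spreadsheet oracle
  ped <- data.frame(
    id = c("s", "d", "k1", "k2"),
    sire = c(NA, NA, "s", "s"), dam = c(NA, NA, "d", "d"),
    line = "A", generation = c(0L, 0L, 1L, 1L), birth_order = 1:4,
    stringsAsFactors = FALSE)
  ebvs <- data.frame(id = c("s", "d", "k1", "k2"),
                     ebv = c(2, 1, 2.5, -0.5),
                     reliability = c(0.64, 0.36, 0.49, 0.49),
                     stringsAsFactors = FALSE)
  out <- deregress(ebvs, ped, min_reliability = 0)
  pa <- (2 + 1) / 2
  r2pa <- (0.64 + 0.36) / 4
  r2ms <- 0.49 - r2pa
  expect_equal(out$debv[out$id == "k1"], pa + (2.5 - pa) / r2ms)
  expect_equal(out$debv[out$id == "k2"], pa + (-0.5 - pa) / r2ms)
  # founders have no parents: PA = 0, r2_MS = reliability
  expect_equal(out$debv[out$id == "s"], 2 / 0.64)

  # reliability 1 and PA 0: deregression is the identity
  ebvs2 <- data.frame(id = ped$id, ebv = c(1, -1, 0.5, 0.2),
                      reliability = c(1 - 1e-9, 1 - 1e-9, 0.5, 0.5),
                      stringsAsFactors = FALSE)
  out2 <- deregress(ebvs2, ped, min_reliability = 0)
  expect_equal(out2$debv[out2$id == "s"], 1, tolerance = 1e-6)

  # variance inflation whenever reliability < 1
  expect_gt(var(out$debv), var(out$ebv))

  # low-reliability individuals are dropped, with a message
  ebvs3 <- ebvs; ebvs3$reliability[3] <- 0.26
  expect_message(out3 <- deregress(ebvs3, ped, min_reliability = 0.05))
  expect_false("k1" %in% out3$id)
})

test_that("deregression undoes shrinkage on unrelated single-record animals", {
  ped <- simulate_pedigree(60, 0, 1, 1, seed = 4)
  A <- pedigree_A(ped)
  set.seed(5); y <- rnorm(60); names(y) <- ped$id
  ebvs <- animal_model_blup(y, A, 0.4)
  out <- deregress(ebvs, ped, min_reliability = 0)
  # dEBV = EBV / reliability = y - mean(y) (PA = 0, rel ~ h2)
  expect_equal(out$debv[match(names(y), out$id)], unname(y - mean(y)),
               tolerance = 0.05)
  expect_gte(cor(out$debv[match(names(y), out$id)], y),
             cor(ebvs$ebv[match(names(y), ebvs$id)], y) - 1e-12)
})

test_that("trait_response bypass returns raw phenotypes for phenotyped ids", {
  ped <- ped_families()
  set.seed(6)
  ph <- rnorm(14); names(ph) <- sprintf("k%02d", 1:14)
  tab <- trait_response(ph, ped, bypass_deregression = TRUE)
  expect_equal(tab$y, unname(ph))
  expect_equal(tab$line, rep("A", 14))
  tab2 <- trait_response(ph, ped, h2 = 0.4, bypass_deregression = FALSE,
                         min_reliability = 0)
  expect_true(all(tab2$id %in% names(ph)))  # own phenotype required
})
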