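# Configuration handling and the end-to-end pipeline runner:
# simulate -> response -> QC -> GWAS -> preselect -> BayesR -> evaluate.

#' Default pipeline configuration
#'
#' Returns the full nested configuration with every tunable of the
#' pipeline. Any element can be overridden by the `...` arguments (given
#' as named nested lists which are merged over the defaults). The
#' configuration round-trips losslessly through JSON
#' ([write_run_config()] / [read_run_config()]), and every stochastic
#' stage derives its seed from the global `seed` by a documented fixed
#' offset (see [derive_seed()]).
#'
#' @param ... named overrides merged over the defaults.
#' @return a nested list of class `run_config`.
#' @export
default_run_config <- function(...) {
  cfg <- list(
    seed = 1L,
    genome = list(n_chromosomes = 5L, chromosome_length_bp = 1e8,
                  variants_per_chromosome = 2000L,
                  recombination_rate = 1e-8, founder_ld_decay = 2e-5),
    lines = list(list(name = "A", n_founders = 100L, n_generations = 2L,
                      n_sires = 25L, n_dams = 50L,
                      litter_size = list(dist = "poisson", mean = 10))),
    chip = list(n_chip = 400L, maf_min = 0.01),
    traits = list(list(name = "T1", h2 = 0.5, n_qtn = 50L,
                       qtn_panel = "wgs_only")),
    response = list(bypass_deregression = TRUE, h2_blup = 0.3,
                    min_reliability = 0.05),
    qc = list(chip_maf_min = 0.01, wgs_maf_min = 0.023,
              call_rate_min = 0.80, hwe_alpha = 1e-6),
    gwas = list(window_size_bp = 55000L, p_threshold = 1e-6),
    sets = list(top_targets = integer(0)),
    bayesr = list(n_iterations = 10000L, burn_in = 5000L, thin = 10L),
    evaluate = list(min_family_size = 5L, rel_threshold = 0.5,
                    reduced_training = integer(0), n_replicates = 1L),
    multi_line = TRUE
  )
  over <- list(...)
  merge_lists <- function(base, new) {
    for (k in names(new)) {
      if (is.list(new[[k]]) && is.list(base[[k]]) &&
          !is.null(names(new[[k]]))) {
        base[[k]] <- merge_lists(base[[k]], new[[k]])
      } else {
        base[[k]] <- new[[k]]
      }
    }
    base
  }
  structure(merge_lists(cfg, over), class = "run_config")
}

#' Validate a pipeline configuration
#'
#' @param config a `run_config` (or plain nested list).
#' @return the config, invisibly; a `seqgp_validation_error` names the
#'   first missing key otherwise.
#' @export
validate_run_config <- function(config) {
  need <- c("seed", "genome", "lines", "chip", "traits", "response", "qc",
            "gwas", "sets", "bayesr", "evaluate")
  for (k in need) {
    if (is.null(config[[k]])) {
      stop_seqgp(sprintf("configuration is missing required key '%s'", k),
                 "validation_error")
    }
  }
  for (k in c("n_chromosomes", "chromosome_length_bp",
              "variants_per_chromosome")) {
    if (is.null(config$genome[[k]])) {
      stop_seqgp(sprintf("configuration is missing required key 'genome.%s'", k),
                 "validation_error")
    }
  }
  if (!length(config$lines)) {
    stop_seqgp("configuration needs at least one line", "validation_error")
  }
  invisible(config)
}

#' Write / read a pipeline configuration as JSON
#'
#' @param config a `run_config`.
#' @param path JSON file path.
#' @return `path` / the `run_config`.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  structure(cfg, class = "run_config")
}

# fixed seed offsets, one per stochastic stage (documented contract)
.seed_offsets <- list(map = 11L, pedigree = 1000L, genotypes = 2000L,
                      trait = 3000L, split = 4000L, bayesr = 5000L)

#' Run the full pipeline
#'
#' Executes simulate -> response -> QC -> GWAS -> preselect (Chip, Top-k,
#' ChipPlusSign and, with several lines, their multi-line variants) ->
#' BayesR -> evaluate -> compare, persisting every intermediate table as
#' TSV under `out_dir` together with a `manifest.json` recording the
#' configuration hash, stage seeds and content hashes of all outputs.
#' Re-running with the same configuration reproduces every output file
#' bit-for-bit.
#'
#' @param config a `run_config` (see [default_run_config()]) or the path
#'   of a JSON configuration.
#' @param out_dir output directory (created if needed).
#' @param quiet suppress stage progress messages.
#' @return (invisibly) a list with the evaluation `report`, the
#'   `comparison` regression summaries, and `out_dir`.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  validate_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  seed <- as.integer(config$seed)

  cfg_path <- file.path(out_dir, "config.json")
  write_run_config(config, cfg_path)
  cfg_hash <- unname(tools::md5sum(cfg_path))
  stamp <- c(sprintf("config_hash=%s", cfg_hash), sprintf("seed=%d", seed))

  ## --- simulate ------------------------------------------------------
  genome <- do.call(genome_config, config$genome)
  map <- make_variant_map(genome, derive_seed(seed, .seed_offsets$map))
  peds <- list(); genos <- list()
  for (i in seq_along(config$lines)) {
    lc <- config$lines[[i]]
    peds[[lc$name]] <- simulate_pedigree(
      lc$n_founders, lc$n_generations, lc$n_sires, lc$n_dams,
      litter_size = lc$litter_size, line = lc$name,
      seed = derive_seed(seed, .seed_offsets$pedigree + i))
    genos[[lc$name]] <- simulate_founders_and_drop(
      peds[[lc$name]], genome,
      seed = derive_seed(seed, .seed_offsets$genotypes + i), map = map)
    say("simulate: line %s, %d individuals x %d variants", lc$name,
        nrow(peds[[lc$name]]), nrow(map))
  }
  ped_all <- do.call(rbind, c(peds, list(make.row.names = FALSE)))
  dos_all <- do.call(rbind, lapply(genos, `[[`, "dosages"))
  geno <- new_geno_matrix(dos_all, map, ped_all$line, genome = genome)
  geno <- designate_chip(geno, config$chip$n_chip, config$chip$maf_min)
  for (l in names(genos)) genos[[l]]$map <- geno$map
  write_pedigree(ped_all, file.path(out_dir, "pedigree.tsv"), stamp)
  write_genotypes(geno, file.path(out_dir, "genotypes.tsv"),
                  comments = stamp)

  ## --- traits and response -------------------------------------------
  traits <- list(); responses <- list()
  for (t in seq_along(config$traits)) {
    tc <- config$traits[[t]]
    tr <- simulate_trait(geno, tc$n_qtn, tc$h2, qtn_panel = tc$qtn_panel,
                         seed = derive_seed(seed, .seed_offsets$trait + t))
    traits[[tc$name]] <- tr
    if (isTRUE(config$response$bypass_deregression)) {
      responses[[tc$name]] <- data.frame(
        id = names(tr$phenotype), line = unname(geno$line),
        y = unname(tr$phenotype), stringsAsFactors = FALSE)
    } else {
      parts <- lapply(names(peds), function(l) {
        ph <- tr$phenotype[peds[[l]]$id]
        trait_response(ph, peds[[l]], h2 = config$response$h2_blup,
                       bypass_deregression = FALSE,
                       min_reliability = config$response$min_reliability)
      })
      responses[[tc$name]] <- do.call(rbind, parts)
    }
    say("trait %s: realized h2 = %.3f", tc$name, tr$realized_h2)
    write_tsv(data.frame(id = names(tr$phenotype), tbv = unname(tr$tbv),
                         phenotype = unname(tr$phenotype),
                         stringsAsFactors = FALSE),
              file.path(out_dir, sprintf("trait_%s.tsv", tc$name)), stamp)
    write_tsv(data.frame(variant_id = tr$qtn_ids, effect = tr$qtn_effects,
                         stringsAsFactors = FALSE),
              file.path(out_dir, sprintf("qtn_%s.tsv", tc$name)), stamp)
  }

  ## --- study design per line -----------------------------------------
  design <- list()
  for (l in names(peds)) {
    ts <- define_test_set(peds[[l]], config$evaluate$min_family_size)
    A <- pedigree_A(peds[[l]])
    design[[l]] <- list(test = ts, A = A)
  }

  ## --- scenarios ------------------------------------------------------
  fit_counter <- 0L
  report <- list()
  run_scenario <- function(scen_geno, train_ids, test_ids, y_tab, tr,
                           line_label, trait_name, n_train_label,
                           replicate, sets_geno, multi = FALSE) {
    y_train <- y_tab$y[match(train_ids, y_tab$id)]
    line_train <- if (multi) scen_geno$line[train_ids] else NULL
    gtrain <- subset_geno(scen_geno, train_ids)
    if (multi) {
      mlm <- ml_variant_universe(sets_geno, config$qc$wgs_maf_min,
                                 config$qc$chip_maf_min,
                                 config$qc$call_rate_min,
                                 config$qc$hwe_alpha)
      chip_mask <- mlm$union_chip
      wgs_mask <- mlm$intersection
    } else {
      chip_mask <- qc_filter(gtrain, "chip", config$qc$chip_maf_min,
                             config$qc$call_rate_min, config$qc$hwe_alpha)
      wgs_mask <- qc_filter(gtrain, "wgs", config$qc$wgs_maf_min,
                            config$qc$call_rate_min, config$qc$hwe_alpha)
    }
    K <- genomic_K(gtrain, which(chip_mask))
    vc <- estimate_null_vc(y_train, K, covariates = line_train)
    gw <- association_scan(y_train, gtrain, vc, covariates = line_train,
                           variant_mask = which(wgs_mask))
    prefix <- if (multi) "ML-" else ""
    write_gwas(gw, file.path(out_dir, sprintf(
      "gwas_%s_%s_n%s_r%d.tsv", line_label, trait_name, n_train_label,
      replicate)), stamp)

    chip0 <- chip_set(scen_geno, chip_mask)
    chip0$name <- paste0(prefix, "Chip")
    sets <- list(chip0)
    tw <- select_top_per_window(gw, config$gwas$window_size_bp)
    tw$name <- paste0(prefix, tw$name)
    sets <- c(sets, list(tw))
    for (tt in config$sets$top_targets) {
      s <- select_top_per_window(gw, config$gwas$window_size_bp,
                                 target_count = tt)
      s$name <- paste0(prefix, "Top", tt)
      sets <- c(sets, list(s))
    }
    cps <- select_chip_plus_sign(gw, chip0, config$gwas$window_size_bp,
                                 config$gwas$p_threshold)
    cps$name <- paste0(prefix, "ChipPlusSign")
    sets <- c(sets, list(cps))

    rows <- list()
    for (s in sets) {
      fit_counter <<- fit_counter + 1L
      bc <- bayesr_config(
        n_iterations = config$bayesr$n_iterations,
        burn_in = config$bayesr$burn_in, thin = config$bayesr$thin,
        seed = derive_seed(seed, .seed_offsets$bayesr + fit_counter))
      Xtr <- set_dosages(gtrain, s)
      fit <- fit_bayesr(y_train, Xtr, line_labels = line_train, config = bc)
      # evaluate separately per test line
      test_lines <- unique(scen_geno$line[test_ids])
      for (tl in test_lines) {
        tid <- test_ids[scen_geno$line[test_ids] == tl]
        Xte <- set_dosages(subset_geno(scen_geno, tid), s)
        gebv <- predict_gebv(fit, Xte,
                             line_labels = if (multi) rep(tl, length(tid)))
        y_test <- y_tab$y[match(tid, y_tab$id)]
        rows[[length(rows) + 1L]] <- data.frame(
          line = tl, trait = trait_name, variant_set = s$name,
          scope = if (multi) "multi" else "within",
          replicate = replicate, n_train = length(train_ids),
          n_train_label = n_train_label, n_test = length(tid),
          n_variants = length(s$variant_ids),
          accuracy = suppressWarnings(accuracy(gebv, y_test)),
          bias = suppressWarnings(bias(gebv, y_test)),
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  }

  n_rep <- config$evaluate$n_replicates
  for (trait_name in names(responses)) {
    y_tab <- responses[[trait_name]]
    train_by_line_rep <- list()
    for (l in names(peds)) {
      ts <- design[[l]]$test
      splits <- if (n_rep > 1L) {
        replicate_split(ts, n_rep,
                        seed = derive_seed(seed, .seed_offsets$split))
      } else list(ts)
      for (r in seq_along(splits)) {
        test_ids <- splits[[r]]$id
        phen_ids <- intersect(y_tab$id[y_tab$line == l], peds[[l]]$id)
        train_ids <- define_training_set(design[[l]]$A, test_ids,
                                         setdiff(phen_ids, test_ids),
                                         config$evaluate$rel_threshold)
        train_by_line_rep[[paste(l, r)]] <- list(train = train_ids,
                                                 test = test_ids)
        say("design: line %s trait %s rep %d: %d train / %d test",
            l, trait_name, r, length(train_ids), length(test_ids))
        sizes <- c(list(c(label = "all", n = length(train_ids))),
                   lapply(config$evaluate$reduced_training,
                          function(k) c(label = as.character(k), n = k)))
        for (sz in sizes) {
          tr_ids <- if (identical(sz[["label"]], "all")) train_ids else
            reduce_training(train_ids, peds[[l]], as.integer(sz[["n"]]))
          report[[length(report) + 1L]] <- run_scenario(
            genos[[l]], tr_ids, test_ids, y_tab, traits[[trait_name]],
            l, trait_name, sz[["label"]], r, NULL, multi = FALSE)
        }
      }
    }
    ## multi-line scenarios
    if (isTRUE(config$multi_line) && length(peds) >= 2L) {
      for (r in seq_len(n_rep)) {
        tr_ids <- unlist(lapply(names(peds), function(l)
          train_by_line_rep[[paste(l, r)]]$train), use.names = FALSE)
        te_ids <- unlist(lapply(names(peds), function(l)
          train_by_line_rep[[paste(l, r)]]$test), use.names = FALSE)
        report[[length(report) + 1L]] <- run_scenario(
          geno, tr_ids, te_ids, y_tab, traits[[trait_name]],
          "multi", trait_name, "all", r, genos, multi = TRUE)
      }
    }
  }
  report <- do.call(rbind, report)
  rownames(report) <- NULL
  write_tsv(report, file.path(out_dir, "report.tsv"), stamp)

  comparison <- NULL
  for (scope in unique(report$scope)) {
    bench <- if (scope == "multi") "ML-Chip" else "Chip"
    sub <- report[report$scope == scope, , drop = FALSE]
    cmp <- tryCatch(compare_scenarios(sub, benchmark = bench),
                    error = function(e) NULL)
    if (!is.null(cmp)) {
      comparison[[scope]] <- cmp
      write_tsv(cmp$differences,
                file.path(out_dir, sprintf("differences_%s.tsv", scope)),
                stamp)
    }
  }

  ## --- manifest -------------------------------------------------------
  outputs <- sort(setdiff(list.files(out_dir), "manifest.json"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("seqgp")),
    config_hash = cfg_hash,
    seed = seed,
    seed_offsets = .seed_offsets,
    files = as.list(stats::setNames(
      unname(tools::md5sum(file.path(out_dir, outputs))), outputs))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  say("pipeline complete: %d scenario rows in %s", nrow(report), out_dir)
  invisible(list(report = report, comparison = comparison,
                 out_dir = out_dir))
}
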