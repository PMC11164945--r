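#' Experiment configuration for the full simulation grid
#'
#' Describes a complete study: the synthetic cohort, the shared
#' class-balanced test split, the partition scenarios, the federated
#' algorithms, the (local epochs, rounds) schedules, the global-imbalance /
#' local-heterogeneity grid, and the number of independent trials. The
#' `"full"` profile keeps the full-scale configuration (VGG16-style
#' network, 128 x 128 inputs, schedules 1 x 100 and 5 x 20, imbalance grid
#' at 50 rounds); the `"tiny"` profile is the desk-scale surface (tiny
#' network, 64 x 64 inputs, schedules 1 x 20 and 5 x 5, imbalance grid at
#' 10 rounds). Profiles differ only in configuration values.
#'
#' @param profile `"tiny"` or `"full"`.
#' @param cohort a [cohort_config()]; defaults to the profile's cohort.
#' @param n_test_per_site test patients per site (half per class).
#' @param scenarios list of partition scenario specs; each a list with
#'   `id`, `strategy` (one of `"dirichlet_class"`, `"quantity_class"`,
#'   `"dirichlet_quantity"`, `"source_based"`) and strategy parameters.
#' @param algorithms subset of fedavg/fedavgm/fedyogi/fedprox.
#' @param epoch_schedules list of `c(local_epochs, rounds)` pairs.
#' @param imbalance_grid list with `s0_fractions`, `alphas`,
#'   `total_patients`, `n_sites`, `local_epochs`, `rounds`; `NULL` skips
#'   the imbalance study.
#' @param trials independent repetitions per cell (default 3).
#' @param train a [train_config()]; defaults to the profile's network.
#' @param images_per_patient override for the cohort's images per patient.
#' @param seed master seed; trial seeds are derived from it.
#' @export
experiment_config <- function(profile = c("tiny", "full"),
                              cohort = NULL,
                              n_test_per_site = 10L,
                              scenarios = default_scenarios(),
                              algorithms = c("fedavg", "fedavgm",
                                             "fedyogi", "fedprox"),
                              epoch_schedules = NULL,
                              imbalance_grid = NULL,
                              trials = 3L,
                              train = NULL,
                              images_per_patient = NULL,
                              seed = 1L) {
  profile <- match.arg(profile)
  if (is.null(cohort)) {
    cohort <- cohort_config(profile = if (profile == "full") "full"
                            else "tiny", seed = seed)
  }
  if (!is.null(images_per_patient))
    cohort$images_per_patient <- as.integer(images_per_patient)
  if (is.null(epoch_schedules))
    epoch_schedules <- if (profile == "full") list(c(1L, 100L), c(5L, 20L))
                       else list(c(1L, 20L), c(5L, 5L))
  if (is.null(imbalance_grid))
    imbalance_grid <- list(s0_fractions = seq(0.1, 0.5, by = 0.1),
                           alphas = c(0, 0.2, 0.4, 0.6, 0.8, 1),
                           total_patients = 84L, n_sites = 2L,
                           local_epochs = 1L,
                           rounds = if (profile == "full") 50L else 10L)
  if (is.null(train))
    train <- train_config(arch = if (profile == "full") "vgg16_like"
                          else "tiny")
  stopifnot(trials >= 1)
  structure(list(profile = profile, cohort = cohort,
                 n_test_per_site = as.integer(n_test_per_site),
                 scenarios = scenarios, algorithms = algorithms,
                 epoch_schedules = epoch_schedules,
                 imbalance_grid = imbalance_grid,
                 trials = as.integer(trials), train = train,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

#' The four standard partition scenarios
#' @export
default_scenarios <- function() {
  list(list(id = "dirichlet_class", strategy = "dirichlet_class", beta = 2),
       list(id = "one_class_per_site", strategy = "quantity_class",
            classes_per_site = 1L),
       list(id = "quantity_skew", strategy = "dirichlet_quantity", beta = 2),
       list(id = "source_based", strategy = "source_based"))
}

#' Build a partition from a scenario spec
#'
#' @param spec scenario list (`strategy` plus parameters).
#' @param pool training-pool data.frame.
#' @param n_sites number of sites for the Dirichlet strategies.
#' @param seed RNG seed.
#' @export
build_partition <- function(spec, pool, n_sites = 2L, seed = 1L) {
  switch(spec$strategy,
         dirichlet_class = dirichlet_class_partition(
           pool, spec$n_sites %||% n_sites, spec$beta, seed),
         quantity_class = quantity_class_partition(
           pool, spec$n_sites %||% n_sites,
           spec$classes_per_site %||% 1L),
         dirichlet_quantity = dirichlet_quantity_partition(
           pool, spec$n_sites %||% n_sites, spec$beta, seed),
         source_based = source_partition(pool),
         imbalance_scenario = imbalance_scenario(
           pool, spec$total_patients %||% 84L, spec$s0_fraction,
           spec$alpha, spec$n_sites %||% n_sites, seed),
         stop("unknown partition strategy '", spec$strategy, "'"))
}

#' Read / write an experiment configuration as YAML
#'
#' @param path YAML file path.
#' @return an [experiment_config()].
#' @export
read_experiment_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("malformed experiment YAML: ", path)
  args <- list(profile = raw$profile %||% "tiny")
  for (f in c("n_test_per_site", "algorithms", "trials", "seed",
              "images_per_patient"))
    if (!is.null(raw[[f]])) args[[f]] <- raw[[f]]
  if (!is.null(raw$scenarios)) args$scenarios <- raw$scenarios
  if (!is.null(raw$epoch_schedules))
    args$epoch_schedules <- lapply(raw$epoch_schedules, as.integer)
  if (!is.null(raw$imbalance_grid)) args$imbalance_grid <- raw$imbalance_grid
  if (!is.null(raw$train)) args$train <- do.call(train_config, raw$train)
  if (!is.null(raw$cohort)) args$cohort <- do.call(cohort_config, raw$cohort)
  do.call(experiment_config, args)
}

#' @rdname read_experiment_config
#' @param config an [experiment_config()].
#' @export
write_experiment_config <- function(config, path) {
  out <- unclass(config)
  out$cohort <- unclass(out$cohort)
  out$train <- unclass(out$train)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Run the full experiment grid
#'
#' Generates the cohort and its images once, makes the shared
#' class-balanced test split once, then runs every
#' scenario x algorithm x schedule x trial cell, the centralized and
#' single-site baselines per schedule and trial, and (unless disabled) the
#' imbalance grid with FedAvg. A failing cell is recorded and the grid
#' continues. Finishes with a DeLong comparison of the best federated
#' scenario against the single-site baseline on the shared test scores.
#'
#' @param config an [experiment_config()].
#' @param verbose print progress lines.
#' @return object of class `"fl_experiment"`: `results` (one row per
#'   cell x trial with AUC, accuracy, CS-bar), `rounds_log`, `imbalance`,
#'   `partitions`, `delong`, `test_ids`, `failures`.
#' @export
run_grid <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  cohort <- generate_cohort(config$cohort)
  images <- generate_images(cohort, config$cohort)
  split <- make_test_split(cohort, config$n_test_per_site,
                           seed = derive_seed(config$seed, 51L))
  pool <- split$train_patients
  test <- split$test_patients
  trial_seeds <- vapply(seq_len(config$trials), function(k)
    derive_seed(config$seed, 52L, k), integer(1))
  results <- list()
  rounds_log <- list()
  partitions <- list()
  failures <- list()
  fits_by_cell <- list()
  note <- function(...) if (verbose) message(sprintf(...))

  run_cell <- function(label, sites, algorithm, epochs, rounds, trial, seed) {
    cfg <- config$train
    cfg$local_epochs <- as.integer(epochs)
    fit <- run_federated(sites, images, test, algorithm = algorithm,
                         rounds = rounds, config = cfg, trial_seed = seed)
    last <- fit$logs[nrow(fit$logs), ]
    results[[length(results) + 1L]] <<- data.frame(
      scenario = label, algorithm = algorithm, local_epochs = epochs,
      rounds = rounds, trial = trial,
      auc = last$auc, accuracy = last$accuracy,
      cs_bar = fit$heterogeneity$weighted_cs)
    rounds_log[[length(rounds_log) + 1L]] <<- data.frame(
      scenario = label, algorithm = algorithm, local_epochs = epochs,
      trial = trial, fit$logs)
    fit
  }

  for (sc in config$scenarios) {
    for (trial in seq_len(config$trials)) {
      pseed <- derive_seed(config$seed, 53L, match(sc$id,
                 vapply(config$scenarios, `[[`, "", "id")), trial)
      sites <- tryCatch(build_partition(sc, pool, seed = pseed),
                        error = function(e) e)
      if (inherits(sites, "error")) {
        failures[[length(failures) + 1L]] <- data.frame(
          scenario = sc$id, algorithm = "(partition)", local_epochs = NA,
          trial = trial, message = conditionMessage(sites))
        next
      }
      partitions[[paste(sc$id, trial, sep = "_t")]] <- sites
      for (alg in config$algorithms) {
        for (sch in config$epoch_schedules) {
          label <- sc$id
          note("scenario %s | %s | %dx%d | trial %d", label, alg,
               sch[1], sch[2], trial)
          res <- tryCatch(
            run_cell(label, sites, alg, sch[1], sch[2], trial,
                     trial_seeds[trial]),
            error = function(e) e)
          if (inherits(res, "error")) {
            failures[[length(failures) + 1L]] <- data.frame(
              scenario = label, algorithm = alg, local_epochs = sch[1],
              trial = trial, message = conditionMessage(res))
          } else {
            key <- paste(label, alg, sch[1], sep = "|")
            fits_by_cell[[key]] <- c(fits_by_cell[[key]], list(res))
          }
        }
      }
    }
  }

  # baselines: centralized and single-site per schedule and trial
  for (sch in config$epoch_schedules) {
    for (trial in seq_len(config$trials)) {
      cfg <- config$train
      cfg$local_epochs <- as.integer(sch[1])
      for (bl in c("centralized", "single_site")) {
        note("baseline %s | %dx%d | trial %d", bl, sch[1], sch[2], trial)
        res <- tryCatch({
          fit <- if (bl == "centralized")
            run_centralized(pool, images, test, rounds = sch[2],
                            config = cfg, trial_seed = trial_seeds[trial])
          else
            run_single_site(pool, images, test, rounds = sch[2],
                            config = cfg, trial_seed = trial_seeds[trial])
          last <- fit$logs[nrow(fit$logs), ]
          results[[length(results) + 1L]] <- data.frame(
            scenario = bl, algorithm = "centralized_sgd",
            local_epochs = sch[1], rounds = sch[2], trial = trial,
            auc = last$auc, accuracy = last$accuracy,
            cs_bar = fit$heterogeneity$weighted_cs)
          key <- paste(bl, sch[1], sep = "|")
          fits_by_cell[[key]] <- c(fits_by_cell[[key]], list(fit))
          fit
        }, error = function(e) e)
        if (inherits(res, "error"))
          failures[[length(failures) + 1L]] <- data.frame(
            scenario = bl, algorithm = "centralized_sgd",
            local_epochs = sch[1], trial = trial,
            message = conditionMessage(res))
      }
    }
  }

  # imbalance grid (FedAvg, fixed schedule)
  imb <- list()
  ig <- config$imbalance_grid
  if (!is.null(ig)) {
    cfg <- config$train
    cfg$local_epochs <- as.integer(ig$local_epochs %||% 1L)
    for (s0 in ig$s0_fractions) {
      for (al in ig$alphas) {
        for (trial in seq_len(config$trials)) {
          note("imbalance s0=%.2f alpha=%.1f trial %d", s0, al, trial)
          res <- tryCatch({
            sites <- imbalance_scenario(
              pool, ig$total_patients %||% 84L, s0, al,
              ig$n_sites %||% 2L,
              seed = derive_seed(config$seed, 54L, round(100 * s0),
                                 round(100 * al), trial))
            het <- weighted_avg_cosine(sites)
            fit <- run_federated(sites, images, test, algorithm = "fedavg",
                                 rounds = ig$rounds %||% 10L, config = cfg,
                                 trial_seed = trial_seeds[trial])
            last <- fit$logs[nrow(fit$logs), ]
            imb[[length(imb) + 1L]] <- data.frame(
              s0_fraction = s0, alpha = al, trial = trial,
              cs_bar = het$weighted_cs, accuracy = last$accuracy,
              auc = last$auc)
            NULL
          }, error = function(e) e)
          if (inherits(res, "error"))
            failures[[length(failures) + 1L]] <- data.frame(
              scenario = sprintf("imbalance_s0%.2f_a%.1f", s0, al),
              algorithm = "fedavg", local_epochs = cfg$local_epochs,
              trial = trial, message = conditionMessage(res))
        }
      }
    }
  }

  results <- if (length(results)) do.call(rbind, results) else NULL
  # DeLong: best federated cell (mean AUC over trials) vs single-site
  delong <- NULL
  if (!is.null(results)) {
    fed <- results[!results$scenario %in% c("centralized", "single_site"), ]
    base_key <- paste("single_site", config$epoch_schedules[[1]][1],
                      sep = "|")
    if (nrow(fed) && !is.null(fits_by_cell[[base_key]])) {
      agg <- stats::aggregate(auc ~ scenario + algorithm + local_epochs,
                              data = fed, FUN = mean)
      best <- agg[which.max(agg$auc), ]
      best_key <- paste(best$scenario, best$algorithm, best$local_epochs,
                        sep = "|")
      bf <- fits_by_cell[[best_key]][[1]]
      sf <- fits_by_cell[[base_key]][[1]]
      delong <- delong_test(bf$eval_scores, sf$eval_scores)
      attr(delong, "comparison") <-
        sprintf("%s/%s (%d epochs) vs single_site", best$scenario,
                best$algorithm, best$local_epochs)
    }
  }
  structure(list(config = config,
                 results = results,
                 rounds_log = if (length(rounds_log))
                   do.call(rbind, rounds_log) else NULL,
                 imbalance = if (length(imb)) do.call(rbind, imb) else NULL,
                 partitions = partitions,
                 delong = delong,
                 test_ids = sort(test$patient_id),
                 failures = if (length(failures))
                   do.call(rbind, failures) else NULL),
            class = "fl_experiment")
}

#' @export
print.fl_experiment <- function(x, ...) {
  cat("Federated learning experiment (", x$config$profile, " profile)\n",
      sep = "")
  if (!is.null(x$results)) {
    agg <- stats::aggregate(auc ~ scenario + algorithm + local_epochs,
                            data = x$results, FUN = mean)
    print(agg, row.names = FALSE)
  }
  if (!is.null(x$delong))
    cat(attr(x$delong, "comparison"), ": p =",
        format(x$delong$p_value, digits = 3), "\n")
  if (!is.null(x$failures))
    cat(nrow(x$failures), "cell(s) failed\n")
  invisible(x)
}

#' Write the experiment report files
#'
#' `results.csv` (one row per scenario x algorithm x schedule x trial),
#' `rounds.csv` (per-round test curves), `imbalance.csv` (one row per
#' s0_fraction x alpha x trial with CS-bar, accuracy, AUC),
#' `partitions/<scenario>.csv` (patient_id, site_id) and
#' `heterogeneity/<scenario>.json`.
#'
#' @param experiment an `"fl_experiment"`.
#' @param output_dir output directory.
#' @return invisibly, the output directory.
#' @export
write_reports <- function(experiment, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(experiment$results))
    write.csv(experiment$results, file.path(output_dir, "results.csv"),
              row.names = FALSE)
  if (!is.null(experiment$rounds_log))
    write.csv(experiment$rounds_log, file.path(output_dir, "rounds.csv"),
              row.names = FALSE)
  if (!is.null(experiment$imbalance))
    write.csv(experiment$imbalance, file.path(output_dir, "imbalance.csv"),
              row.names = FALSE)
  pdir <- file.path(output_dir, "partitions")
  hdir <- file.path(output_dir, "heterogeneity")
  dir.create(pdir, showWarnings = FALSE)
  dir.create(hdir, showWarnings = FALSE)
  for (nm in names(experiment$partitions)) {
    sites <- experiment$partitions[[nm]]
    tab <- do.call(rbind, lapply(sites, function(s)
      if (s$n > 0) data.frame(patient_id = s$patients$patient_id,
                              site_id = s$site_id) else NULL))
    write.csv(tab, file.path(pdir, paste0(nm, ".csv")), row.names = FALSE)
    het <- weighted_avg_cosine(sites)
    jsonlite::write_json(
      list(weighted_cs = het$weighted_cs,
           per_site_cs = het$per_site_cs,
           global_counts = as.list(het$global_counts), n = het$n),
      file.path(hdir, paste0(nm, ".json")), auto_unbox = TRUE, digits = NA)
  }
  invisible(output_dir)
}
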