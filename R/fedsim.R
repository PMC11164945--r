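#' Run an in-process federated training simulation
#'
#' Simulates one server and the given sites: every round, the server
#' broadcasts the global weights, each non-empty site runs local mini-batch
#' training (focal loss + Adam, with the FedProx proximal term when
#' `algorithm = "fedprox"`), the server computes the sample-size-weighted
#' average and applies its algorithm-specific update (identity for
#' FedAvg/FedProx, momentum for FedAvgM, adaptive Yogi step for FedYogi),
#' and the updated global model is evaluated on the shared test set. All
#' sites and the server start from identical seeded initial weights;
#' shuffling and augmentation use per-(round, site) seeds derived from
#' `trial_seed`, so runs are exactly reproducible.
#'
#' @param sites list of site partitions (e.g. from [source_partition()]).
#' @param images named list of grayscale image matrices per patient.
#' @param eval_patients data.frame of test patients.
#' @param algorithm `"fedavg"`, `"fedavgm"`, `"fedyogi"` or `"fedprox"`.
#' @param rounds number of communication rounds.
#' @param config a [train_config()].
#' @param server_hp server hyperparameters ([server_hparams()]).
#' @param trial_seed master seed of the trial.
#' @param eval_images images for the test patients (defaults to `images`).
#' @param verbose print a line per round.
#' @return object of class `"fl_fit"`: final weights, per-round logs, the
#'   final test [score_set()], the partition heterogeneity report and the
#'   run configuration. Methods: `print`, `summary`, `coef`, `predict`,
#'   `plot`.
#' @export
run_federated <- function(sites, images, eval_patients,
                          algorithm = c("fedavg", "fedavgm", "fedyogi",
                                        "fedprox"),
                          rounds = 20L, config = train_config(),
                          server_hp = server_hparams(algorithm),
                          trial_seed = 1L, eval_images = images,
                          verbose = FALSE) {
  algorithm <- match.arg(algorithm)
  active <- Filter(function(s) s$n > 0, sites)
  if (!length(active)) stop("all sites are empty")
  if (rounds < 1) stop("rounds must be >= 1")
  if (algorithm == "fedprox" && config$prox_mu == 0)
    config$prox_mu <- server_hp$mu
  net <- build_model(config$arch, init_seed = derive_seed(trial_seed, 41L),
                     input_size = config$input_size)
  spec <- preprocess_spec(target_size = net$input_dim[1],
                          channels = net$input_dim[3])
  site_data <- lapply(active, function(s)
    make_tensor(s$patients, images, spec))
  eval_data <- make_tensor(eval_patients, eval_images, spec)
  eval_x <- stack_channels(eval_data$x, net$input_dim[3])
  sizes <- vapply(site_data, function(d) length(d$y), numeric(1))
  state <- server_state(algorithm, net$weights, server_hp)
  logs <- vector("list", rounds)
  for (t in seq_len(rounds)) {
    broadcast <- state$global_weights
    site_w <- vector("list", length(active))
    for (i in seq_along(active)) {
      site_w[[i]] <- local_train(
        broadcast, net, site_data[[i]], config,
        global_anchor = broadcast,
        seed = derive_seed(trial_seed, 42L, t, active[[i]]$site_id))
    }
    agg <- fedavg_aggregate(site_w, sizes)
    state <- server_update(state, agg)
    p <- net_predict(net, state$global_weights, eval_x)
    acc <- mean((p >= 0.5) == (eval_data$y == 1))
    auc <- roc_auc(score_set(p, eval_data$y, eval_data$patient_id))
    logs[[t]] <- data.frame(round = t, n = sum(sizes),
                            sites = paste(sizes, collapse = "/"),
                            accuracy = acc, auc = auc)
    if (verbose)
      message(sprintf("round %d/%d: accuracy %.3f, AUC %.3f",
                      t, rounds, acc, auc))
  }
  p <- net_predict(net, state$global_weights, eval_x)
  fit <- list(weights = state$global_weights, net = net,
              algorithm = algorithm, rounds = rounds, config = config,
              server_hp = server_hp, trial_seed = trial_seed,
              site_sizes = sizes,
              heterogeneity = weighted_avg_cosine(active),
              logs = do.call(rbind, logs),
              eval_scores = score_set(p, eval_data$y, eval_data$patient_id))
  class(fit) <- "fl_fit"
  fit
}

#' Centralized training baseline
#'
#' Pools all training patients into a single simulated site and trains with
#' the same preprocessing, loss and optimizer; `rounds` plays the role of
#' epochs over the pooled data (each "round" is `local_epochs` passes).
#'
#' @param pool training-pool data.frame.
#' @inheritParams run_federated
#' @export
run_centralized <- function(pool, images, eval_patients, rounds = 20L,
                            config = train_config(), trial_seed = 1L,
                            eval_images = images, verbose = FALSE) {
  if (nrow(pool) == 0) stop("training pool is empty")
  run_federated(list(new_site_partition(1L, pool)), images, eval_patients,
                algorithm = "fedavg", rounds = rounds, config = config,
                trial_seed = trial_seed, eval_images = eval_images,
                verbose = verbose)
}

#' Single-center baseline: train on the private-like site only
#'
#' @inheritParams run_centralized
#' @export
run_single_site <- function(pool, images, eval_patients, rounds = 20L,
                            config = train_config(), trial_seed = 1L,
                            eval_images = images, verbose = FALSE) {
  private <- pool[pool$site == "private_like", , drop = FALSE]
  if (nrow(private) == 0) stop("pool has no private-like patients")
  run_centralized(private, images, eval_patients, rounds = rounds,
                  config = config, trial_seed = trial_seed,
                  eval_images = eval_images, verbose = verbose)
}

#' @export
print.fl_fit <- function(x, ...) {
  cat("Federated fit:", x$algorithm, "|", length(x$site_sizes),
      "site(s) of sizes", paste(x$site_sizes, collapse = "/"),
      "|", x$rounds, "rounds x", x$config$local_epochs, "local epoch(s)\n")
  last <- x$logs[nrow(x$logs), ]
  cat(sprintf("final test accuracy %.3f, AUC %.3f | partition CS-bar %.4f\n",
              last$accuracy, last$auc, x$heterogeneity$weighted_cs))
  invisible(x)
}

#' @export
summary.fl_fit <- function(object, ...) {
  rep <- confusion_metrics(object$eval_scores)
  out <- list(fit = object, metrics = rep,
              auc_ci = jackknife_ci(object$eval_scores, metric = "auc"))
  class(out) <- "summary.fl_fit"
  out
}

#' @export
print.summary.fl_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("AUC %.3f (95%% CI %.3f, %.3f by patient jackknife)\n",
              x$auc_ci$estimate, x$auc_ci$ci_low, x$auc_ci$ci_high))
  print(x$metrics)
  invisible(x)
}

#' @export
coef.fl_fit <- function(object, ...) object$weights

#' Score new patients with a fitted global model
#'
#' @param object an `"fl_fit"`.
#' @param patients data.frame of patients to score.
#' @param images named list of their grayscale images.
#' @param ... unused.
#' @return a [score_set()] of per-image probabilities.
#' @export
predict.fl_fit <- function(object, patients, images, ...) {
  spec <- preprocess_spec(target_size = object$net$input_dim[1],
                          channels = object$net$input_dim[3])
  d <- make_tensor(patients, images, spec)
  x <- stack_channels(d$x, object$net$input_dim[3])
  p <- net_predict(object$net, object$weights, x)
  score_set(p, d$y, d$patient_id)
}

#' @export
plot.fl_fit <- function(x, ...) {
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  graphics::plot(x$logs$round, x$logs$accuracy, type = "l",
                 xlab = "round", ylab = "test accuracy",
                 main = x$algorithm, ylim = c(0, 1), ...)
  graphics::plot(x$logs$round, x$logs$auc, type = "l",
                 xlab = "round", ylab = "test AUC", ylim = c(0, 1), ...)
  invisible(x)
}
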