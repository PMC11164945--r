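test_that("weighted aggregation obeys its algebra", {
  set.seed(3)
  mk <- function(val) list(a = array(val, c(2, 2)), b = val * 1:3)
  # convex-combination fixed point
  w <- mk(rnorm(1))
  expect_equal(fedavg_aggregate(list(w, w, w), c(5, 1, 3)), w)
  # scalar hand value with the in-study counts: 42/188 of 1.0
  agg <- fedavg_aggregate(list(wv1(1.0), wv1(0.0)), c(42, 146))
  expect_equal(as.numeric(agg$w), 42 / 188, tolerance = 1e-12)
  expect_equal(round(as.numeric(agg$w), 4), 0.2234)
  # single site: identity
  expect_equal(fedavg_aggregate(list(w), 7), w)
  # permutation invariance
  ws <- list(mk(0.1), mk(-2), mk(5))
  ns <- c(10, 20, 5)
  perm <- c(3, 1, 2)
  expect_equal(fedavg_aggregate(ws, ns),
               fedavg_aggregate(ws[perm], ns[perm]))
  # envelope: aggregate lies within the elementwise min/max of inputs
  for (i in 1:20) {
    ws <- lapply(1:3, function(k) mk(rnorm(1)))
    ns <- runif(3, 1, 10)
    agg <- fedavg_aggregate(ws, ns)
    for (nm in names(agg)) {
      lo <- pmin(ws[[1]][[nm]], ws[[2]][[nm]], ws[[3]][[nm]])
      hi <- pmax(ws[[1]][[nm]], ws[[2]][[nm]], ws[[3]][[nm]])
      expect_true(all(agg[[nm]] >= lo - 1e-12 & agg[[nm]] <= hi + 1e-12))
    }
  }
  expect_error(fedavg_aggregate(list(w), c(1, 2)), "lengths")
  expect_error(fedavg_aggregate(list(w, mk(1)), c(1, -2)), "positive")
  expect_error(fedavg_aggregate(list(w, list(a = array(1, c(3, 3)),
                                             b = 1:3)), c(1, 2)),
               "conformable")
})

test_that("server momentum update matches the hand-worked recursion", {
  st <- server_state("fedavgm", wv1(1.0),
                     hparams = list(beta = 0.9, eta = 1.0))
  st$momentum <- wv1(0.2)
  st2 <- fedavgm_update(st, wv1(0.6))
  expect_equal(as.numeric(st2$momentum$w), 0.58, tolerance = 1e-12)
  expect_equal(as.numeric(st2$global_weights$w), 0.42, tolerance = 1e-12)
  # beta = 0, eta = 1 collapses to plain averaging
  st <- server_state("fedavgm", wv1(1.0), hparams = list(beta = 0, eta = 1))
  expect_equal(as.numeric(fedavgm_update(st, wv1(0.6))$global_weights$w),
               0.6, tolerance = 1e-15)
  # stationary point: zero pseudo-gradient, zero momentum
  st <- server_state("fedavgm", wv1(0.3),
                     hparams = list(beta = 0.9, eta = 1))
  expect_equal(as.numeric(fedavgm_update(st, wv1(0.3))$global_weights$w),
               0.3, tolerance = 1e-15)
})

test_that("adaptive Yogi update matches the hand-worked recursion", {
  hp <- list(beta1 = 0.9, beta2 = 0.99, tau = 1e-3, eta = 0.1)
  st <- server_state("fedyogi", wv1(1.0), hparams = hp)
  st$v <- wv1(0.1)
  st2 <- fedyogi_update(st, wv1(1.5))
  expect_equal(as.numeric(st2$m$w), 0.05, tolerance = 1e-12)
  expect_equal(as.numeric(st2$v$w), 0.1025, tolerance = 1e-12)
  expect_equal(as.numeric(st2$global_weights$w),
               1 + 0.1 * 0.05 / (sqrt(0.1025) + 1e-3), tolerance = 1e-12)
  expect_equal(round(as.numeric(st2$global_weights$w), 4), 1.0156)
  # stationary point
  st <- server_state("fedyogi", wv1(0.5), hparams = hp)
  st$v <- wv1(0.04)
  expect_equal(as.numeric(fedyogi_update(st, wv1(0.5))$global_weights$w),
               0.5, tolerance = 1e-15)
  # sign(0) = 0: second moment unchanged when v equals delta^2
  st <- server_state("fedyogi", wv1(0), hparams = hp)
  st$v <- wv1(0.25)
  st2 <- fedyogi_update(st, wv1(0.5))   # delta = 0.5, delta^2 = 0.25
  expect_equal(as.numeric(st2$v$w), 0.25, tolerance = 1e-15)
  # defensive check on a corrupted second moment
  st <- server_state("fedyogi", wv1(0), hparams = hp)
  st$v <- wv1(-0.1)
  expect_error(fedyogi_update(st, wv1(0.5)), "non-positive")
})

test_that("algorithm reductions hold bitwise over multiple rounds", {
  fx <- fed_fixture()
  sp <- make_test_split(fx$cohort, 2L, seed = 2L)
  sites <- source_partition(sp$train_patients)
  cfg <- fed_fixture_config()
  base <- run_federated(sites, fx$images, sp$test_patients, "fedavg",
                        rounds = 3, config = cfg, trial_seed = 9)
  m0 <- run_federated(sites, fx$images, sp$test_patients, "fedavgm",
                      rounds = 3, config = cfg,
                      server_hp = list(beta = 0, eta = 1), trial_seed = 9)
  p0 <- run_federated(sites, fx$images, sp$test_patients, "fedprox",
                      rounds = 3, config = cfg,
                      server_hp = list(mu = 0), trial_seed = 9)
  expect_identical(base$weights, m0$weights)
  expect_identical(base$weights, p0$weights)
  expect_equal(base$logs$auc, m0$logs$auc)
  expect_equal(base$logs$auc, p0$logs$auc)
  # a positive mu changes the trajectory
  pmu <- run_federated(sites, fx$images, sp$test_patients, "fedprox",
                       rounds = 3, config = cfg,
                       server_hp = list(mu = 0.5), trial_seed = 9)
  expect_false(identical(base$weights, pmu$weights))
})

test_that("two sites with identical data and seeds reproduce either site", {
  fx <- fed_fixture()
  sp <- make_test_split(fx$cohort, 2L, seed = 2L)
  pool <- sp$train_patients
  # same patients, same site_id, hence synchronized local seeds
  twin_sites <- list(fedus:::new_site_partition(1L, pool),
                     fedus:::new_site_partition(1L, pool))
  cfg <- fed_fixture_config()
  twin <- run_federated(twin_sites, fx$images, sp$test_patients, "fedavg",
                        rounds = 2, config = cfg, trial_seed = 5)
  solo <- run_federated(list(fedus:::new_site_partition(1L, pool)),
                        fx$images, sp$test_patients, "fedavg",
                        rounds = 2, config = cfg, trial_seed = 5)
  expect_equal(twin$weights, solo$weights, tolerance = 1e-12)
})

test_that("baselines are the single-site reductions of the federated loop", {
  fx <- fed_fixture()
  sp <- make_test_split(fx$cohort, 2L, seed = 2L)
  pool <- sp$train_patients
  cfg <- fed_fixture_config()
  cen <- run_centralized(pool, fx$images, sp$test_patients, rounds = 2,
                         config = cfg, trial_seed = 3)
  fed1 <- run_federated(list(fedus:::new_site_partition(1L, pool)),
                        fx$images, sp$test_patients, "fedavg", rounds = 2,
                        config = cfg, trial_seed = 3)
  expect_identical(cen$weights, fed1$weights)
  # single-site baseline trains only on private-like patients
  ss <- run_single_site(pool, fx$images, sp$test_patients, rounds = 2,
                        config = cfg, trial_seed = 3)
  expect_equal(unname(ss$site_sizes),
               sum(pool$site == "private_like") * 2)
  # the full-size default split leaves 143 private-like training patients
  big <- default_split()
  expect_equal(sum(big$train_patients$site == "private_like"), 143L)
  # determinism in the trial seed
  cen2 <- run_centralized(pool, fx$images, sp$test_patients, rounds = 2,
                          config = cfg, trial_seed = 3)
  expect_identical(cen$weights, cen2$weights)
  expect_identical(cen$logs, cen2$logs)
  expect_error(run_centralized(pool[0, ], fx$images, sp$test_patients),
               "empty")
})

test_that("fitted models expose the standard S3 surface", {
  fx <- fed_fixture()
  sp <- make_test_split(fx$cohort, 2L, seed = 2L)
  fit <- run_federated(source_partition(sp$train_patients), fx$images,
                       sp$test_patients, "fedavg", rounds = 2,
                       config = fed_fixture_config(), trial_seed = 1)
  expect_s3_class(fit, "fl_fit")
  expect_output(print(fit), "Federated fit")
  expect_named(coef(fit), names(fit$net$weights))
  sc <- predict(fit, sp$test_patients, fx$images)
  expect_s3_class(sc, "score_set")
  expect_equal(length(sc$scores), nrow(sp$test_patients) * 2)
  expect_equal(sc$scores, fit$eval_scores$scores, tolerance = 1e-12)
  sm <- suppressWarnings(summary(fit))
  expect_s3_class(sm$metrics, "metric_report")
  expect_true(sm$auc_ci$ci_low <= sm$auc_ci$estimate &&
                sm$auc_ci$estimate <= sm$auc_ci$ci_high)
  pdf(NULL)
  on.exit(dev.off())
  expect_invisible(plot(fit))
  expect_equal(nrow(fit$logs), 2L)
})
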