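# fit mechanics run on a reduced annealing schedule; the full two-stage
# schedule is exercised by the calibration acceptance test

test_that("fit improves the objective, respects bounds, and is seeded", {
  ds <- small_study()
  fit1 <- fit_parameters(ds, init = model_parameters(dt = 0.05),
                         schedule = tiny_schedule(), seed = 42)
  expect_s3_class(fit1, "aux_fit")
  expect_lte(fit1$objective, fit1$objective_init)
  expect_true(all(fit1$scores$score >= 0))
  # every fitted value inside its bounds
  for (nm in names(fit1$bounds)) {
    expect_gte(fit1$theta[[nm]], fit1$bounds[[nm]][1])
    expect_lte(fit1$theta[[nm]], fit1$bounds[[nm]][2])
  }
  # running best of the accepted-score sequence is non-increasing
  expect_true(all(diff(fit1$trace$best) <= 0))
  # deterministic given the seed
  fit2 <- fit_parameters(ds, init = model_parameters(dt = 0.05),
                         schedule = tiny_schedule(), seed = 42)
  expect_identical(fit1$theta, fit2$theta)
  expect_identical(fit1$objective, fit2$objective)
  fit3 <- fit_parameters(ds, init = model_parameters(dt = 0.05),
                         schedule = tiny_schedule(), seed = 43)
  expect_false(identical(fit1$theta, fit3$theta))
})

test_that("empty fit split and non-finite initial objective error", {
  ds <- small_study()
  val_only <- study_dataset(Filter(function(p) p$split == "validation",
                                   ds$profiles))
  expect_error(fit_parameters(val_only, schedule = tiny_schedule()),
               "fit split")
})

test_that("validate_fit returns split averages and warns without validation", {
  ds <- small_study()
  fit <- fit_parameters(ds, init = model_parameters(dt = 0.05),
                        schedule = annealing_schedule(
                          iters_per_temp = 5, n_temps = 2, n_screen = 4),
                        seed = 1)
  v <- validate_fit(fit, ds)
  expect_true(is.finite(v$fit_avg) && is.finite(v$validation_avg))
  # identical fit and validation profiles give identical averages
  twin <- ds$profiles[vapply(ds$profiles, function(p) p$split == "fit", TRUE)]
  for (i in seq_along(twin)) twin[[i]]$split <- "validation"
  both <- study_dataset(c(
    ds$profiles[vapply(ds$profiles, function(p) p$split == "fit", TRUE)],
    twin))
  vb <- validate_fit(fit, both)
  expect_equal(vb$validation_avg, vb$fit_avg)
  fit_only <- study_dataset(
    ds$profiles[vapply(ds$profiles, function(p) p$split == "fit", TRUE)])
  expect_warning(validate_fit(fit, fit_only), "validation")
})

test_that("noisy refits keep validation scores at or above fit scores", {
  # repeated twin-noise experiment on model-generated profiles: the
  # validation set covers the same genotype and condition with an
  # independent noise draw, so any advantage of the fit split over
  # validation is pure noise overfitting -- the calibrated model should
  # score no better on held-out noise in most replicates
  truth <- model_parameters(dt = 0.05)
  free <- default_bounds()[c("mu_input", "P_polar_bottom", "lambda_growth",
                             "u_mu", "eta")]
  wins <- 0L
  n_rep <- 10L
  for (s in seq_len(n_rep)) {
    mk <- function(seed) model_pseudodata(
      truth, genotypes = list(genotype("wt")),
      regimes = list(light_regime("CL75")),
      noise_sd = 5, seed = seed, n_replicates = 4)
    dsa <- mk(100 + s)
    twin <- mk(600 + s)$profiles
    for (i in seq_along(twin)) twin[[i]]$split <- "validation"
    ds <- study_dataset(c(dsa$profiles, twin))
    fit <- fit_parameters(ds, init = truth, bounds = free,
                          schedule = annealing_schedule(
                            iters_per_temp = 15, n_temps = 4, n_screen = 8),
                          seed = s)
    if (fit$validation_avg >= fit$fit_avg) wins <- wins + 1L
  }
  expect_gte(wins / n_rep, 0.8)
})
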