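# Two-stage simulated-annealing calibration of the transport model against
# per-cell length profiles.  Stage 0 screens the parameter box with a Latin
# hypercube and narrows the bounds around the best point; the parameters are
# then optimised twice by full annealing runs.

#' Default fitting bounds
#'
#' Box constraints for every fitted parameter, including the two free
#' genotype factors (`abcb_nonpolar`, `sav3_synthesis`).  Fixed constants
#' (`I_c0`, `epsilon`, `I_fr_max`, `l0`, `dt`) are not fitted.
#'
#' @return Named list of `c(lower, upper)` pairs.
#' @export
default_bounds <- function() {
  list(
    lambda_growth = c(0.5, 40),
    u_mu = c(0.01, 10),
    a1 = c(0.001, 10),
    mu_input = c(1, 1000),
    u_c = c(0, 12000),
    b1 = c(100, 20000),
    beta = c(0.5, 5),
    u_fr = c(0, 2),
    a2 = c(0.01, 5),
    eta = c(0, 80),
    u_I = c(0, 130),
    a3 = c(10, 1e5),
    P_np = c(0.01, 2),
    P_polar_bottom = c(0.01, 5),
    P_polar_out = c(0.01, 3),
    abcb_nonpolar = c(0.05, 1),
    sav3_synthesis = c(0.05, 1)
  )
}

#' Annealing schedule settings
#'
#' Geometric cooling with factor `cooling`, `iters_per_temp` Metropolis
#' iterations per temperature level, `n_temps` levels per run, Gaussian
#' proposals with standard deviation `step_frac` of each parameter's bound
#' width (one randomly chosen coordinate per iteration), and an LHS screen
#' of `n_screen` points in stage 0 that narrows each bound to
#' `narrow_frac` of its width around the stage-0 optimum.
#'
#' @param cooling geometric cooling factor per temperature level.
#' @param iters_per_temp iterations per temperature level.
#' @param n_temps temperature levels per annealing run.
#' @param step_frac proposal standard deviation as a fraction of bound width.
#' @param n_screen Latin-hypercube screening points in stage 0.
#' @param narrow_frac bound width retained around the stage-0 optimum.
#' @param t_init initial temperature; `NULL` sets it from the spread of the
#'   stage-0 objective values.
#' @return A list of settings.
#' @export
annealing_schedule <- function(cooling = 0.95, iters_per_temp = 200,
                               n_temps = 24, step_frac = 0.05,
                               n_screen = 600, narrow_frac = 0.5,
                               t_init = NULL) {
  list(cooling = cooling, iters_per_temp = iters_per_temp,
       n_temps = n_temps, step_frac = step_frac, n_screen = n_screen,
       narrow_frac = narrow_frac, t_init = t_init)
}

# apply a named parameter vector (possibly including genotype factors) to
# params + genotype factor list
apply_theta <- function(theta, params, geno_factors) {
  core <- setdiff(names(theta), c("abcb_nonpolar", "sav3_synthesis"))
  p <- unclass(params)
  p[core] <- as.list(theta[core])
  params <- validate_parameters(p)
  if ("abcb_nonpolar" %in% names(theta) &&
      !is.null(geno_factors$abcb1_abcb19)) {
    geno_factors$abcb1_abcb19$nonpolar_factor <-
      unname(theta[["abcb_nonpolar"]])
  }
  if ("sav3_synthesis" %in% names(theta) && !is.null(geno_factors$sav3)) {
    geno_factors$sav3$synthesis_factor <- unname(theta[["sav3_synthesis"]])
  }
  list(params = params, geno_factors = geno_factors)
}

# lean objective: simulates each (genotype, condition) of the fit split
# via direct core calls (no snapshot bookkeeping) and averages the J-scores;
# agrees with score_dataset() on the same parameters (tested)
make_objective <- function(dataset, params, geno_factors, variant) {
  fitset <- filter_profiles(dataset, split = "fit")
  if (!length(fitset$profiles)) {
    stop("dataset has an empty fit split", call. = FALSE)
  }
  profs <- fitset$profiles
  keys <- vapply(profs, function(p) paste(p$genotype, p$condition), "")
  combos <- lapply(unique(keys), function(key) {
    idx <- which(keys == key)
    p1 <- profs[[idx[1]]]
    rg <- light_regime(p1$condition)
    list(genotype = p1$genotype, regime = rg, profiles = profs[idx])
  })

  run_core <- function(q0, l0, t0, hours, p, rg_list, geno) {
    sim_core_cpp(q0, l0, t0, as.integer(round(hours / p$dt)), p$dt,
                 as.integer(round(hours / p$dt)) + 1L, unclass(p), rg_list,
                 unclass(geno), c(0, 0, 0), FALSE)
  }

  function(theta) {
    ap <- apply_theta(theta, params, geno_factors)
    p <- ap$params
    total <- 0
    n <- 0L
    for (cb in combos) {
      geno <- ap$geno_factors[[cb$genotype]] %||%
        genotype_factors(cb$genotype)
      onset_h <- min(cb$regime$fr_onset_day, 4) * 24
      end_h <- cb$regime$fr_end_day * 24
      white <- list(par_intensity = cb$regime$par_intensity,
                    light_hours = light_hours(cb$regime), fr_onset_h = Inf)
      fr <- white
      fr$fr_onset_h <- cb$regime$fr_onset_day * 24
      g0 <- build_grid(18, 4, p$l0)
      base <- tryCatch(
        run_core(g0$q, g0$l, 0, onset_h, p, white, geno),
        error = function(e) NULL)
      if (is.null(base)) return(Inf)
      rest <- end_h - onset_h
      branch <- lapply(list(white, fr), function(rg) tryCatch(
        run_core(base$q, base$l, onset_h, rest, p, rg, geno),
        error = function(e) NULL))
      if (any(vapply(branch, is.null, TRUE))) return(Inf)
      clip <- base$clip_total + branch[[1]]$clip_total +
        branch[[2]]$clip_total
      if (clip > 1e-12 * max(branch[[2]]$cum_input, 1e-12)) return(Inf)
      for (pr in cb$profiles) {
        sim_l <- if (pr$day <= 4) base$l
        else if (pr$treatment == "FR") branch[[2]]$l
        else branch[[1]]$l
        total <- total + j_score(pr, sim_l, variant = variant, dt = p$dt)
        n <- n + 1L
      }
    }
    total / n
  }
}

anneal_run <- function(fn, x0, lower, upper, f0, t_init, schedule, stage,
                       trace_env) {
  x <- x0
  fx <- f0
  best <- x
  fbest <- fx
  width <- upper - lower
  temp <- t_init
  it <- 0L
  for (lev in seq_len(schedule$n_temps)) {
    for (k in seq_len(schedule$iters_per_temp)) {
      it <- it + 1L
      j <- sample.int(length(x), 1L)
      xp <- x
      xp[j] <- xp[j] + rnorm(1L, 0, schedule$step_frac * width[j])
      xp[j] <- min(max(xp[j], lower[j]), upper[j])
      fp <- fn(xp)
      acc <- is.finite(fp) && (fp <= fx || runif(1L) < exp((fx - fp) / temp))
      if (acc) {
        x <- xp
        fx <- fp
        if (fx < fbest) {
          best <- x
          fbest <- fx
        }
      }
      trace_env$rows[[length(trace_env$rows) + 1L]] <- data.frame(
        stage = stage, iteration = it, temperature = temp,
        proposal = fp, accepted = acc, current = fx, best = fbest
      )
    }
    temp <- temp * schedule$cooling
  }
  list(x = best, f = fbest)
}

#' Fit model parameters by two-stage simulated annealing
#'
#' Calibrates the model against the `fit` split of a study dataset.  The
#' objective is the unweighted mean J-score over all fit-split profiles,
#' each scored against a full simulation of its genotype and condition.
#' Stage 0 evaluates a Latin-hypercube screen of the bounds and narrows
#' them around the best point; the parameters are then optimised twice by
#' annealing runs (the second restarts from the first's optimum, with the
#' bounds re-narrowed around it and a lower initial temperature, so its
#' fixed-fraction proposals act as fine-tuning moves).  Reproducible given
#' `seed`.
#'
#' @param dataset a `study_dataset` with a non-empty fit split.
#' @param init an `aux_params` starting point (also supplies the fixed
#'   constants).  Defaults to [model_parameters()].
#' @param bounds named list of `c(lower, upper)` per fitted parameter;
#'   see [default_bounds()].  The fitted set is `names(bounds)`.
#' @param schedule an [annealing_schedule()].
#' @param seed integer seed for all stochastic elements of the fit.
#' @param variant J-score variant, see [j_score()].
#' @return An object of class `aux_fit`: fitted `params`, fitted
#'   `geno_factors`, per-profile `scores`, per-genotype / per-condition /
#'   per-split aggregates, the optimizer `trace`, the objective at the
#'   initial guess (`objective_init`) and optimum (`objective`), `bounds`,
#'   and `seed`.
#' @export
fit_parameters <- function(dataset, init = model_parameters(),
                           bounds = default_bounds(),
                           schedule = annealing_schedule(), seed = 1L,
                           variant = "mean_relative") {
  stopifnot(inherits(dataset, "study_dataset"), inherits(init, "aux_params"))
  set.seed(seed)
  free <- names(bounds)
  lower <- vapply(bounds, `[`, 0, 1L)
  upper <- vapply(bounds, `[`, 0, 2L)
  if (any(upper < lower)) stop("invalid bounds", call. = FALSE)

  labels <- unique(vapply(dataset$profiles, function(p) p$genotype, ""))
  geno_factors <- lapply(labels, genotype_factors)
  names(geno_factors) <- labels

  fn <- make_objective(dataset, init, geno_factors, variant)

  x0 <- vapply(free, function(nm) {
    v <- switch(nm,
                abcb_nonpolar = geno_factors$abcb1_abcb19$nonpolar_factor %||% 0.5,
                sav3_synthesis = geno_factors$sav3$synthesis_factor %||% 0.5,
                init[[nm]])
    min(max(v, lower[[nm]]), upper[[nm]])
  }, 0)
  names(x0) <- free
  f0 <- fn(x0)
  if (!is.finite(f0)) {
    stop("objective is not finite at the initial guess", call. = FALSE)
  }

  # stage 0: Latin-hypercube screen, then narrow the bounds
  n_screen <- schedule$n_screen
  fs <- f0
  xbest <- x0
  fbest <- f0
  if (n_screen > 0) {
    u <- lhs::randomLHS(n_screen, length(free))
    cand <- sweep(sweep(u, 2, upper - lower, "*"), 2, lower, "+")
    colnames(cand) <- free
    fs <- c(f0, apply(cand, 1, function(r) fn(stats::setNames(r, free))))
    ib <- which.min(fs)
    if (ib > 1L) {
      xbest <- stats::setNames(cand[ib - 1L, ], free)
      fbest <- fs[ib]
    }
  }
  half <- schedule$narrow_frac * (upper - lower) / 2
  nlower <- pmax(lower, xbest - half)
  nupper <- pmin(upper, xbest + half)

  # initial temperature from a pilot sample of proposal deltas around the
  # stage-0 optimum, targeting ~50% early acceptance of a median-size
  # worsening move (t = median / ln 2)
  t_init <- schedule$t_init
  if (is.null(t_init)) {
    deltas <- replicate(30, {
      j <- sample.int(length(xbest), 1L)
      xp <- xbest
      xp[j] <- min(max(
        xp[j] + rnorm(1L, 0, schedule$step_frac * (nupper[j] - nlower[j])),
        nlower[j]), nupper[j])
      fn(xp) - fbest
    })
    deltas <- deltas[is.finite(deltas) & deltas > 0]
    t_init <- if (length(deltas) >= 5) stats::median(deltas) / log(2)
              else max(0.05 * fbest, 1e-8)
  }

  trace_env <- new.env(parent = emptyenv())
  trace_env$rows <- list()
  r1 <- anneal_run(fn, xbest, nlower, nupper, fbest, t_init, schedule,
                   stage = 1L, trace_env)
  # second optimization round: bounds re-narrowed around the first round's
  # optimum, so the fixed-fraction proposals become fine-tuning moves
  half2 <- schedule$narrow_frac^2 * (upper - lower) / 2
  n2lower <- pmax(lower, r1$x - half2)
  n2upper <- pmin(upper, r1$x + half2)
  r2 <- anneal_run(fn, r1$x, n2lower, n2upper, r1$f,
                   max(0.1 * t_init, 1e-10), schedule, stage = 2L,
                   trace_env)

  # local simplex polish: single-coordinate annealing moves stall on
  # correlated (diagonal) valleys of the objective; a bounded Nelder-Mead
  # descent from the annealing optimum resolves them
  fn_box <- function(x) fn(stats::setNames(pmin(pmax(x, lower), upper),
                                           free))
  polish_budget <- min(150 * length(free),
                       2 * schedule$n_temps * schedule$iters_per_temp)
  nm <- stats::optim(r2$x, fn_box, method = "Nelder-Mead",
                     control = list(maxit = polish_budget, reltol = 1e-10))
  if (is.finite(nm$value) && nm$value < r2$f) {
    r2 <- list(x = stats::setNames(pmin(pmax(nm$par, lower), upper), free),
               f = nm$value)
  }
  trace_env$rows[[length(trace_env$rows) + 1L]] <- data.frame(
    stage = 3L, iteration = nm$counts[[1]], temperature = 0,
    proposal = nm$value, accepted = nm$value < r2$f + 1e-300,
    current = r2$f, best = r2$f)

  ap <- apply_theta(r2$x, init, geno_factors)
  scores <- score_dataset(ap$params, dataset, ap$geno_factors,
                          variant = variant)
  fit_avg <- mean(scores$score[scores$split == "fit"])
  val <- scores$score[scores$split == "validation"]

  structure(
    list(
      params = ap$params,
      geno_factors = ap$geno_factors,
      theta = r2$x,
      scores = scores,
      by_genotype = aggregate_scores(scores, "genotype"),
      by_condition = aggregate_scores(scores, "condition"),
      fit_avg = fit_avg,
      validation_avg = if (length(val)) mean(val) else NA_real_,
      objective = r2$f,
      objective_init = f0,
      trace = do.call(rbind, trace_env$rows),
      bounds = bounds,
      seed = seed,
      variant = variant
    ),
    class = "aux_fit"
  )
}

#' @export
print.aux_fit <- function(x, ...) {
  cat(sprintf(
    "<aux_fit> objective %.4g (from %.4g at init), fit avg %.4g, validation avg %.4g\n",
    x$objective, x$objective_init, x$fit_avg, x$validation_avg))
  cat("  by genotype: ",
      paste(sprintf("%s %.3g", names(x$by_genotype), x$by_genotype),
            collapse = ", "), "\n")
  invisible(x)
}

#' Re-score a fit on the fit and validation splits
#'
#' Simulates every profile of `dataset` with the fitted parameters and
#' returns the split averages.
#'
#' @param fit an `aux_fit`.
#' @param dataset a `study_dataset`.
#' @return List with `fit_avg` and (when a validation split exists)
#'   `validation_avg`, plus the per-profile `scores` data frame.
#' @export
validate_fit <- function(fit, dataset) {
  stopifnot(inherits(fit, "aux_fit"))
  scores <- score_dataset(fit$params, dataset, fit$geno_factors,
                          variant = fit$variant)
  out <- list(fit_avg = mean(scores$score[scores$split == "fit"]),
              scores = scores)
  val <- scores$score[scores$split == "validation"]
  if (length(val)) {
    out$validation_avg <- mean(val)
  } else {
    warning("dataset has no validation split; returning fit average only",
            call. = FALSE)
  }
  out
}
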