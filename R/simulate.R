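#' Simulate hypocotyl growth
#'
#' Integrates the auxin transport/growth model from germination (`t = 0`,
#' all lengths `l0`, no auxin) for `duration_days` under a genotype and
#' light regime.  The far-red treatment is governed by the regime (use
#' [with_treatment()] for white-light controls).  The default engine is the
#' compiled explicit-Euler core; `engine = "r"` runs the pure-R [step()]
#' path (identical update, used for cross-checks).
#'
#' @param params an `aux_params`.
#' @param genotype an `aux_genotype`.
#' @param regime an `aux_regime`.
#' @param duration_days length of the run (days); default `fr_end_day`.
#' @param save_every snapshot interval (h).
#' @param n_rows,n_layers grid dimensions.
#' @param init optional `aux_grid` to continue from (with its time).
#' @param root_closed close the root-facing boundary (conservative system).
#' @param engine `"cpp"` (compiled core) or `"r"` (pure-R step loop).
#' @return An object of class `aux_sim` with elements `final_state`
#'   (`aux_grid`), `final_lengths`, `snapshots` (list of `aux_grid`),
#'   `mass_ledger` (data frame: `time_h`, `cum_input`, `cum_degraded`,
#'   `cum_root`, `total_q`), `params`, `genotype`, `regime`.
#' @examples
#' \donttest{
#' sim <- simulate_hypocotyl(default_parameters(), genotype("wt"),
#'                           light_regime("CL75"), duration_days = 6)
#' sim$final_lengths
#' }
#' @export
simulate_hypocotyl <- function(params, genotype = auxgrad::genotype("wt"),
                               regime = light_regime("CL75"),
                               duration_days = NULL, save_every = 6,
                               n_rows = 18, n_layers = 4, init = NULL,
                               root_closed = FALSE,
                               engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  stopifnot(inherits(params, "aux_params"), inherits(genotype, "aux_genotype"),
            inherits(regime, "aux_regime"))
  duration_days <- duration_days %||% regime$fr_end_day
  if (duration_days < 0) stop("duration_days must be >= 0", call. = FALSE)

  state <- init %||% build_grid(n_rows, n_layers, params$l0)
  duration_h <- duration_days * 24
  n_steps <- as.integer(round(duration_h / params$dt))
  save_stride <- max(1L, as.integer(round(save_every / params$dt)))

  if (engine == "cpp") {
    res <- sim_core_cpp(
      q0 = state$q, l0vec = state$l, t0 = state$t,
      n_steps = n_steps, dt = params$dt, save_stride = save_stride,
      pars = unclass(params),
      regime = list(par_intensity = regime$par_intensity,
                    light_hours = light_hours(regime),
                    fr_onset_h = regime$fr_onset_day * 24),
      geno = unclass(genotype),
      ledger0 = attr(state, "ledger") %||% c(0, 0, 0),
      root_closed = root_closed
    )
    tol <- 1e-12 * max(res$cum_input + sum(state$q), 1e-12)
    if (res$clip_total > tol) {
      stop("integration unstable: clipped negative quantities (total ",
           format(res$clip_total, digits = 3), "); reduce `dt`",
           call. = FALSE)
    }
    if (res$clip_total > 0) {
      warning("clipped small negative auxin quantities; consider reducing `dt`",
              call. = FALSE)
    }
    L <- nrow(state$q); R <- ncol(state$q)
    snaps <- lapply(seq_len(res$n_save), function(i) {
      g <- state
      g$q <- matrix(res$save_q[((i - 1) * L * R + 1):(i * L * R)], L, R)
      g$l <- res$save_l[i, ]
      g$t <- res$save_t[i]
      g
    })
    final <- state
    final$q <- res$q; final$l <- res$l; final$t <- res$t
    attr(final, "ledger") <- c(res$cum_input, res$cum_deg, res$cum_root)
    ledger <- as.data.frame(res$ledger)
    names(ledger) <- c("time_h", "cum_input", "cum_degraded", "cum_root",
                       "total_q")
  } else {
    led0 <- attr(state, "ledger") %||% c(0, 0, 0)
    snaps <- list(state)
    ledger <- data.frame(time_h = state$t, cum_input = led0[1],
                         cum_degraded = led0[2], cum_root = led0[3],
                         total_q = sum(state$q[, -ncol(state$q)]))
    led <- led0
    if (n_steps > 0) {
      for (i in seq_len(n_steps)) {
        state <- step(state, params, regime, genotype,
                      root_closed = root_closed)
        led <- led + attr(state, "ledger_increment")
        if (i %% save_stride == 0 || i == n_steps) {
          snaps[[length(snaps) + 1L]] <- state
          ledger <- rbind(ledger, data.frame(
            time_h = state$t, cum_input = led[1], cum_degraded = led[2],
            cum_root = led[3], total_q = sum(state$q[, -ncol(state$q)])))
        }
      }
    }
    final <- state
    attr(final, "ledger") <- unname(led)
    rownames(ledger) <- NULL
  }

  structure(
    list(final_state = final, final_lengths = final$l, snapshots = snaps,
         mass_ledger = ledger, params = params, genotype = genotype,
         regime = regime),
    class = "aux_sim"
  )
}

#' @export
print.aux_sim <- function(x, ...) {
  cat(sprintf(
    "<aux_sim> %s under %s, t = %g h\n  final lengths (um): %s\n  total: %.1f um\n",
    x$genotype$name, x$regime$label, x$final_state$t,
    paste(sprintf("%.1f", x$final_lengths), collapse = " "),
    sum(x$final_lengths)))
  invisible(x)
}

#' Simulate the three standard observation sets of one condition
#'
#' Runs a genotype under one light condition and returns the day-4 profile
#' (white light), the day-6 white-light profile, and the day-6 FR profile,
#' sharing the common white-light trajectory up to FR onset.
#'
#' @inheritParams simulate_hypocotyl
#' @return List with numeric vectors `day4`, `day6_white`, `day6_fr` and
#'   the three `aux_sim` objects (`sim_day4`, `sim_white`, `sim_fr`).
#' @export
simulate_conditions <- function(params, genotype, regime, save_every = 24) {
  onset <- min(regime$fr_onset_day, 4)
  white <- with_treatment(regime, "white")
  base <- simulate_hypocotyl(params, genotype, white, duration_days = onset,
                             save_every = save_every)
  rest <- regime$fr_end_day - onset
  simw <- simulate_hypocotyl(params, genotype, white, duration_days = rest,
                             save_every = save_every,
                             init = base$final_state)
  simf <- simulate_hypocotyl(params, genotype, regime, duration_days = rest,
                             save_every = save_every,
                             init = base$final_state)
  list(day4 = base$final_lengths, day6_white = simw$final_lengths,
       day6_fr = simf$final_lengths,
       sim_day4 = base, sim_white = simw, sim_fr = simf)
}

#' Flatten a simulation to a data frame
#'
#' One row per (snapshot time, layer, row) with columns `time_h`, `layer`,
#' `row`, `q`, `concentration`, `length_um`.  The root row appears with its
#' fixed nominal length.
#'
#' @param x an `aux_sim`.
#' @param ... unused.
#' @return A data frame.
#' @export
as.data.frame.aux_sim <- function(x, ...) {
  do.call(rbind, lapply(x$snapshots, function(g) {
    L <- nrow(g$q); R <- ncol(g$q)
    lfull <- c(g$l, g$l0)
    data.frame(
      time_h = g$t,
      layer = rep(seq_len(L), R),
      row = rep(seq_len(R), each = L),
      q = as.vector(g$q),
      concentration = as.vector(sweep(g$q, 2, lfull, "/")),
      length_um = rep(lfull, each = L)
    )
  }))
}
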