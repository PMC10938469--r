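# shared fixtures: small, fast parameter sets and datasets built in code

# parameters that produce visible growth quickly (coarse dt for speed)
quick_params <- function(...) {
  args <- list(...)
  if (!("dt" %in% names(args))) args$dt <- 0.05
  do.call(default_parameters, args)
}

# a reduced annealing schedule for fit-mechanics tests (the full schedule
# is exercised by the calibration acceptance test)
tiny_schedule <- function() {
  annealing_schedule(iters_per_temp = 15, n_temps = 4, n_screen = 8)
}

small_study <- function(seed = 7L) {
  generate_study(synthetic_spec(noise_sd = 4, n_replicates = 4, seed = seed))
}

# brute-force transport oracle: explicit edge list over the grid graph,
# independent of the matrix-shift implementation
oracle_transport <- function(state, params, I_t, geno = genotype("wt"),
                             root_closed = FALSE) {
  q <- state$q
  L <- nrow(q)
  R <- ncol(q)
  RH <- R - 1
  lfull <- c(state$l, state$l0)
  np <- geno$nonpolar_factor * params$P_np
  P_bot <- np + geno$polar_factor * params$P_polar_bottom
  P_out <- np + geno$polar_factor * params$P_polar_out
  rate <- matrix(0, L, R)
  pair <- matrix(0, L * R, L * R)  # contribution of each directed edge
  idx <- function(ly, r) (r - 1) * L + ly
  donor_val <- function(ly, r) {
    if (params$transport_on_concentration) q[ly, r] / lfull[r] else q[ly, r]
  }
  for (r in seq_len(RH)) {
    for (ly in seq_len(L)) {
      flows <- list()
      if (!(root_closed && r == RH)) {
        flows <- c(flows, list(list(to = c(ly, r + 1), P = P_bot)))
      }
      if (r > 1) flows <- c(flows, list(list(to = c(ly, r - 1), P = np)))
      if (ly > 1) flows <- c(flows, list(list(to = c(ly - 1, r), P = P_out)))
      if (ly < L) flows <- c(flows, list(list(to = c(ly + 1, r), P = np)))
      for (f in flows) {
        v <- f$P * donor_val(ly, r)
        rate[ly, r] <- rate[ly, r] - v
        rate[f$to[1], f$to[2]] <- rate[f$to[1], f$to[2]] + v
        pair[idx(ly, r), idx(f$to[1], f$to[2])] <-
          pair[idx(ly, r), idx(f$to[1], f$to[2])] + v
      }
    }
  }
  S3 <- sigmoid(I_t, params$u_I, params$a3, clamp = params$clamp_regulatory)
  for (r in seq_len(RH)) {
    for (ly in seq_len(L)) {
      rate[ly, r] <- rate[ly, r] - params$eta * q[ly, r] / state$l[r] * S3
    }
  }
  list(rate = rate, pair = pair)
}

is_unimodal <- function(x, tol = 1e-9) {
  d <- diff(x)
  d[abs(d) < tol] <- 0
  s <- sign(d)
  s <- s[s != 0]
  sum(diff(s) != 0) <= 1
}
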