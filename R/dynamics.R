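# Pure-R reference implementation of the model dynamics.  simulate_hypocotyl()
# normally runs the compiled core; these functions define the same update and
# are the unit-testable surface for single rates and single steps.

#' Auxin input rate into the top endodermal cell
#'
#' Rate at which auxin produced in the cotyledons enters the hypocotyl:
#' `input_factor * synthesis_factor * mu * alpha(t) * M1(I_c0 + int I, u_c)`.
#' The Monod term tracks cumulative light (cotyledon size); `alpha(t)` is
#' the red:far-red production modifier.  The input is applied only to the
#' endodermal cell of row 1.
#'
#' @param t time (h).
#' @param params an `aux_params`.
#' @param regime an `aux_regime`.
#' @param genotype an `aux_genotype`.
#' @return Input rate (quantity/h).
#' @export
auxin_input_rate <- function(t, params, regime,
                             genotype = auxgrad::genotype("wt")) {
  stopifnot(all(t >= 0))
  genotype$input_factor * genotype$synthesis_factor * params$mu_input *
    production_modifier(t, regime, params) *
    monod(params$I_c0 + cumulative_light(t, regime), params$u_c, params$b1,
          clamp = params$clamp_regulatory)
}

face_permeabilities <- function(params, genotype) {
  list(
    bottom = genotype$nonpolar_factor * params$P_np +
      genotype$polar_factor * params$P_polar_bottom,
    top = genotype$nonpolar_factor * params$P_np,
    out = genotype$nonpolar_factor * params$P_np +
      genotype$polar_factor * params$P_polar_out,
    inward = genotype$nonpolar_factor * params$P_np
  )
}

#' Transport and degradation rates
#'
#' For every cell, the net rate `sum_j (P_ji q_j - P_ij q_i) - eta *
#' (q_i/l_i) * S3(I_t, u_I)`.  Neighbourhood: vertical neighbours within a
#' layer, horizontal neighbours between adjacent layers.  Face
#' permeabilities are the non-polar component on every face plus the polar
#' basipetal component on the bottom face and the polar centrifugal
#' component on the outward face.  Closed boundaries: the epidermis outer
#' face, the endodermis inner face, and the top of row 1.  The root row
#' receives the basipetal flux from the last hypocotyl row and returns
#' nothing (absorbing sink, no degradation).
#'
#' @param state an `aux_grid`.
#' @param params an `aux_params`.
#' @param I_t current PAR intensity (uE).
#' @param genotype an `aux_genotype`.
#' @param root_closed close the face into the root row (used to express a
#'   fully conservative system in tests).
#' @return List with `rate` (matrix like `q`), `degradation_rate` (total,
#'   quantity/h) and `root_rate` (flux into the root row, quantity/h).
#' @export
transport_and_decay_rates <- function(state, params, I_t,
                                      genotype = auxgrad::genotype("wt"),
                                      root_closed = FALSE) {
  q <- state$q
  L <- nrow(q)
  R <- ncol(q)
  RH <- R - 1L
  if (length(state$l) != RH) {
    stop("state length vector does not match grid", call. = FALSE)
  }
  lfull <- c(state$l, state$l0)
  P <- face_permeabilities(params, genotype)

  qd <- q
  if (params$transport_on_concentration) {
    qd <- sweep(q, 2, lfull, "/")
  }
  rate <- matrix(0, L, R)
  hyp <- seq_len(RH)

  # bottom faces: donors rows 1..RH -> receivers rows 2..RH+1
  don <- if (root_closed) seq_len(RH - 1L) else hyp
  if (length(don)) {
    f <- P$bottom * qd[, don, drop = FALSE]
    rate[, don] <- rate[, don] - f
    rate[, don + 1L] <- rate[, don + 1L] + f
  }
  root_rate <- if (root_closed) 0 else sum(P$bottom * qd[, RH])

  # top faces: donors rows 2..RH -> receivers rows 1..RH-1
  if (RH >= 2L) {
    don <- 2:RH
    f <- P$top * qd[, don, drop = FALSE]
    rate[, don] <- rate[, don] - f
    rate[, don - 1L] <- rate[, don - 1L] + f
  }
  # outward faces: donor layers 2..L -> receiver layers 1..L-1
  if (L >= 2L) {
    f <- P$out * qd[2:L, hyp, drop = FALSE]
    rate[2:L, hyp] <- rate[2:L, hyp] - f
    rate[1:(L - 1L), hyp] <- rate[1:(L - 1L), hyp] + f
    # inward faces: donor layers 1..L-1 -> receiver layers 2..L
    f <- P$inward * qd[1:(L - 1L), hyp, drop = FALSE]
    rate[1:(L - 1L), hyp] <- rate[1:(L - 1L), hyp] - f
    rate[2:L, hyp] <- rate[2:L, hyp] + f
  }

  S3 <- sigmoid(I_t, params$u_I, params$a3, clamp = params$clamp_regulatory)
  deg <- params$eta * sweep(q[, hyp, drop = FALSE], 2, state$l, "/") * S3
  rate[, hyp] <- rate[, hyp] - deg

  list(rate = rate, degradation_rate = sum(deg), root_rate = root_rate)
}

#' Epidermal growth rates
#'
#' `rate_k = lambda * S1(A_k, u_mu)` where `A_k` is the auxin concentration
#' of the epidermal cell in row `k`.  Only the epidermis drives elongation;
#' inner layers follow passively, so all layers of a row share its length.
#'
#' @inheritParams transport_and_decay_rates
#' @return Vector of row elongation rates (um/h).
#' @export
growth_rates <- function(state, params) {
  A <- epidermal_concentration(state)
  params$lambda_growth *
    sigmoid(A, params$u_mu, params$a1, clamp = params$clamp_regulatory)
}

#' Advance the grid by one Euler step
#'
#' Explicit-Euler update over `params$dt`: transport/degradation plus the
#' auxin source into the top endodermal cell update `q`; epidermal growth
#' updates the row lengths; time advances by `dt`.  Any negative quantity
#' that would arise is clipped at zero with a warning (the step size is too
#' large); clips beyond `1e-12` of cumulative input abort.
#'
#' @inheritParams transport_and_decay_rates
#' @param regime an `aux_regime`.
#' @return The updated `aux_grid` (with an attribute `ledger_increment`
#'   holding the input/degradation/root-flux increments of this step).
#' @export
step <- function(state, params, regime,
                 genotype = auxgrad::genotype("wt"), root_closed = FALSE) {
  dt <- params$dt
  I_t <- par_intensity(state$t, regime)
  td <- transport_and_decay_rates(state, params, I_t, genotype,
                                  root_closed = root_closed)
  input <- auxin_input_rate(state$t, params, regime, genotype)
  gr <- growth_rates(state, params)

  L <- nrow(state$q)
  qn <- state$q + dt * td$rate
  qn[L, 1] <- qn[L, 1] + dt * input
  clip <- -sum(qn[qn < 0])
  if (clip > 0) {
    tol <- 1e-12 * max(dt * input + sum(state$q), 1e-12)
    if (clip > tol) {
      stop("integration unstable: negative auxin quantities (total ",
           format(clip, digits = 3),
           ") exceeded tolerance; reduce `dt`", call. = FALSE)
    }
    warning("clipped small negative auxin quantities; consider reducing `dt`",
            call. = FALSE)
    qn[qn < 0] <- 0
  }
  state$q <- qn
  state$l <- state$l + dt * gr
  state$t <- state$t + dt
  attr(state, "ledger_increment") <- c(
    input = dt * input,
    degraded = dt * td$degradation_rate,
    root = dt * td$root_rate
  )
  state
}
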