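#' Model parameters
#'
#' Constructs and validates the full parameter set of the auxin
#' transport/growth model.  Units: lengths in micrometres, time in hours,
#' light in uE (umol photons m-2 s-1), auxin in arbitrary quantity units
#' (concentration = quantity / cell length).
#'
#' @param lambda_growth maximal cell elongation rate (um/h).
#' @param u_mu translational value of the growth sigmoid (auxin
#'   concentration units): epidermal concentration below which cells do not
#'   elongate.
#' @param a1 shape constant of the growth sigmoid.
#' @param mu_input maximal auxin input rate into the top endodermal cell
#'   (quantity/h).
#' @param I_c0 initial light-integration value (uE), set arbitrarily to 25.
#' @param u_c translational value of the cumulative-light Monod term (uE h).
#' @param b1 half constant of the cumulative-light Monod term (uE h).
#' @param beta natural red:far-red ratio (dimensionless).
#' @param u_fr translational value of the far-red production switch.
#' @param a2 shape constant of the far-red production switch.
#' @param I_fr_max maximal relative far-red signal (default 1, so the signal
#'   is continuous at far-red onset).
#' @param epsilon residual active-phytochrome fraction (default 0.3).
#' @param eta degradation parameter (um/h scale: the degradation rate is
#'   `eta * concentration * S3`).
#' @param u_I translational value of the degradation light sigmoid (uE).
#' @param a3 shape constant of the degradation light sigmoid.
#' @param P_np non-polar per-face permeability (1/h), the ABCB-type
#'   component present on all four faces.
#' @param P_polar_bottom additional basipetal (PIN-type) permeability (1/h);
#'   the bottom face carries `P_np + P_polar_bottom`.
#' @param P_polar_out additional centrifugal (toward-epidermis) permeability
#'   (1/h); the outward face carries `P_np + P_polar_out`.
#' @param dt explicit-Euler integration step (h).
#' @param l0 initial cell length (um).
#' @param clamp_regulatory clamp `x - u` at zero inside the regulatory
#'   functions so each response is monotone above its translational value
#'   (default `TRUE`; `FALSE` gives the symmetric printed form).
#' @param transport_on_concentration if `TRUE`, transport fluxes act on
#'   donor concentration `q/l` instead of quantity `q` (exploratory option;
#'   default `FALSE`, the literal quantity-based rule).
#' @return An object of class `aux_params` (a validated named list).
#' @seealso [default_parameters()] for the calibrated set shipped with the
#'   package, [perturb()] for sensitivity perturbations.
#' @export
model_parameters <- function(lambda_growth = 25,
                             u_mu = 2,
                             a1 = 0.6,
                             mu_input = 600,
                             I_c0 = 25,
                             u_c = 600,
                             b1 = 4500,
                             beta = 1.7,
                             u_fr = 0.4,
                             a2 = 3,
                             I_fr_max = 1,
                             epsilon = 0.3,
                             eta = 4,
                             u_I = 20,
                             a3 = 70000,
                             P_np = 0.3,
                             P_polar_bottom = 0.3,
                             P_polar_out = 0.02,
                             dt = 0.01,
                             l0 = 10,
                             clamp_regulatory = TRUE,
                             transport_on_concentration = FALSE) {
  p <- list(
    lambda_growth = lambda_growth, u_mu = u_mu, a1 = a1,
    mu_input = mu_input, I_c0 = I_c0, u_c = u_c, b1 = b1,
    beta = beta, u_fr = u_fr, a2 = a2,
    I_fr_max = I_fr_max, epsilon = epsilon,
    eta = eta, u_I = u_I, a3 = a3,
    P_np = P_np, P_polar_bottom = P_polar_bottom,
    P_polar_out = P_polar_out,
    dt = dt, l0 = l0,
    clamp_regulatory = isTRUE(clamp_regulatory),
    transport_on_concentration = isTRUE(transport_on_concentration)
  )
  validate_parameters(p)
}

#' @rdname model_parameters
#' @param p a candidate parameter list.
#' @export
validate_parameters <- function(p) {
  num <- setdiff(names(p), c("clamp_regulatory", "transport_on_concentration"))
  for (nm in num) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("parameter `", nm, "` must be a single finite number", call. = FALSE)
    }
  }
  nonneg <- c("lambda_growth", "u_mu", "a1", "mu_input", "I_c0", "u_c", "b1",
              "beta", "u_fr", "a2", "eta", "u_I", "a3",
              "P_np", "P_polar_bottom", "P_polar_out")
  for (nm in nonneg) {
    if (p[[nm]] < 0) stop("parameter `", nm, "` must be >= 0", call. = FALSE)
  }
  if (p$a1 <= 0 || p$a2 <= 0 || p$a3 <= 0 || p$b1 <= 0) {
    stop("shape/half constants a1, a2, a3, b1 must be > 0", call. = FALSE)
  }
  if (p$dt <= 0) stop("`dt` must be > 0", call. = FALSE)
  if (p$l0 <= 0) stop("`l0` must be > 0", call. = FALSE)
  if (p$epsilon <= 0 || p$epsilon > 1) {
    stop("`epsilon` must lie in (0, 1]", call. = FALSE)
  }
  if (p$I_fr_max <= 0) stop("`I_fr_max` must be > 0", call. = FALSE)
  structure(p, class = "aux_params")
}

#' Calibrated default parameters
#'
#' The parameter set obtained by running the package's two-stage
#' simulated-annealing calibration ([fit_parameters()]) against the packaged
#' synthetic study ([generate_study()] with its default specification) and
#' freezing the fitted values.  They are the package's working defaults for
#' simulation examples and structural tests, not measured constants.
#'
#' @param ... overrides passed to [model_parameters()].
#' @return An `aux_params` object.
#' @export
default_parameters <- function(...) {
  base <- list(
    lambda_growth = 40,
    u_mu = 2.4376,
    a1 = 0.001,
    mu_input = 692.4082,
    I_c0 = 25,
    u_c = 0,
    b1 = 4872.23,
    beta = 2.016912,
    u_fr = 0.7424714,
    a2 = 2.928803,
    I_fr_max = 1,
    epsilon = 0.3,
    eta = 2.956263,
    u_I = 5.092684,
    a3 = 88145.59,
    P_np = 0.1547805,
    P_polar_bottom = 0.2353261,
    P_polar_out = 0.01,
    dt = 0.01,
    l0 = 10
  )
  do.call(model_parameters, modifyList(base, list(...)))
}

#' Calibrated default genotype factors
#'
#' Genotype multipliers fitted alongside [default_parameters()]: the
#' `abcb1 abcb19` non-polar transport factor and the `sav3` synthesis
#' factor.  The `pin3 pin4 pin7` factors are fixed at 0.1 by construction.
#'
#' @return Named list of [genotype()] objects for `wt`, `abcb1_abcb19`,
#'   `sav3` and `pin3_pin4_pin7`.
#' @export
default_genotype_factors <- function() {
  list(
    wt = genotype("wt"),
    abcb1_abcb19 = genotype("abcb1_abcb19", nonpolar_factor = 0.8419337),
    sav3 = genotype("sav3", synthesis_factor = 0.7898063),
    pin3_pin4_pin7 = genotype("pin3_pin4_pin7")
  )
}

#' @export
print.aux_params <- function(x, ...) {
  cat("<aux_params> auxin transport/growth model parameters\n")
  num <- vapply(x, function(v) if (is.logical(v)) as.character(v)
                else format(v, digits = 4), "")
  cat(paste0("  ", format(names(x), width = 28), num, collapse = "\n"), "\n")
  invisible(x)
}

#' Read and write parameter configuration files
#'
#' Parameters are stored as a flat key-value mapping (JSON or YAML, chosen
#' by file extension), one key per [model_parameters()] field.  Unknown keys
#' are rejected; missing keys take the constructor defaults.
#'
#' @param path file path ending in `.json`, `.yaml` or `.yml`.
#' @return `read_parameters()` returns an `aux_params` object;
#'   `write_parameters()` returns `path` invisibly.
#' @export
read_parameters <- function(path) {
  cfg <- read_config(path)
  known <- names(formals(model_parameters))
  bad <- setdiff(names(cfg), known)
  if (length(bad)) {
    stop("unknown parameter key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  do.call(model_parameters, cfg)
}

#' @rdname read_parameters
#' @param params an `aux_params` object.
#' @export
write_parameters <- function(params, path) {
  stopifnot(inherits(params, "aux_params"))
  write_config(unclass(params), path)
  invisible(path)
}

#' Perturb one parameter by a signed fraction
#'
#' Returns a copy of `params` with field `name` multiplied by
#' `1 + fraction`, for one-at-a-time sensitivity scans.
#'
#' @param params an `aux_params` object.
#' @param name parameter key to perturb.
#' @param fraction signed relative change, e.g. `0.01` for +1 percent.
#' @return A validated `aux_params` copy.
#' @export
perturb <- function(params, name, fraction) {
  stopifnot(inherits(params, "aux_params"))
  if (!name %in% names(params) || is.logical(params[[name]])) {
    stop("unknown or non-numeric parameter `", name, "`", call. = FALSE)
  }
  params[[name]] <- params[[name]] * (1 + fraction)
  validate_parameters(unclass(params))
}
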