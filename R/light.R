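#' Light regimes
#'
#' A light regime holds the photosynthetically active radiation (PAR)
#' schedule and the far-red (FR) treatment window.  The four study
#' conditions combine continuous light (CL) or a 16 h : 8 h long-day (LD)
#' photoperiod with fluence rates of 75 or 130 uE.  FR is switched on at the
#' start of `fr_onset_day` (day d begins at `t = 24 d` hours; onset at
#' t = 96 h for the default day 4) and the treatment window ends at
#' `fr_end_day` (default 6).
#'
#' @param label preset name `"CL75"`, `"CL130"`, `"LD75"` or `"LD130"`, or
#'   any tag when the other arguments are given explicitly.
#' @param par_intensity fluence rate during the light phase (uE).
#' @param photoperiod `"continuous"` or `"long_day"` (16 h light : 8 h dark,
#'   each 24 h cycle starting with light at t = 0).
#' @param fr_onset_day day FR is switched on; `Inf` for an untreated
#'   (white-light) run.
#' @param fr_end_day end of the treatment window (simulation horizon).
#' @return An object of class `aux_regime`.
#' @examples
#' light_regime("CL75")
#' light_regime("LD130", fr_onset_day = Inf)   # white-light control
#' @export
light_regime <- function(label = "CL75", par_intensity = NULL,
                         photoperiod = NULL, fr_onset_day = 4,
                         fr_end_day = 6) {
  presets <- list(
    CL75  = list(par = 75,  photo = "continuous"),
    CL130 = list(par = 130, photo = "continuous"),
    LD75  = list(par = 75,  photo = "long_day"),
    LD130 = list(par = 130, photo = "long_day")
  )
  if (is.null(par_intensity) || is.null(photoperiod)) {
    if (!label %in% names(presets)) {
      stop("unknown regime label `", label,
           "`; give par_intensity and photoperiod explicitly", call. = FALSE)
    }
    par_intensity <- par_intensity %||% presets[[label]]$par
    photoperiod <- photoperiod %||% presets[[label]]$photo
  }
  photoperiod <- match.arg(photoperiod, c("continuous", "long_day"))
  if (par_intensity < 0) stop("par_intensity must be >= 0", call. = FALSE)
  if (fr_onset_day < 0 || fr_end_day < fr_onset_day && is.finite(fr_onset_day)) {
    stop("need 0 <= fr_onset_day <= fr_end_day", call. = FALSE)
  }
  structure(
    list(label = label, par_intensity = par_intensity,
         photoperiod = photoperiod, fr_onset_day = fr_onset_day,
         fr_end_day = fr_end_day),
    class = "aux_regime"
  )
}

#' @export
print.aux_regime <- function(x, ...) {
  cat(sprintf("<aux_regime> %s: %g uE, %s, FR day %g-%g\n", x$label,
              x$par_intensity, x$photoperiod, x$fr_onset_day, x$fr_end_day))
  invisible(x)
}

#' Apply a treatment to a regime
#'
#' `"white"` disables the FR window (onset at infinity); `"FR"` restores the
#' regime's configured onset day (default 4).
#'
#' @param regime an `aux_regime`.
#' @param treatment `"white"` or `"FR"`.
#' @param fr_onset_day onset day used when `treatment = "FR"` and the regime
#'   has no finite onset.
#' @return A modified `aux_regime`.
#' @export
with_treatment <- function(regime, treatment = c("FR", "white"),
                           fr_onset_day = 4) {
  treatment <- match.arg(treatment)
  if (treatment == "white") {
    regime$fr_onset_day <- Inf
  } else if (!is.finite(regime$fr_onset_day)) {
    regime$fr_onset_day <- fr_onset_day
  }
  regime
}

light_hours <- function(regime) {
  if (regime$photoperiod == "continuous") 24 else 16
}

#' PAR intensity at a time point
#'
#' Piecewise-constant fluence rate: the regime's intensity during the light
#' phase, zero during the dark phase of a long-day cycle.
#'
#' @param t time since germination (h), scalar or vector.
#' @param regime an `aux_regime`.
#' @return Fluence rate(s) in uE.
#' @export
par_intensity <- function(t, regime) {
  stopifnot(all(t >= 0))
  lh <- light_hours(regime)
  if (lh >= 24) return(rep_len(regime$par_intensity, length(t)))
  ifelse(t %% 24 < lh, regime$par_intensity, 0)
}

#' Cumulative light integral
#'
#' Closed-form integral of the piecewise-constant PAR schedule from 0 to
#' `t`, a proxy for cotyledon (auxin source) size.
#'
#' @inheritParams par_intensity
#' @return Integrated light in uE h.
#' @export
cumulative_light <- function(t, regime) {
  stopifnot(all(t >= 0))
  lh <- light_hours(regime)
  if (lh >= 24) return(regime$par_intensity * t)
  days <- floor(t / 24)
  tod <- t - 24 * days
  regime$par_intensity * (days * lh + pmin(tod, lh))
}

#' Relative phytochrome (far-red) signal
#'
#' Before FR onset the signal is 1 (white light).  After onset it decays
#' with apparent first-order kinetics and a 30 min half-life,
#' \eqn{I_{fr,max} 2^{-2s}} for `s` hours since onset, until it reaches the
#' residual plateau `epsilon * I_fr_max` (about 30 percent of phytochrome
#' remains active) at \eqn{s = -\log_2(\epsilon)/2}.
#'
#' @inheritParams par_intensity
#' @param params an `aux_params` (uses `epsilon`, `I_fr_max`).
#' @return Relative signal value(s).
#' @export
phytochrome_signal <- function(t, regime, params) {
  stopifnot(all(t >= 0))
  onset <- regime$fr_onset_day * 24
  s <- t - onset
  s_star <- -log2(params$epsilon) / 2
  out <- rep_len(1, length(t))
  dec <- is.finite(onset) & s >= 0 & s <= s_star
  plat <- is.finite(onset) & s > s_star
  out[dec] <- params$I_fr_max * 2^(-2 * s[dec])
  out[plat] <- params$epsilon * params$I_fr_max
  out
}

#' Auxin production modifier alpha(t)
#'
#' The effect of the red:far-red ratio on auxin production:
#' \eqn{\alpha(t) = 1 - S_2(\beta I_{fr}(t), u_{fr})}.  In white light the
#' effective ratio `beta * 1` is high and production is partly suppressed;
#' under FR the phytochrome signal falls toward `epsilon`, the sigmoid
#' argument drops and production rises.
#'
#' @inheritParams phytochrome_signal
#' @return Modifier value(s) in `[0, 1]`.
#' @export
production_modifier <- function(t, regime, params) {
  ifr <- phytochrome_signal(t, regime, params)
  1 - sigmoid(params$beta * ifr, params$u_fr, params$a2,
              clamp = params$clamp_regulatory)
}
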