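#' One-at-a-time parameter sensitivity scan
#'
#' Perturbs each fitted parameter by `+fraction` and `-fraction` (default
#' 1 percent), re-simulates the fit-split conditions, and reports the
#' J-score difference `delta_J = (baseline global J) - (perturbed global
#' J)`.  The global J is the unweighted mean over fit-split profiles, i.e.
#' the calibration objective, so the baseline equals the fit's final score.
#' Negative `delta_J` means the perturbation worsened the fit; the most
#' negative values mark the most sensitive parameters.
#'
#' @param fit an `aux_fit`.
#' @param dataset a `study_dataset` with a fit split.
#' @param fraction relative perturbation (default `0.01`).
#' @param parameters keys to scan; defaults to all fitted parameters
#'   (`names(fit$bounds)`).  Fixed constants can be included explicitly.
#' @return An object of class `sensitivity_report`: a data frame with
#'   columns `parameter`, `sign` (`"+"`/`"-"`), `delta_J` and `rank`
#'   (1 = most negative `delta_J`), with the baseline score in attribute
#'   `baseline`.
#' @export
sensitivity_scan <- function(fit, dataset, fraction = 0.01,
                             parameters = NULL) {
  stopifnot(inherits(fit, "aux_fit"), inherits(dataset, "study_dataset"))
  fitset <- filter_profiles(dataset, split = "fit")
  if (!length(fitset$profiles)) {
    stop("dataset has an empty fit split", call. = FALSE)
  }
  parameters <- parameters %||% names(fit$bounds)

  global_j <- function(params, geno_factors) {
    sc <- score_dataset(params, fitset, geno_factors, variant = fit$variant)
    mean(sc$score)
  }
  baseline <- global_j(fit$params, fit$geno_factors)

  perturb_one <- function(name, frac) {
    params <- fit$params
    gf <- fit$geno_factors
    if (name == "abcb_nonpolar") {
      if (is.null(gf$abcb1_abcb19)) return(baseline)
      gf$abcb1_abcb19$nonpolar_factor <-
        min(gf$abcb1_abcb19$nonpolar_factor * (1 + frac), 1)
    } else if (name == "sav3_synthesis") {
      if (is.null(gf$sav3)) return(baseline)
      gf$sav3$synthesis_factor <-
        min(gf$sav3$synthesis_factor * (1 + frac), 1)
    } else {
      params <- perturb(params, name, frac)
    }
    tryCatch(global_j(params, gf), error = function(e) {
      warning("sensitivity entry failed for ", name, " (", frac, "): ",
              conditionMessage(e), call. = FALSE)
      NA_real_
    })
  }

  rows <- list()
  for (nm in parameters) {
    for (sg in c(1, -1)) {
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = nm, sign = if (sg > 0) "+" else "-",
        delta_J = baseline - perturb_one(nm, sg * fraction)
      )
    }
  }
  rep <- do.call(rbind, rows)
  rep$rank <- rank(rep$delta_J, ties.method = "min")
  structure(rep, class = c("sensitivity_report", "data.frame"),
            baseline = baseline, fraction = fraction)
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf("<sensitivity_report> baseline global J = %.5g, +/-%g%% scan\n",
              attr(x, "baseline"), 100 * attr(x, "fraction")))
  ord <- order(x$delta_J)
  print.data.frame(head(x[ord, ], 10), row.names = FALSE)
  if (nrow(x) > 10) cat("  ... (", nrow(x), "entries )\n")
  invisible(x)
}

#' @importFrom utils head
NULL
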