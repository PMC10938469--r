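#' Genotype scenarios
#'
#' A genotype enters the model as four multiplicative factors in `[0, 1]`:
#' `synthesis_factor` on the maximal auxin input rate (auxin biosynthesis,
#' TAA1/SAV3), `nonpolar_factor` on the non-polar permeability (ABCB1/19),
#' `polar_factor` on both polar permeability components (PIN3/4/7), and
#' `input_factor` on the auxin entry term (cotyledon-to-hypocotyl transfer,
#' itself PIN-dependent).  The wild type has all factors 1; the
#' `pin3 pin4 pin7` triple mutant is defined by the 10 percent input and
#' 10 percent polar-transport scenario.
#'
#' @param name one of `"wt"`, `"abcb1_abcb19"`, `"sav3"`,
#'   `"pin3_pin4_pin7"`, or `"custom"`.
#' @param synthesis_factor,nonpolar_factor,polar_factor,input_factor
#'   multipliers in `[0, 1]`; defaults depend on `name`.
#' @return An object of class `aux_genotype`.
#' @examples
#' genotype("wt")
#' genotype("pin3_pin4_pin7")                      # 0.1 polar, 0.1 input
#' genotype("sav3", synthesis_factor = 0.3)
#' @export
genotype <- function(name = c("wt", "abcb1_abcb19", "sav3",
                              "pin3_pin4_pin7", "custom"),
                     synthesis_factor = NULL, nonpolar_factor = NULL,
                     polar_factor = NULL, input_factor = NULL) {
  name <- match.arg(name)
  def <- switch(name,
    wt             = c(1, 1, 1, 1),
    abcb1_abcb19   = c(1, NA, 1, 1),   # nonpolar factor must be supplied/fitted
    sav3           = c(NA, 1, 1, 1),   # synthesis factor must be supplied/fitted
    pin3_pin4_pin7 = c(1, 1, 0.1, 0.1),
    custom         = c(1, 1, 1, 1)
  )
  f <- c(
    synthesis_factor %||% def[1],
    nonpolar_factor  %||% def[2],
    polar_factor     %||% def[3],
    input_factor     %||% def[4]
  )
  if (anyNA(f)) {
    # a mutant whose free factor was not supplied: fall back to 1 so the
    # object is usable before fitting; fit_parameters() treats it as free
    f[is.na(f)] <- 1
  }
  if (any(f < 0 | f > 1)) {
    stop("genotype factors must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(name = name, synthesis_factor = f[1], nonpolar_factor = f[2],
         polar_factor = f[3], input_factor = f[4]),
    class = "aux_genotype"
  )
}

#' Map a genotype label to its model factors
#'
#' Known labels: `wt` (all factors 1), `pin3_pin4_pin7` (polar and input
#' factors 0.1), `abcb1_abcb19` (non-polar factor free in `[0, 1]`, supplied
#' via `...` or left at 1 until fitted), `sav3` (synthesis factor free,
#' likewise).  Unknown labels error unless explicit factors are given.
#'
#' @param name genotype label.
#' @param ... explicit factor overrides passed to [genotype()].
#' @return An `aux_genotype` object.
#' @export
genotype_factors <- function(name, ...) {
  known <- c("wt", "abcb1_abcb19", "sav3", "pin3_pin4_pin7")
  if (!name %in% known) {
    dots <- list(...)
    if (!length(dots)) {
      stop("unknown genotype `", name,
           "`; supply explicit factors or use one of: ",
           paste(known, collapse = ", "), call. = FALSE)
    }
    return(genotype("custom", ...))
  }
  genotype(name, ...)
}

#' @export
print.aux_genotype <- function(x, ...) {
  cat(sprintf(
    "<aux_genotype> %s (synthesis %.3g, nonpolar %.3g, polar %.3g, input %.3g)\n",
    x$name, x$synthesis_factor, x$nonpolar_factor, x$polar_factor,
    x$input_factor))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
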