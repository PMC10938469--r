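#' Build the cellular grid
#'
#' The hypocotyl is a 2-D matrix of cells: `n_layers` concentric layers
#' (1 = epidermis, 2 = outer cortex, 3 = inner cortex, 4 = endodermis in the
#' standard four-layer grid) by `n_rows` rows top to bottom, plus one extra
#' row at the bottom representing the root compartment (row `n_rows + 1`),
#' added to avoid boundary artefacts at the lower end.  All four layers of a
#' row share one row length (the epidermis dictates elongation); the root
#' row has a fixed nominal length and never grows.
#'
#' @param n_rows number of hypocotyl cell rows (18 in the standard model).
#' @param n_layers number of cell layers (4 in the standard model).
#' @param l0 initial cell length (um).
#' @return An object of class `aux_grid` with elements `q` (layers x rows
#'   quantity matrix, all zero), `l` (`n_rows` lengths, all `l0`), and
#'   `t = 0`.
#' @examples
#' g <- build_grid()          # 4 x 19 grid, 18 lengths of 10 um
#' dim(g$q)
#' @export
build_grid <- function(n_rows = 18, n_layers = 4, l0 = 10) {
  if (n_rows < 1 || n_layers < 1) {
    stop("n_rows and n_layers must be >= 1", call. = FALSE)
  }
  if (l0 <= 0) stop("l0 must be > 0", call. = FALSE)
  structure(
    list(
      q = matrix(0, nrow = n_layers, ncol = n_rows + 1,
                 dimnames = list(layer = NULL, row = NULL)),
      l = rep(l0, n_rows),
      t = 0,
      l0 = l0
    ),
    class = "aux_grid"
  )
}

#' @export
print.aux_grid <- function(x, ...) {
  cat(sprintf(
    "<aux_grid> %d layers x %d rows (+ root), t = %g h, total q = %.4g\n",
    nrow(x$q), ncol(x$q) - 1L, x$t, sum(x$q[, -ncol(x$q)])))
  invisible(x)
}

#' Epidermal concentration profile of a grid state
#'
#' @param state an `aux_grid`.
#' @return Concentrations `q/l` of the epidermal (layer 1) hypocotyl cells.
#' @export
epidermal_concentration <- function(state) {
  nh <- ncol(state$q) - 1L
  state$q[1, seq_len(nh)] / state$l
}
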