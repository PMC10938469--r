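#' J-score: deviation between measured and simulated profiles
#'
#' Fit-quality objective comparing a measured cell-length profile with the
#' simulated 18 lengths.  The default `mean_relative` variant is the mean
#' relative absolute error `(1/18) * sum_k |l_k - g_k| / l_k` (dimensionless
#' and scale-free across cells).  The `literal` variant evaluates the score
#' exactly as printed in the source model, `dt * sum_k |l_k - g_k l_k|`,
#' reading the simulated value as a scale factor on the measured mean.
#'
#' @param measured a `cell_length_profile`.
#' @param simulated_lengths 18 simulated lengths (um).
#' @param variant `"mean_relative"` (default) or `"literal"`.
#' @param dt weighting step for the literal variant (h).
#' @return Non-negative score; 0 means a perfect fit (mean_relative).
#' @examples
#' p <- cell_length_profile("wt", "CL75", "FR", 6, rep(100, 18))
#' j_score(p, rep(110, 18))   # uniform 10 percent deviation -> 0.10
#' @export
j_score <- function(measured, simulated_lengths,
                    variant = c("mean_relative", "literal"), dt = 0.01) {
  variant <- match.arg(variant)
  stopifnot(inherits(measured, "cell_length_profile"))
  if (length(simulated_lengths) != 18L) {
    stop("simulated_lengths must have 18 entries", call. = FALSE)
  }
  l <- measured$mean_lengths
  g <- simulated_lengths
  if (variant == "mean_relative") {
    mean(abs(l - g) / l)
  } else {
    dt * sum(abs(l - g * l))
  }
}

#' Aggregate J-scores by group
#'
#' Arithmetic mean of scores per genotype, condition or split, as used to
#' summarise fit quality per genotype and per growth condition.
#'
#' @param scores data frame with columns `genotype`, `condition`, `split`,
#'   `score` (as produced by [score_dataset()]).
#' @param by grouping: `"genotype"`, `"condition"` or `"split"`.
#' @return Named numeric vector of group means.
#' @export
aggregate_scores <- function(scores, by = c("genotype", "condition",
                                            "split")) {
  by <- match.arg(by)
  if (!nrow(scores)) stop("no scores to aggregate", call. = FALSE)
  v <- tapply(scores$score, scores[[by]], mean)
  stats::setNames(as.vector(v), names(v))
}

#' Score every profile of a dataset against the model
#'
#' Simulates each (genotype, condition) pair present in the dataset once
#' (sharing the trajectory up to FR onset) and computes the J-score of
#' every profile against the matching simulated day/treatment lengths.
#'
#' @param params an `aux_params`.
#' @param dataset a `study_dataset`.
#' @param geno_factors named list of `aux_genotype` objects keyed by
#'   genotype label (defaults to [genotype_factors()] on each label).
#' @param variant J-score variant, see [j_score()].
#' @param save_every snapshot interval passed to the underlying
#'   simulations (h); scoring only needs the endpoints.
#' @return Data frame with one row per profile: `genotype`, `condition`,
#'   `treatment`, `day`, `split`, `score`.
#' @export
score_dataset <- function(params, dataset, geno_factors = NULL,
                          variant = "mean_relative", save_every = 96) {
  profs <- dataset$profiles
  keys <- vapply(profs, function(p) paste(p$genotype, p$condition), "")
  out <- vector("list", length(profs))
  for (key in unique(keys)) {
    idx <- which(keys == key)
    p1 <- profs[[idx[1]]]
    geno <- geno_factors[[p1$genotype]] %||% genotype_factors(p1$genotype)
    sims <- simulate_conditions(params, geno, light_regime(p1$condition),
                                save_every = save_every)
    for (i in idx) {
      p <- profs[[i]]
      sim_l <- if (p$day <= 4) sims$day4
      else if (p$treatment == "FR") sims$day6_fr
      else sims$day6_white
      out[[i]] <- data.frame(
        genotype = p$genotype, condition = p$condition,
        treatment = p$treatment, day = p$day, split = p$split,
        score = j_score(p, sim_l, variant = variant, dt = params$dt)
      )
    }
  }
  do.call(rbind, out)
}
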