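# Synthetic study generator.  The real per-cell length measurements behind
# the model are not deposited anywhere, so the package ships a generator
# that emulates their statistical structure: arch-shaped profiles with an
# interior maximum, genotype ordering wt > abcb1 abcb19 > sav3, weaker
# growth at high fluence rates, and a far-red boost over white light.

#' Specification for the synthetic study
#'
#' Defaults encode the study conditions the generator emulates: an
#' arch-shaped day-4 baseline, day-6 growth scaled by genotype
#' (wt 1.0 > abcb1 abcb19 0.6 > sav3 0.35), by condition (low fluence grows
#' more than high; continuous light more than long days), and a 1.5-fold
#' far-red boost over white light.  Replicate noise is Gaussian per cell.
#'
#' @param base_length baseline cell length at the hypocotyl ends (um).
#' @param arch_amplitude day-6 growth amplitude at the arch centre (um).
#' @param arch_center centre of the arch (row index; 9.5 puts the maximum
#'   between cells 9 and 10 of 18).
#' @param arch_width Gaussian width of the arch (rows).
#' @param day4_amplitude amplitude of the shallow day-4 arch (um).
#' @param genotype_scalers named growth multipliers per genotype.
#' @param condition_scalers named growth multipliers per light condition.
#' @param fr_boost multiplier of FR over white-light day-6 growth (>= 1).
#' @param noise_sd replicate noise standard deviation (um).
#' @param n_replicates replicates per profile.
#' @param seed RNG seed making the generated study reproducible.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(base_length = 20,
                           arch_amplitude = 250,
                           arch_center = 9.5,
                           arch_width = 5,
                           day4_amplitude = 60,
                           genotype_scalers = c(wt = 1, abcb1_abcb19 = 0.6,
                                                sav3 = 0.35),
                           condition_scalers = c(CL75 = 1, LD75 = 0.85,
                                                 CL130 = 0.7, LD130 = 0.55),
                           fr_boost = 1.5,
                           noise_sd = 8,
                           n_replicates = 8,
                           seed = 1L) {
  stopifnot(base_length > 0, arch_amplitude >= 0, arch_width > 0,
            day4_amplitude >= 0, fr_boost >= 1, noise_sd >= 0,
            n_replicates >= 1)
  if (any(genotype_scalers <= 0) || any(condition_scalers <= 0)) {
    stop("scalers must be positive", call. = FALSE)
  }
  if (genotype_scalers["wt"] < max(genotype_scalers)) {
    stop("the wild-type scaler must be the largest", call. = FALSE)
  }
  structure(
    list(base_length = base_length, arch_amplitude = arch_amplitude,
         arch_center = arch_center, arch_width = arch_width,
         day4_amplitude = day4_amplitude,
         genotype_scalers = genotype_scalers,
         condition_scalers = condition_scalers, fr_boost = fr_boost,
         noise_sd = noise_sd, n_replicates = n_replicates,
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' Arch-shaped cell-length profile
#'
#' The smooth interior-maximum family
#' `length_k = base + amplitude * exp(-((k - center)/width)^2)`,
#' mimicking the characteristic arch-shaped distribution of epidermal cell
#' lengths along the hypocotyl (longest cells in the middle).
#'
#' @param n_cells number of cells (18 in the standard profiles).
#' @param base baseline length (um).
#' @param amplitude arch height (um).
#' @param center arch centre (row index).
#' @param width Gaussian width (rows).
#' @return Numeric vector of `n_cells` lengths.
#' @examples
#' arch_profile(18, 20, 250, 9.5, 5)
#' @export
arch_profile <- function(n_cells, base, amplitude, center = 9.5, width = 5) {
  if (n_cells < 1) stop("n_cells must be >= 1", call. = FALSE)
  if (base <= 0) stop("base must be > 0", call. = FALSE)
  if (amplitude < 0) stop("amplitude must be >= 0", call. = FALSE)
  if (width <= 0) stop("width must be > 0", call. = FALSE)
  k <- seq_len(n_cells)
  base + amplitude * exp(-((k - center) / width)^2)
}

#' Generate the synthetic study dataset
#'
#' Emits profiles for the three genotypes times four light conditions times
#' three observation sets (day-4 white baseline, day-6 white, day-6 FR).
#' Day-6 lengths are the day-4 baseline plus an arch-shaped growth increment
#' scaled by the genotype, condition and (for FR) `fr_boost` multipliers;
#' replicate noise yields means and 95 percent confidence intervals
#' (`1.96 * sd / sqrt(n)`).  Split tags follow the study's scheme: all wild
#' type plus mutants at CL75/LD130 are `fit`, mutants at CL130/LD75 are
#' `validation`.  Fully reproducible from `spec$seed`.
#'
#' @param spec a [synthetic_spec()].
#' @return A `study_dataset` of 36 profiles.
#' @export
generate_study <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  genos <- names(spec$genotype_scalers)
  conds <- names(spec$condition_scalers)
  bump <- arch_profile(18, spec$base_length, 1, spec$arch_center,
                       spec$arch_width) - spec$base_length
  day4 <- spec$base_length + spec$day4_amplitude * bump
  profiles <- list()
  for (g in genos) {
    for (cc in conds) {
      scale <- spec$genotype_scalers[[g]] * spec$condition_scalers[[cc]]
      truth <- list(
        list(treatment = "white", day = 4, mu = day4),
        list(treatment = "white", day = 6,
             mu = day4 + spec$arch_amplitude * scale * bump),
        list(treatment = "FR", day = 6,
             mu = day4 + spec$arch_amplitude * scale * spec$fr_boost * bump)
      )
      for (tr in truth) {
        reps <- matrix(
          rnorm(18 * spec$n_replicates, mean = tr$mu, sd = spec$noise_sd),
          nrow = 18
        )
        reps <- pmax(reps, 1)  # replicate lengths cannot be non-positive
        m <- rowMeans(reps)
        ci <- if (spec$n_replicates > 1) {
          1.96 * apply(reps, 1, sd) / sqrt(spec$n_replicates)
        } else {
          rep(0, 18)
        }
        profiles[[length(profiles) + 1L]] <- cell_length_profile(
          g, cc, tr$treatment, tr$day, m, ci, spec$n_replicates
        )
      }
    }
  }
  study_dataset(profiles)
}

#' Generate epidermal cell-file counts
#'
#' Draws cell counts per epidermal file from a discrete distribution on
#' 15 to 23 cells with the mode at 18 (a symmetric triangular weighting),
#' matching the observed count range that fixed the model grid at 18 rows.
#'
#' @param n_files number of cell files to draw.
#' @param seed RNG seed.
#' @return Integer vector of counts in `[15, 23]`.
#' @export
generate_cell_counts <- function(n_files, seed = 1L) {
  if (n_files < 1) stop("n_files must be >= 1", call. = FALSE)
  set.seed(seed)
  support <- 15:23
  w <- 5 - abs(support - 18)   # 1 2 3 4 5 4 3 2 1, mode at 18
  sample(support, n_files, replace = TRUE, prob = w / sum(w))
}

#' Model-generated pseudo-data
#'
#' Runs the model itself for each genotype and regime, extracts the day-4
#' and day-6 (white and FR) length profiles, adds Gaussian noise, and
#' packages the result as a `study_dataset`.  This is the ground-truth
#' harness for parameter-recovery tests: with `noise_sd = 0` the profiles
#' equal the simulation outputs exactly.
#'
#' @param params an `aux_params` (the ground truth).
#' @param genotypes list of `aux_genotype` objects.
#' @param regimes list of `aux_regime` objects.
#' @param noise_sd Gaussian noise (um).
#' @param seed RNG seed.
#' @param n_replicates replicates per profile when `noise_sd > 0`.
#' @return A `study_dataset`.
#' @export
model_pseudodata <- function(params,
                             genotypes = list(auxgrad::genotype("wt")),
                             regimes = list(light_regime("CL75")),
                             noise_sd = 0, seed = 1L, n_replicates = 4L) {
  stopifnot(inherits(params, "aux_params"))
  set.seed(seed)
  profiles <- list()
  for (g in genotypes) {
    for (rg in regimes) {
      sims <- simulate_conditions(params, g, rg)
      for (tr in list(list("white", 4, sims$day4),
                      list("white", 6, sims$day6_white),
                      list("FR", 6, sims$day6_fr))) {
        mu <- tr[[3]]
        if (noise_sd > 0) {
          reps <- matrix(rnorm(18 * n_replicates, mu, noise_sd), nrow = 18)
          reps <- pmax(reps, 1)
          m <- rowMeans(reps)
          ci <- 1.96 * apply(reps, 1, sd) / sqrt(n_replicates)
          nrep <- n_replicates
        } else {
          m <- mu
          ci <- rep(0, 18)
          nrep <- 1L
        }
        profiles[[length(profiles) + 1L]] <- cell_length_profile(
          g$name, rg$label, tr[[1]], tr[[2]], m, ci, nrep
        )
      }
    }
  }
  study_dataset(profiles)
}
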