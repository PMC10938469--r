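#' Cell-length profiles and study datasets
#'
#' A `cell_length_profile` holds the mean epidermal cell lengths of one
#' genotype under one light condition, treatment and day: 18 means (cell 1 =
#' top of the hypocotyl), 18 half-widths of the 95 percent confidence
#' intervals, and the replicate count.  A `study_dataset` is a list of
#' profiles, each tagged `fit` or `validation`.
#'
#' @param genotype genotype label.
#' @param condition condition label (`CL75`, `CL130`, `LD75`, `LD130`).
#' @param treatment `"white"` or `"FR"`.
#' @param day observation day (4 or 6).
#' @param mean_lengths 18 mean lengths (um).
#' @param ci95 18 CI half-widths (um).
#' @param n replicate count.
#' @param split `"fit"` or `"validation"`.
#' @return An object of class `cell_length_profile`.
#' @export
cell_length_profile <- function(genotype, condition, treatment, day,
                                mean_lengths, ci95 = rep(0, 18), n = 1,
                                split = NULL) {
  if (length(mean_lengths) != 18L) {
    stop("a profile needs exactly 18 mean lengths", call. = FALSE)
  }
  if (any(mean_lengths <= 0)) {
    stop("all mean lengths must be > 0", call. = FALSE)
  }
  if (length(ci95) != 18L || any(ci95 < 0)) {
    stop("ci95 needs 18 non-negative half-widths", call. = FALSE)
  }
  structure(
    list(genotype = genotype, condition = condition, treatment = treatment,
         day = day, mean_lengths = as.numeric(mean_lengths),
         ci95 = as.numeric(ci95), n = n,
         split = split %||% default_split(genotype, condition)),
    class = "cell_length_profile"
  )
}

# fit split: all wild type, plus mutants at CL75 and LD130;
# validation: mutants at CL130 and LD75
default_split <- function(genotype, condition) {
  if (genotype == "wt" || condition %in% c("CL75", "LD130")) "fit"
  else "validation"
}

#' @rdname cell_length_profile
#' @param profiles list of `cell_length_profile` objects.
#' @export
study_dataset <- function(profiles) {
  stopifnot(all(vapply(profiles, inherits, TRUE, "cell_length_profile")))
  structure(list(profiles = profiles), class = "study_dataset")
}

#' @export
print.study_dataset <- function(x, ...) {
  d <- as.data.frame(x)
  cat(sprintf(
    "<study_dataset> %d profiles (%d fit / %d validation)\n",
    length(x$profiles),
    sum(vapply(x$profiles, function(p) p$split == "fit", TRUE)),
    sum(vapply(x$profiles, function(p) p$split == "validation", TRUE))))
  cat("  genotypes:", paste(unique(d$genotype), collapse = ", "), "\n")
  cat("  conditions:", paste(unique(d$condition), collapse = ", "), "\n")
  invisible(x)
}

#' Select profiles from a dataset
#'
#' @param dataset a `study_dataset`.
#' @param split,genotype,condition optional filters.
#' @return A `study_dataset` with the matching profiles.
#' @export
filter_profiles <- function(dataset, split = NULL, genotype = NULL,
                            condition = NULL) {
  keep <- vapply(dataset$profiles, function(p) {
    (is.null(split) || p$split %in% split) &&
      (is.null(genotype) || p$genotype %in% genotype) &&
      (is.null(condition) || p$condition %in% condition)
  }, TRUE)
  study_dataset(dataset$profiles[keep])
}

#' @export
as.data.frame.study_dataset <- function(x, ...) {
  do.call(rbind, lapply(x$profiles, function(p) {
    data.frame(
      genotype = p$genotype, condition = p$condition,
      treatment = p$treatment, day = p$day, cell_index = 1:18,
      mean_length_um = p$mean_lengths, ci95_um = p$ci95, n = p$n,
      split = p$split
    )
  }))
}

#' Read and write study-dataset CSV files
#'
#' Long-format CSV with columns `genotype`, `condition`, `treatment`,
#' `day`, `cell_index` (1-18), `mean_length_um`, `ci95_um`, `n`, `split`.
#' Numbers are serialised with full precision so a write/read round trip is
#' value-identical.
#'
#' @param dataset a `study_dataset`.
#' @param path CSV file path.
#' @return `read_study_csv()` returns a `study_dataset`; `write_study_csv()`
#'   returns `path` invisibly.
#' @export
write_study_csv <- function(dataset, path) {
  write_csv_full(as.data.frame(dataset), path)
  invisible(path)
}

#' @rdname write_study_csv
#' @export
read_study_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("genotype", "condition", "treatment", "day", "cell_index",
            "mean_length_um", "ci95_um", "n", "split")
  if (!all(need %in% names(d))) {
    stop("study CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  key <- interaction(d$genotype, d$condition, d$treatment, d$day,
                     drop = TRUE)
  profiles <- lapply(split(d, key), function(g) {
    g <- g[order(g$cell_index), ]
    cell_length_profile(g$genotype[1], g$condition[1], g$treatment[1],
                        g$day[1], g$mean_length_um, g$ci95_um, g$n[1],
                        split = g$split[1])
  })
  study_dataset(unname(profiles))
}

# CSV writer with repr-faithful numbers (%.17g round-trips doubles exactly)
write_csv_full <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
}
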