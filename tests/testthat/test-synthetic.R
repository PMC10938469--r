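test_that("arch profiles have the right shape and domain checks", {
  a <- arch_profile(18, 20, 250, 9.5, 5)
  expect_length(a, 18)
  expect_equal(which.max(a), 9)          # symmetric about 9.5: cells 9/10 tie
  expect_equal(a[9], a[10])
  expect_equal(arch_profile(18, 20, 0), rep(20, 18))   # flat at amplitude 0
  expect_error(arch_profile(0, 20, 10), "n_cells")
  expect_error(arch_profile(18, -1, 10), "base")
  expect_error(arch_profile(18, 20, 10, width = 0), "width")
})

test_that("generated study reproduces the study's qualitative structure", {
  ds <- generate_study(synthetic_spec(seed = 3))
  expect_length(ds$profiles, 36)   # 3 genotypes x 4 conditions x 3 sets
  d <- as.data.frame(ds)
  expect_true(all(d$mean_length_um >= 10))

  totals <- with(subset(d, day == 6 & treatment == "FR"),
                 tapply(mean_length_um, list(genotype, condition), sum))
  for (cc in colnames(totals)) {
    expect_gt(totals["wt", cc], totals["abcb1_abcb19", cc])
    expect_gt(totals["abcb1_abcb19", cc], totals["sav3", cc])
  }
  # FR exceeds white for wt at day 6 in every condition: cell-wise on the
  # noise-free truth, and on total length under the default noise (at the
  # hypocotyl ends the FR and white means converge, so finite replicates
  # can cross there)
  truth <- as.data.frame(generate_study(synthetic_spec(noise_sd = 0)))
  for (cc in unique(d$condition)) {
    pick <- function(dd, tr) subset(dd, genotype == "wt" & condition == cc &
                                      day == 6 &
                                      treatment == tr)$mean_length_um
    expect_true(all(pick(truth, "FR") > pick(truth, "white")))
    expect_gt(sum(pick(d, "FR")), sum(pick(d, "white")))
  }
  # every day-6 profile peaks at an interior cell
  for (p in ds$profiles) {
    if (p$day == 6) {
      expect_true(which.max(p$mean_lengths) %in% 2:17)
    }
  }
  # split tags follow the fit/validation scheme
  expect_true(all(d$split[d$genotype == "wt"] == "fit"))
  expect_true(all(d$split[d$genotype != "wt" &
                            d$condition %in% c("CL75", "LD130")] == "fit"))
  expect_true(all(d$split[d$genotype != "wt" &
                            d$condition %in% c("CL130", "LD75")] ==
                    "validation"))
})

test_that("generator is seed-reproducible and CI scales as 1/sqrt(n)", {
  s1 <- generate_study(synthetic_spec(seed = 9))
  s2 <- generate_study(synthetic_spec(seed = 9))
  expect_identical(s1, s2)
  s3 <- generate_study(synthetic_spec(seed = 10))
  expect_false(identical(s1, s3))

  ci4 <- mean(as.data.frame(generate_study(
    synthetic_spec(n_replicates = 4, seed = 5)))$ci95_um)
  ci16 <- mean(as.data.frame(generate_study(
    synthetic_spec(n_replicates = 16, seed = 5)))$ci95_um)
  expect_equal(ci4 / ci16, 2, tolerance = 0.2)
})

test_that("cell counts stay in [15, 23] with mode 18", {
  n <- generate_cell_counts(1e4, seed = 2)
  expect_true(all(n >= 15 & n <= 23))
  expect_equal(as.integer(names(which.max(table(n)))), 18)
  expect_identical(generate_cell_counts(100, seed = 4),
                   generate_cell_counts(100, seed = 4))
})

test_that("model pseudodata equals simulation output at zero noise", {
  pq <- quick_params()
  ds <- model_pseudodata(pq, noise_sd = 0, seed = 1)
  expect_length(ds$profiles, 3)
  sims <- simulate_conditions(pq, genotype("wt"), light_regime("CL75"))
  fr6 <- Filter(function(p) p$treatment == "FR" && p$day == 6, ds$profiles)
  expect_equal(fr6[[1]]$mean_lengths, sims$day6_fr)
  expect_equal(fr6[[1]]$ci95, rep(0, 18))
  # with noise: nonzero CIs, seed-reproducible
  dn1 <- model_pseudodata(pq, noise_sd = 2, seed = 8)
  dn2 <- model_pseudodata(pq, noise_sd = 2, seed = 8)
  expect_identical(dn1, dn2)
  expect_true(all(dn1$profiles[[1]]$ci95 > 0))
})
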