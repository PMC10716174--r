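test_that("design validation names the offending field", {
  expect_error(sim_design(10, c(L = 0.5, M = 0.3, H = 0.3)),
               "channel_proportions")
  expect_error(sim_design(10, c(L = 0.7, M = 0.15, H = 0.15),
                          missing_rate = 1.5), "missing_rate")
  expect_error(sim_design(0, c(L = 0.7, M = 0.15, H = 0.15)), "n_proteins")
  expect_error(sim_design(10, c(L = 0.7, M = 0.15, H = 0.15),
                          time_points = c("2h", "4h"),
                          regulation = list(early = list(fraction = 0.1,
                                                         log2_effect = 1,
                                                         onset = "8h"))),
               "onset")
})

test_that("identical seeds give identical ground truth and report", {
  d <- benchmark_design(mix = "mix1", n_proteins = 40, seed = 42)
  t1 <- simulate_ground_truth(d)
  t2 <- simulate_ground_truth(d)
  expect_identical(t1, t2)
  expect_identical(simulate_precursor_report(t1), simulate_precursor_report(t2))
})

test_that("without regulation every true fold change is zero", {
  d <- sim_design(30, c(L = 0.2, M = 0.4, H = 0.4),
                  time_points = c("2h", "4h", "24h"), seed = 5)
  truth <- simulate_ground_truth(d)
  expect_true(all(truth$true_fc$true_log2fc == 0))
  expect_true(all(truth$proteins$class == "none"))
})

test_that("mix1 ground truth carries exact 70/15/15 channel proportions", {
  d <- benchmark_design(mix = "mix1", n_proteins = 25, seed = 7)
  truth <- simulate_ground_truth(d)
  wide <- tidyr::pivot_wider(truth$channel_abundance,
                             id_cols = c("protein_group", "run"),
                             names_from = "channel",
                             values_from = "true_abundance")
  expect_equal(wide$L / (wide$L + wide$M + wide$H), rep(0.70, nrow(wide)))
  expect_equal(wide$M / wide$H, rep(1, nrow(wide)))
  expect_equal(wide$M / wide$L, rep(15 / 70, nrow(wide)))
})

test_that("noiseless reports equal abundance times ionization exactly", {
  d <- benchmark_design(mix = "mix1", n_proteins = 15, seed = 9,
                        noise_sd_log2 = 0, missing_rate = 0, decoy_rate = 0)
  truth <- simulate_ground_truth(d)
  rep <- simulate_precursor_report(truth)
  joined <- rep |>
    dplyr::left_join(truth$channel_abundance,
                     by = c("protein_group", "run", "channel")) |>
    dplyr::left_join(truth$peptides,
                     by = c("protein_group", "stripped_sequence",
                            "modified_sequence", "charge"))
  expect_equal(joined$ms1_quantity,
               joined$true_abundance * 2^joined$ionization_log2)
  expect_identical(joined$ms1_quantity, joined$ms2_quantity)

  # per-precursor H/L intensity ratio is exactly 15/70 in mix1
  wide <- tidyr::pivot_wider(rep,
                             id_cols = c("modified_sequence", "charge", "run"),
                             names_from = "channel",
                             values_from = "ms2_quantity")
  expect_equal(wide$H / wide$L, rep(15 / 70, nrow(wide)))

  # summed channel intensities recover the design proportions exactly
  shares <- tapply(rep$ms2_quantity, rep$channel, sum)
  expect_equal(as.numeric(shares[c("L", "M", "H")] / sum(shares)),
               c(0.70, 0.15, 0.15))
})

test_that("missingness and decoy rates converge to their design values", {
  base <- list(n_proteins = 500, peptides_mean = 3, n_replicates = 3,
               seed = 13)
  d0 <- do.call(benchmark_design,
                c(base, list(mix = "mix1", missing_rate = 0, decoy_rate = 0.1)))
  dm <- do.call(benchmark_design,
                c(base, list(mix = "mix1", missing_rate = 0.2, decoy_rate = 0.1)))
  full <- simulate_precursor_report(simulate_ground_truth(d0))
  thin <- simulate_precursor_report(simulate_ground_truth(dm))
  n0 <- nrow(full)
  expect_gt(n0, 1e4)
  dropped <- n0 - nrow(thin)
  expect_gt(stats::binom.test(dropped, n0, 0.2)$p.value, 0.01)

  # decoys fail the 0.01 q-value thresholds; observed count within the
  # binomial 99% interval around decoy_rate
  fails <- sum(full$channel_q_value > 0.01)
  lo <- qbinom(0.005, n0, 0.1)
  hi <- qbinom(0.995, n0, 0.1)
  expect_gte(fails, lo)
  expect_lte(fails, hi)
  expect_true(all(full$q_value[full$channel_q_value > 0.01] > 0.01))
  expect_true(all(full$q_value < 0.01 | full$q_value > 0.01))
})

test_that("regulation is a step from the onset time point onward", {
  d <- timecourse_design(n_proteins = 120, effect = 1.5, seed = 21,
                         noise_sd_log2 = 0)
  truth <- simulate_ground_truth(d)
  tp <- d$time_points
  fc <- truth$true_fc |>
    dplyr::left_join(truth$proteins[, c("protein_group", "class")],
                     by = "protein_group")
  for (cls in c("early", "intermediate", "late")) {
    onset <- d$regulation[[cls]]$onset
    on_idx <- match(onset, tp)
    sub <- fc[fc$class == cls, ]
    expect_gt(nrow(sub), 0)
    expect_true(all(sub$true_log2fc[match(sub$time_point, tp) >= on_idx] == 1.5))
    expect_true(all(sub$true_log2fc[match(sub$time_point, tp) < on_idx] == 0))
  }
  # regulated channel abundance reflects the fold change exactly
  early <- fc$protein_group[fc$class == "early"][1]
  ab <- truth$channel_abundance[truth$channel_abundance$protein_group == early, ]
  wide <- tidyr::pivot_wider(ab, id_cols = c("run", "condition"),
                             names_from = "channel",
                             values_from = "true_abundance")
  expect_equal(log2(wide$H / wide$M) - log2(0.45 / 0.45),
               rep(1.5, nrow(wide)))
})

test_that("class fractions follow the design within sampling error", {
  d <- timecourse_design(n_proteins = 2000, fraction_per_class = 0.08,
                         seed = 31)
  truth <- simulate_ground_truth(d)
  tab <- table(truth$proteins$class)
  for (cls in c("early", "intermediate", "late")) {
    expect_gt(stats::binom.test(tab[[cls]], 2000, 0.08)$p.value, 0.001)
  }
})

test_that("sticky contamination inflates only the light channel", {
  d <- sim_design(200, c(L = 0.05, M = 0.475, H = 0.475),
                  contamination_rate = 0.3, noise_sd_log2 = 0,
                  missing_rate = 0, seed = 8)
  truth <- simulate_ground_truth(d)
  expect_gt(sum(truth$proteins$sticky_abundance > 0), 0)
  rep <- simulate_precursor_report(truth)
  joined <- rep |>
    dplyr::left_join(truth$channel_abundance,
                     by = c("protein_group", "run", "channel")) |>
    dplyr::left_join(truth$peptides,
                     by = c("protein_group", "stripped_sequence",
                            "modified_sequence", "charge")) |>
    dplyr::left_join(truth$proteins[, c("protein_group", "sticky_abundance")],
                     by = "protein_group")
  expected <- (joined$true_abundance +
                 ifelse(joined$channel == "L", joined$sticky_abundance, 0)) *
    2^joined$ionization_log2
  expect_equal(joined$ms2_quantity, expected)
})

test_that("written simulations round-trip through the reader", {
  d <- benchmark_design(mix = "mix2", n_proteins = 12, seed = 14)
  truth <- simulate_ground_truth(d)
  dir <- withr::local_tempdir()
  paths <- write_simulation(truth, dir, dialect = "diann_channels")
  back <- suppressMessages(read_precursor_report(paths[["report"]],
                                                 dialect = "diann_channels"))
  fwd <- simulate_precursor_report(truth)
  expect_equal(back, fwd, ignore_attr = TRUE)
  expect_true(file.exists(paths[["truth"]]))
  expect_true(file.exists(paths[["design"]]))
})
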