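test_that("single-precursor matrices keep ratios and total intensity", {
  m <- matrix(c(100, 200), nrow = 1, dimnames = list("p1", c("a", "b")))
  out <- maxlfq(m)
  expect_equal(unname(out["b"] / out["a"]), 2)
  expect_equal(sum(out), 300)
})

test_that("consistent fold changes are recovered exactly", {
  m <- rbind(c(100, 200, 400),
             c(10, 20, 40))
  colnames(m) <- c("a", "b", "c")
  out <- maxlfq(m)
  expect_equal(unname(diff(log2(out))), c(1, 1))
  expect_same_lfq(out, oracle_maxlfq(m))
})

test_that("disconnected columns fall back to summed intensity", {
  m <- rbind(c(100, NA), c(50, NA), c(NA, 30))
  colnames(m) <- c("a", "b")
  out <- maxlfq(m)
  expect_equal(unname(out), c(150, 30))
  expect_error(maxlfq(m[0, , drop = FALSE]), "non-empty")
})

test_that("maxlfq matches the brute-force least-squares oracle", {
  set.seed(99)
  for (i in 1:80) {
    m <- random_peptide_matrix()
    expect_same_lfq(maxlfq(m), oracle_maxlfq(m))
  }
  # and with a stricter pair requirement
  set.seed(100)
  for (i in 1:20) {
    m <- random_peptide_matrix(missing = 0.5)
    expect_same_lfq(maxlfq(m, min_shared = 2), oracle_maxlfq(m, min_shared = 2))
  }
})

test_that("scaling one column scales only its abundance (connected case)", {
  # ratio-consistent (rank-one) matrix: the anchoring to summed intensity
  # then makes column scaling an exact equivariance
  set.seed(4)
  m <- outer(2^rnorm(4, 12, 1), c(1, 0.5, 2))
  colnames(m) <- c("a", "b", "c")
  base <- maxlfq(m)
  m2 <- m
  m2[, 2] <- m2[, 2] * 8
  shifted <- maxlfq(m2)
  expect_equal(unname(shifted["b"] / base["b"]), 8, tolerance = 1e-9)
  expect_equal(unname(shifted[c("a", "c")]), unname(base[c("a", "c")]),
               tolerance = 1e-9)
})

test_that("peptide matrices aggregate duplicates by maximum", {
  tbl <- make_precursor_tbl(4, protein_group = rep("P1", 4))
  tbl$modified_sequence <- c("AK", "AK", "BK", "BK")
  tbl$stripped_sequence <- tbl$modified_sequence
  tbl$channel <- c("H", "H", "H", "M")
  tbl$ms2_quantity <- c(10, 20, 5, 7)
  m <- build_peptide_matrix(tbl, "P1", quant_source = "ms2")
  expect_identical(dim(m), c(2L, 2L))
  expect_equal(m["AK/2", "run1|H"], 20)
  expect_error(build_peptide_matrix(tbl, "NOPE"), "not found")
})

test_that("a fully observed protein yields one quant per sample and channel", {
  d <- benchmark_design(mix = c("mix1", "mix2"), n_proteins = 8, seed = 2,
                        n_replicates = 1, noise_sd_log2 = 0,
                        missing_rate = 0, decoy_rate = 0)
  tbl <- simulate_precursor_report(simulate_ground_truth(d))
  q <- quantify_channels(tbl, quant_source = "ms2")
  per <- dplyr::count(q, .data$protein_group)
  expect_true(all(per$n == 6))  # 2 runs x 3 channels

  # noiseless joint LFQ recovers the design proportions exactly
  mix1 <- q[grepl("mix1", q$run), ]
  shares <- tapply(mix1$lfq_intensity, mix1$channel, sum)
  expect_equal(as.numeric(shares[c("L", "M", "H")] / sum(shares)),
               c(0.70, 0.15, 0.15), tolerance = 1e-9)
})

test_that("single-channel proteins and quant sources are respected", {
  tbl <- make_precursor_tbl(2, protein_group = c("P1", "P1"))
  tbl$modified_sequence <- c("AK", "BK")
  tbl$channel <- "H"
  tbl$ms1_quantity <- c(100, 200)
  tbl$ms2_quantity <- c(400, 800)
  q1 <- quantify_channels(tbl, quant_source = "ms1")
  q2 <- quantify_channels(tbl, quant_source = "ms2")
  expect_identical(unique(q1$channel), "H")
  expect_equal(q2$lfq_intensity / q1$lfq_intensity, 4)
  expect_identical(q1$n_precursors, 2L)
})

test_that("ratios follow the LFQ values and skip half-missing pairs", {
  q <- tibble::tibble(protein_group = c("P1", "P1", "P2"),
                      gene = c("G1", "G1", "G2"),
                      run = "r1",
                      channel = c("H", "M", "H"),
                      lfq_intensity = c(2000, 1000, 500),
                      n_precursors = 1L)
  r <- compute_ratios(q, "H", "M")
  expect_identical(r$protein_group, "P1")
  expect_equal(r$log2_ratio, 1)
  expect_error(compute_ratios(q, "H", "H"), "different")

  # global rescaling leaves ratios untouched
  q2 <- dplyr::mutate(q, lfq_intensity = lfq_intensity * 1e3)
  expect_equal(compute_ratios(q2, "H", "M")$log2_ratio, r$log2_ratio)
})

test_that("noiseless equimolar benchmarks give zero median H/M ratio", {
  d <- benchmark_design(mix = "mix2", n_proteins = 12, seed = 6,
                        noise_sd_log2 = 0, missing_rate = 0, decoy_rate = 0)
  tbl <- simulate_precursor_report(simulate_ground_truth(d))
  r <- compute_ratios(quantify_channels(tbl), "H", "M")
  expect_equal(median(r$log2_ratio), 0, tolerance = 1e-9)
})

test_that("per-protein ratio spread shrinks with precursor count", {
  d <- benchmark_design(mix = "mix2", n_proteins = 400, seed = 16,
                        noise_sd_log2 = 0.25, missing_rate = 0,
                        decoy_rate = 0)
  tbl <- simulate_precursor_report(simulate_ground_truth(d))
  q <- quantify_channels(tbl)
  r <- compute_ratios(q, "H", "M")
  sds <- r |>
    dplyr::left_join(dplyr::distinct(q[, c("protein_group", "n_precursors")]),
                     by = "protein_group") |>
    dplyr::group_by(.data$protein_group, .data$n_precursors) |>
    dplyr::summarise(s = sd(.data$log2_ratio), .groups = "drop") |>
    dplyr::filter(!is.na(.data$s)) |>
    dplyr::mutate(bin = cut(.data$n_precursors, c(0, 2, 5, Inf))) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(s = median(.data$s), .groups = "drop")
  expect_true(all(diff(sds$s) < 0))
})

test_that("precursor label ratios report labeled-over-light distributions", {
  tbl <- make_precursor_tbl(3, protein_group = rep("P1", 3))
  tbl$modified_sequence <- "SHAREDPEPK"
  tbl$stripped_sequence <- "SHAREDPEPK"
  tbl$channel <- c("L", "M", "H")
  tbl$ms2_quantity <- c(100, 100, 200)
  r <- precursor_label_ratio(tbl)
  expect_equal(r$log2_ratio[r$labeled_channel == "M"], 0)
  expect_equal(r$log2_ratio[r$labeled_channel == "H"], 1)

  d <- benchmark_design(mix = "mix2", n_proteins = 10, seed = 3,
                        noise_sd_log2 = 0, missing_rate = 0, decoy_rate = 0)
  rep2 <- simulate_precursor_report(simulate_ground_truth(d))
  lr <- precursor_label_ratio(rep2)
  expect_equal(unique(round(lr$log2_ratio[lr$labeled_channel == "H"], 9)), 1)
  med <- attr(lr, "medians")
  expect_true(all(med$median_log2_ratio[med$labeled_channel == "H"] == 1))

  # a run without light intensities yields no rows for that run
  no_l <- tbl[tbl$channel != "L", ]
  expect_message(out <- precursor_label_ratio(no_l), "No light")
  expect_identical(nrow(out), 0L)
})
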