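#' Runs implied by a simulation design
#'
#' @param design A [sim_design()].
#' @return A tibble with one row per run: `run`, `condition` (mixture name
#'   or time-point label) and `replicate`.
#' @export
design_runs <- function(design) {
  validate_sim_design(design)
  conditions <- names(design$channel_proportions)
  tidyr::expand_grid(condition = conditions,
                     replicate = seq_len(design$n_replicates)) |>
    dplyr::mutate(run = paste0(.data$condition, "_r", .data$replicate),
                  .before = 1)
}

random_peptides <- function(n) {
  aa <- strsplit("ACDEFGHILNPQSTVWY", "")[[1]]  # no K/R/M internally
  gen <- function(m) {
    len <- sample(8:14, m, replace = TRUE)
    core <- vapply(len, function(l)
      paste(sample(aa, l, replace = TRUE), collapse = ""), character(1))
    paste0(core, sample(c("K", "R"), m, replace = TRUE))
  }
  seqs <- gen(n)
  while (anyDuplicated(seqs)) {
    dup <- duplicated(seqs)
    seqs[dup] <- gen(sum(dup))
  }
  seqs
}

#' Generate per-protein ground truth for a simulation design
#'
#' Draws, under the design's seed, a log2-normal baseline abundance per
#' protein, a truncated negative-binomial number of peptides per protein
#' with log2-normal ionization efficiencies, a regulation class per
#' protein (multinomial over the design's class fractions), and the true
#' abundance of every (protein, channel, run) cell: baseline times the
#' condition's channel proportion, times `2^log2_effect` in the regulated
#' channel from the class's onset time point onward. "Sticky" proteins
#' receive an unlabeled-background abundance drawn independently of their
#' own baseline.
#'
#' @param design A valid [sim_design()].
#' @return An object of class `nsp_truth`: a list with tibbles `proteins`
#'   (`protein_group`, `gene`, `baseline_log2`, `class`,
#'   `sticky_abundance`), `peptides` (`protein_group`,
#'   `stripped_sequence`, `modified_sequence`, `charge`,
#'   `ionization_log2`), `true_fc` (`protein_group`, `time_point`,
#'   `true_log2fc`; empty for benchmark designs), `channel_abundance`
#'   (`protein_group`, `run`, `condition`, `channel`, `true_abundance`),
#'   plus `runs` and the originating `design`.
#' @export
#' @examples
#' d <- benchmark_design(mix = "mix1", n_proteins = 20, seed = 3)
#' truth <- simulate_ground_truth(d)
#' head(truth$channel_abundance)
simulate_ground_truth <- function(design) {
  validate_sim_design(design)
  with_seed(design$seed, {
    n <- design$n_proteins
    proteins <- tibble::tibble(
      protein_group = sprintf("P%05d", seq_len(n)),
      gene = sprintf("GENE%05d", seq_len(n)),
      baseline_log2 = rnorm(n, design$baseline_log2_mean,
                            design$baseline_log2_sd))

    classes <- "none"
    probs <- 1
    if (!is.null(design$regulation)) {
      fr <- vapply(design$regulation, function(r) r$fraction, numeric(1))
      classes <- c(names(design$regulation), "none")
      probs <- c(fr, 1 - sum(fr))
    }
    proteins$class <- sample(classes, n, replace = TRUE, prob = probs)

    proteins$sticky_abundance <- 0
    if (design$contamination_rate > 0) {
      sticky <- runif(n) < design$contamination_rate
      proteins$sticky_abundance[sticky] <-
        2^rnorm(sum(sticky), design$baseline_log2_mean, design$baseline_log2_sd)
    }

    n_pep <- pmax(1L, rnbinom(n, mu = design$peptides_mean,
                              size = design$peptides_dispersion))
    peptides <- tibble::tibble(
      protein_group = rep(proteins$protein_group, n_pep),
      stripped_sequence = random_peptides(sum(n_pep)),
      charge = sample(2:3, sum(n_pep), replace = TRUE),
      ionization_log2 = rnorm(sum(n_pep), 0, design$ionization_log2_sd))
    peptides$modified_sequence <- peptides$stripped_sequence
    peptides <- peptides[, c("protein_group", "stripped_sequence",
                             "modified_sequence", "charge", "ionization_log2")]

    # true per-time-point log2 fold change: step from onset onward
    if (!is.null(design$time_points)) {
      tp <- design$time_points
      fc_of <- function(class) {
        if (class == "none") return(rep(0, length(tp)))
        r <- design$regulation[[class]]
        ifelse(match(tp, tp) >= match(r$onset, tp), r$log2_effect, 0)
      }
      true_fc <- tidyr::expand_grid(protein_group = proteins$protein_group,
                                    time_point = tp) |>
        dplyr::left_join(proteins[, c("protein_group", "class")],
                         by = "protein_group") |>
        dplyr::mutate(true_log2fc = purrr::map2_dbl(
          .data$class, .data$time_point,
          function(cl, t) fc_of(cl)[match(t, tp)])) |>
        dplyr::select(-"class")
    } else {
      true_fc <- tibble::tibble(protein_group = character(),
                                time_point = character(),
                                true_log2fc = numeric())
    }

    runs <- design_runs(design)
    prop <- dplyr::bind_rows(lapply(names(design$channel_proportions),
      function(cond) {
        p <- design$channel_proportions[[cond]]
        tibble::tibble(condition = cond, channel = c("L", "M", "H"),
                       proportion = unname(p[c("L", "M", "H")]))
      }))
    channel_abundance <-
      tidyr::expand_grid(protein_group = proteins$protein_group,
                         run = runs$run) |>
      dplyr::left_join(runs, by = "run") |>
      tidyr::expand_grid(channel = c("L", "M", "H")) |>
      dplyr::left_join(prop, by = c("condition", "channel")) |>
      dplyr::left_join(proteins[, c("protein_group", "baseline_log2", "class")],
                       by = "protein_group")
    if (nrow(true_fc) > 0) {
      channel_abundance <- channel_abundance |>
        dplyr::left_join(true_fc, by = c("protein_group",
                                         "condition" = "time_point")) |>
        dplyr::mutate(effect = ifelse(.data$channel == design$regulated_channel,
                                      .data$true_log2fc, 0))
    } else {
      channel_abundance$effect <- 0
    }
    channel_abundance <- channel_abundance |>
      dplyr::mutate(true_abundance =
                      2^(.data$baseline_log2 + .data$effect) * .data$proportion) |>
      dplyr::select("protein_group", "run", "condition", "channel",
                    "true_abundance")

    structure(list(proteins = proteins, peptides = peptides,
                   true_fc = true_fc, channel_abundance = channel_abundance,
                   runs = runs, design = design),
              class = "nsp_truth")
  })
}

#' Simulate a channel-resolved precursor report from ground truth
#'
#' Expands the ground truth to one row per (peptide, charge, channel, run),
#' attaching an MS1-style and an MS2-style quantity, each equal to the true
#' channel abundance times the peptide's ionization factor times
#' independent log2-normal noise of standard deviation `noise_sd_log2`.
#' Rows are dropped independently at `missing_rate`; a `decoy_rate`
#' fraction of the surviving rows receives q-values failing the 0.01
#' thresholds (all three of precursor, channel and translated q-value),
#' while all other rows receive q-values below 0.01. Sticky proteins gain
#' unlabeled (L-channel) intensity independent of their own abundance.
#'
#' @param truth An `nsp_truth` from [simulate_ground_truth()].
#' @param design The same design the truth was generated from (defaults to
#'   the design stored in `truth`); a mismatch is an error.
#' @return A precursor tibble in the package's `simple` dialect (see
#'   [read_precursor_report()]), deterministic given the design seed.
#' @export
#' @examples
#' d <- benchmark_design(mix = "mix1", n_proteins = 10, seed = 3)
#' report <- simulate_precursor_report(simulate_ground_truth(d))
#' dplyr::count(report, channel)
simulate_precursor_report <- function(truth, design = truth$design) {
  if (!inherits(truth, "nsp_truth")) {
    abort("`truth` must be produced by simulate_ground_truth().")
  }
  if (!identical(truth$design, validate_sim_design(design))) {
    abort("`design` does not match the design `truth` was generated from.")
  }
  report_seed <- (design$seed %% 2000000000L) + 1L
  with_seed(report_seed, {
    rows <- truth$channel_abundance |>
      dplyr::left_join(truth$proteins[, c("protein_group", "gene",
                                          "sticky_abundance")],
                       by = "protein_group") |>
      dplyr::mutate(base = .data$true_abundance +
                      ifelse(.data$channel == "L", .data$sticky_abundance, 0)) |>
      dplyr::filter(.data$base > 0) |>
      dplyr::inner_join(truth$peptides, by = "protein_group",
                        relationship = "many-to-many")
    # stable order before any random draw so the draw sequence is reproducible
    rows <- dplyr::arrange(rows, .data$protein_group, .data$modified_sequence,
                           .data$charge, .data$channel, .data$run)
    n <- nrow(rows)
    sdl <- design$noise_sd_log2
    ion <- 2^rows$ionization_log2
    rows$ms1_quantity <- rows$base * ion * 2^rnorm(n, 0, sdl)
    rows$ms2_quantity <- rows$base * ion * 2^rnorm(n, 0, sdl)

    keep <- runif(n) >= design$missing_rate
    decoy <- runif(n) < design$decoy_rate
    pass_q <- function(m) runif(m, 0, 0.0099)
    fail_q <- function(m) runif(m, 0.0101, 0.5)
    draw <- function() ifelse(decoy, fail_q(n), pass_q(n))
    rows$q_value <- draw()
    rows$channel_q_value <- draw()
    rows$translated_q_value <- draw()

    rows <- rows[keep, , drop = FALSE]
    tibble::as_tibble(rows) |>
      dplyr::mutate(is_contaminant = FALSE) |>
      dplyr::select("protein_group", "gene", "stripped_sequence",
                    "modified_sequence", "charge", "channel", "run",
                    "ms1_quantity", "ms2_quantity", "q_value",
                    "channel_q_value", "translated_q_value", "is_contaminant")
  })
}

#' Write a simulation (report, ground truth, design) to a directory
#'
#' @param truth An `nsp_truth`.
#' @param dir Output directory, created if needed.
#' @param dialect Report dialect passed to [write_precursor_report()].
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(truth, dir, dialect = c("simple", "diann_channels")) {
  dialect <- match.arg(dialect)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  report <- simulate_precursor_report(truth)
  paths <- c(report = file.path(dir, "precursor_report.tsv"),
             truth = file.path(dir, "ground_truth.tsv"),
             design = file.path(dir, "design.yaml"))
  write_precursor_report(report, paths[["report"]], dialect = dialect)
  truth_tbl <- truth$channel_abundance |>
    dplyr::left_join(truth$proteins[, c("protein_group", "class")],
                     by = "protein_group")
  if (nrow(truth$true_fc) > 0) {
    truth_tbl <- dplyr::left_join(truth_tbl, truth$true_fc,
                                  by = c("protein_group",
                                         "condition" = "time_point"))
  }
  readr::write_tsv(truth_tbl, paths[["truth"]])
  design <- truth$design
  design$channel_proportions <- lapply(design$channel_proportions, as.list)
  yaml::write_yaml(unclass(design), paths[["design"]])
  invisible(paths)
}
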