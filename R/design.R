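#' Describe a triple-SILAC simulation design
#'
#' A `sim_design` captures everything the synthetic-data generator needs:
#' how many proteins and peptides to draw, the mixing proportions of the
#' light (L), intermediate (M) and heavy (H) SILAC channels in each
#' condition, the replicate structure, optional time-course regulation
#' classes, and the noise, missingness, contamination and decoy rates.
#'
#' Two kinds of experiment are expressible. A *benchmark* design lists one
#' set of channel proportions per mixture condition (e.g. the 70/15/15 and
#' 20/40/40 L/M/H benchmark mixes); every condition is measured in
#' `n_replicates` runs and no protein is regulated. A *time-course* design
#' supplies `time_points` plus a `regulation` list; every time point is
#' measured in `n_replicates` runs, the base channel proportions apply to
#' every run, and regulated proteins have their `regulated_channel`
#' abundance multiplied by `2^log2_effect` from the class's onset time
#' point onward (a step profile).
#'
#' @param n_proteins Number of simulated protein groups.
#' @param channel_proportions Named list of conditions, each a named numeric
#'   vector over channels `L`, `M`, `H` summing to 1; or a single such
#'   vector (recycled to one condition named `"cond"` or, for time-course
#'   designs, to every time point).
#' @param n_replicates Replicate runs per condition or time point.
#' @param time_points Ordered character vector of time-point labels
#'   (e.g. `c("2h","4h","6h","9h","24h")`), or `NULL` for benchmark designs.
#' @param regulation Named list of regulation classes. Each element is a
#'   list with `fraction` (of proteins in the class), `log2_effect`
#'   (signed log2 fold change) and `onset` (a time-point label). Proteins
#'   not assigned to any class are unregulated. `NULL` means no regulation.
#' @param regulated_channel Channel carrying the regulation signal
#'   (default `"H"`, the usual treatment channel).
#' @param peptides_mean,peptides_dispersion Mean and dispersion (negative
#'   binomial `size`) of the peptides-per-protein distribution, truncated
#'   at 1 so every protein has at least one peptide.
#' @param baseline_log2_mean,baseline_log2_sd Log2-normal parameters of the
#'   per-protein baseline intensity.
#' @param ionization_log2_sd Spread of the per-peptide multiplicative
#'   ionization efficiency (log2-normal, median 1).
#' @param noise_sd_log2 Standard deviation, in log2 units, of the
#'   multiplicative intensity noise applied independently to every
#'   quantity.
#' @param missing_rate Probability that a generated precursor row is
#'   dropped.
#' @param contamination_rate Fraction of proteins receiving "sticky"
#'   unlabeled (L-channel) background intensity drawn independently of the
#'   protein's own abundance.
#' @param decoy_rate Fraction of precursor rows assigned failing q-values
#'   (> 0.01); all other rows receive q-values below 0.01.
#' @param seed Integer seed; identical designs with identical seeds give
#'   byte-identical simulations.
#'
#' @return An object of class `sim_design`.
#' @seealso [benchmark_design()], [timecourse_design()],
#'   [simulate_ground_truth()], [simulate_precursor_report()]
#' @export
#' @examples
#' d <- sim_design(n_proteins = 50,
#'                 channel_proportions = list(mix1 = c(L = .7, M = .15, H = .15)),
#'                 seed = 1)
#' d
sim_design <- function(n_proteins,
                       channel_proportions,
                       n_replicates = 3,
                       time_points = NULL,
                       regulation = NULL,
                       regulated_channel = "H",
                       peptides_mean = 5,
                       peptides_dispersion = 2,
                       baseline_log2_mean = 20,
                       baseline_log2_sd = 2,
                       ionization_log2_sd = 1,
                       noise_sd_log2 = 0.25,
                       missing_rate = 0,
                       contamination_rate = 0,
                       decoy_rate = 0,
                       seed = 1L) {
  if (is.numeric(channel_proportions)) {
    channel_proportions <- list(cond = channel_proportions)
  }
  if (!is.null(time_points)) {
    time_points <- as.character(time_points)
    if (length(channel_proportions) == 1L) {
      channel_proportions <-
        setNames(rep(channel_proportions, length(time_points)), time_points)
    }
    if (!identical(sort(names(channel_proportions)), sort(time_points))) {
      abort("For a time-course design, `channel_proportions` must be one vector (applied to all time points) or one per time point.")
    }
    channel_proportions <- channel_proportions[time_points]
  }
  design <- structure(
    list(n_proteins = as.integer(n_proteins),
         channel_proportions = channel_proportions,
         n_replicates = as.integer(n_replicates),
         time_points = time_points,
         regulation = regulation,
         regulated_channel = regulated_channel,
         peptides_mean = peptides_mean,
         peptides_dispersion = peptides_dispersion,
         baseline_log2_mean = baseline_log2_mean,
         baseline_log2_sd = baseline_log2_sd,
         ionization_log2_sd = ionization_log2_sd,
         noise_sd_log2 = noise_sd_log2,
         missing_rate = missing_rate,
         contamination_rate = contamination_rate,
         decoy_rate = decoy_rate,
         seed = as.integer(seed)),
    class = "sim_design")
  validate_sim_design(design)
}

validate_sim_design <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  bad <- function(field, msg) {
    abort(paste0("Invalid simulation design: field `", field, "` ", msg))
  }
  if (is.na(design$n_proteins) || design$n_proteins < 1) {
    bad("n_proteins", "must be a positive count.")
  }
  for (cond in names(design$channel_proportions)) {
    p <- design$channel_proportions[[cond]]
    if (!all(c("L", "M", "H") %in% names(p))) {
      bad("channel_proportions", paste0("(", cond, ") must name channels L, M, H."))
    }
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      bad("channel_proportions",
          paste0("(", cond, ") must be nonnegative and sum to 1 (got ",
                 format(sum(p)), ")."))
    }
  }
  if (design$n_replicates < 1) bad("n_replicates", "must be at least 1.")
  for (field in c("missing_rate", "contamination_rate", "decoy_rate")) {
    v <- design[[field]]
    if (!is_scalar_number(v) || v < 0 || v > 1) bad(field, "must lie in [0, 1].")
  }
  if (!is_scalar_number(design$noise_sd_log2) || design$noise_sd_log2 < 0) {
    bad("noise_sd_log2", "must be a nonnegative number.")
  }
  if (design$peptides_mean < 1) bad("peptides_mean", "must be at least 1.")
  if (!is.null(design$regulation)) {
    if (is.null(design$time_points)) {
      bad("regulation", "requires `time_points`.")
    }
    total <- 0
    for (cls in names(design$regulation)) {
      r <- design$regulation[[cls]]
      if (!is.list(r) || is.null(r$fraction) || is.null(r$log2_effect) ||
          is.null(r$onset)) {
        bad("regulation", paste0("class `", cls,
            "` must supply fraction, log2_effect and onset."))
      }
      if (!r$onset %in% design$time_points) {
        bad("regulation", paste0("class `", cls, "` onset `", r$onset,
            "` is not a configured time point."))
      }
      if (r$fraction < 0 || r$fraction > 1) {
        bad("regulation", paste0("class `", cls, "` fraction must lie in [0, 1]."))
      }
      total <- total + r$fraction
    }
    if (total > 1 + 1e-9) bad("regulation", "class fractions must sum to at most 1.")
    if (!design$regulated_channel %in% c("L", "M", "H")) {
      bad("regulated_channel", "must be one of L, M, H.")
    }
  }
  design
}

#' @export
print.sim_design <- function(x, ...) {
  kind <- if (is.null(x$time_points)) "benchmark" else "time-course"
  cat("<sim_design> (", kind, ")\n", sep = "")
  cat("  proteins: ", x$n_proteins,
      "; peptides/protein ~ NB(mean ", x$peptides_mean,
      ", size ", x$peptides_dispersion, ") >= 1\n", sep = "")
  for (cond in names(x$channel_proportions)) {
    p <- x$channel_proportions[[cond]]
    cat("  ", cond, ": L/M/H = ", paste(format(p[c("L", "M", "H")]),
        collapse = "/"), " x ", x$n_replicates, " replicates\n", sep = "")
  }
  if (!is.null(x$regulation)) {
    for (cls in names(x$regulation)) {
      r <- x$regulation[[cls]]
      cat("  class ", cls, ": fraction ", r$fraction, ", log2 effect ",
          r$log2_effect, ", onset ", r$onset, "\n", sep = "")
    }
  }
  cat("  noise sd(log2) ", x$noise_sd_log2, "; missing ", x$missing_rate,
      "; contamination ", x$contamination_rate, "; decoys ", x$decoy_rate,
      "; seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Benchmark mixture designs with defined channel proportions
#'
#' Convenience constructor for the two triple-SILAC benchmark mixtures used
#' to validate pulsed-SILAC quantification: `mix1` mimics a non-enriched
#' pulse-labeled sample (70% light, 15% intermediate, 15% heavy) and
#' `mix2` an enriched newly-synthesized-proteome sample (20% light, 40%
#' intermediate, 40% heavy). The intermediate and heavy channels are
#' equimolar in both mixes, so the expected protein-level log2 H/M ratio
#' is 0 throughout.
#'
#' @param mix `"mix1"`, `"mix2"`, or both.
#' @param n_proteins,n_replicates,noise_sd_log2,missing_rate,decoy_rate,seed
#'   Study conditions; defaults are the package's standard benchmark
#'   settings (5000 proteins, 3 runs, log2 noise sd 0.25, 5% missingness,
#'   2% decoy rows).
#' @param ... Further arguments passed to [sim_design()].
#' @return A `sim_design`.
#' @export
#' @examples
#' benchmark_design(mix = "mix1", n_proteins = 100, seed = 7)
benchmark_design <- function(mix = c("mix1", "mix2"),
                             n_proteins = 5000,
                             n_replicates = 3,
                             noise_sd_log2 = 0.25,
                             missing_rate = 0.05,
                             decoy_rate = 0.02,
                             seed = 1L,
                             ...) {
  mixes <- list(mix1 = c(L = 0.70, M = 0.15, H = 0.15),
                mix2 = c(L = 0.20, M = 0.40, H = 0.40))
  mix <- match.arg(mix, several.ok = TRUE)
  sim_design(n_proteins = n_proteins,
             channel_proportions = mixes[mix],
             n_replicates = n_replicates,
             noise_sd_log2 = noise_sd_log2,
             missing_rate = missing_rate,
             decoy_rate = decoy_rate,
             seed = seed,
             ...)
}

#' Time-course design with planted early/intermediate/late regulation
#'
#' Convenience constructor for a pulsed-SILAC time-course experiment in
#' which the heavy channel carries the treated condition and the
#' intermediate channel the control; regulated proteins step up (or down)
#' in the heavy channel from their class's onset time point. Default
#' classes follow the standard five-point design: early onset at 2 h,
#' intermediate at 4 h, late at 24 h.
#'
#' @param n_proteins Number of protein groups.
#' @param time_points Ordered time-point labels.
#' @param effect Absolute log2 effect size of regulated classes.
#' @param fraction_per_class Fraction of proteins in each regulated class.
#' @param noise_sd_log2,n_replicates,missing_rate,seed Study conditions.
#' @param channel_proportions Base L/M/H proportions of every run
#'   (default an enriched-like 10/45/45 mix).
#' @param ... Passed to [sim_design()].
#' @return A `sim_design`.
#' @export
timecourse_design <- function(n_proteins = 300,
                              time_points = c("2h", "4h", "6h", "9h", "24h"),
                              effect = 1.5,
                              fraction_per_class = 0.08,
                              noise_sd_log2 = 0.15,
                              n_replicates = 3,
                              missing_rate = 0,
                              seed = 1L,
                              channel_proportions = c(L = 0.10, M = 0.45, H = 0.45),
                              ...) {
  regulation <- list(
    early        = list(fraction = fraction_per_class, log2_effect = effect,
                        onset = time_points[1]),
    intermediate = list(fraction = fraction_per_class, log2_effect = effect,
                        onset = time_points[2]),
    late         = list(fraction = fraction_per_class, log2_effect = effect,
                        onset = time_points[length(time_points)]))
  sim_design(n_proteins = n_proteins,
             channel_proportions = channel_proportions,
             n_replicates = n_replicates,
             time_points = time_points,
             regulation = regulation,
             noise_sd_log2 = noise_sd_log2,
             missing_rate = missing_rate,
             seed = seed,
             ...)
}
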