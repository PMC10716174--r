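#' Coefficient of variation in percent
#'
#' `100 * sd(x) / mean(x)` on linear-scale values, the standard precision
#' metric for replicate SILAC ratios.
#'
#' @param values Numeric vector of linear-scale replicate values.
#' @param min_n Minimum number of present values (default 2).
#' @return CV in percent, or `NA` when fewer than `min_n` values are
#'   present or the mean is zero (with a warning).
#' @export
#' @examples
#' cv_percent(c(1, 2, 3))  # 50
cv_percent <- function(values, min_n = 2) {
  x <- values[!is.na(values)]
  if (length(x) < min_n) return(NA_real_)
  m <- mean(x)
  if (m == 0) {
    warn("cv_percent: mean of values is 0; CV undefined.")
    return(NA_real_)
  }
  100 * sd(x) / m
}

#' Deviation of observed log2 ratios from a theoretical ratio
#'
#' Per protein, the median-over-samples log2 ratio minus the theoretical
#' log2 ratio of the mixing design; the summary median over proteins is
#' attached as the `median_deviation` attribute (the accuracy number
#' conventionally printed under benchmark boxplots).
#'
#' @param ratios A ratio tibble from [compute_ratios()].
#' @param theoretical_log2 The design's true log2 ratio (e.g.
#'   `log2(15/70)` for the heavy/light pair of a 70/15/15 mix).
#' @return Tibble `protein_group`, `deviation`, with attribute
#'   `median_deviation`.
#' @export
accuracy_deviation <- function(ratios, theoretical_log2) {
  out <- ratios |>
    dplyr::filter(!is.na(.data$log2_ratio)) |>
    dplyr::group_by(.data$protein_group) |>
    dplyr::summarise(deviation = median(.data$log2_ratio) - theoretical_log2,
                     .groups = "drop")
  attr(out, "median_deviation") <- median(out$deviation)
  out
}

#' Number of quantified protein groups
#'
#' @param ratios A ratio tibble from [compute_ratios()].
#' @param scope `"overall"` (protein groups with at least one ratio
#'   anywhere) or `"per_sample"` (one count per run).
#' @return For `"overall"` a single integer; for `"per_sample"` a tibble
#'   `run`, `n_quantified`.
#' @export
count_quantified <- function(ratios, scope = c("overall", "per_sample")) {
  scope <- match.arg(scope)
  present <- ratios[!is.na(ratios$log2_ratio), , drop = FALSE]
  if (scope == "overall") {
    return(dplyr::n_distinct(present$protein_group))
  }
  present |>
    dplyr::group_by(run = .data$run) |>
    dplyr::summarise(n_quantified = dplyr::n_distinct(.data$protein_group),
                     .groups = "drop")
}

#' Missing-value rate (%) of a ratio matrix
#'
#' Percentage of absent (protein, run) ratio cells over the grid of all
#' runs by all proteins quantified in at least one run.
#'
#' @param ratios A ratio tibble from [compute_ratios()].
#' @param scope `"overall"` or `"per_sample"`.
#' @return Percentage (overall) or a tibble `run`, `missing_rate`.
#' @export
missing_rate <- function(ratios, scope = c("overall", "per_sample")) {
  scope <- match.arg(scope)
  present <- ratios[!is.na(ratios$log2_ratio), , drop = FALSE]
  proteins <- unique(present$protein_group)
  runs <- unique(ratios$run)
  if (length(proteins) == 0 || length(runs) == 0) {
    return(if (scope == "overall") NA_real_ else
      tibble::tibble(run = character(), missing_rate = numeric()))
  }
  if (scope == "overall") {
    total <- length(proteins) * length(runs)
    return(100 * (total - nrow(dplyr::distinct(present, .data$protein_group,
                                               .data$run))) / total)
  }
  tibble::tibble(run = runs) |>
    dplyr::left_join(
      dplyr::summarise(dplyr::group_by(present, .data$run),
                       n = dplyr::n_distinct(.data$protein_group),
                       .groups = "drop"),
      by = "run") |>
    dplyr::mutate(missing_rate =
                    100 * (length(proteins) - dplyr::coalesce(.data$n, 0L)) /
                    length(proteins)) |>
    dplyr::select("run", "missing_rate")
}

#' Principal component analysis of log2 SILAC ratio profiles
#'
#' Proteins with any absent ratio across the analyzed runs are dropped
#' (complete-case); the samples-by-proteins matrix is column-centered and
#' decomposed by singular values (via [stats::prcomp()]).
#'
#' @param ratios A ratio tibble from [compute_ratios()].
#' @return An object of class `nsp_pca`: list with `scores` (tibble `run`,
#'   `PC1`, `PC2`, ...), `explained_variance` (fractions summing to 1) and
#'   `n_proteins` used.
#' @export
pca_ratios <- function(ratios) {
  wide <- ratios |>
    dplyr::filter(!is.na(.data$log2_ratio)) |>
    dplyr::distinct(.data$protein_group, .data$run, .keep_all = TRUE) |>
    tidyr::pivot_wider(id_cols = "protein_group", names_from = "run",
                       values_from = "log2_ratio")
  mat <- as.matrix(wide[, -1, drop = FALSE])
  rownames(mat) <- wide$protein_group
  if (ncol(mat) < 2) abort("PCA needs at least 2 samples.")
  mat <- mat[stats::complete.cases(mat), , drop = FALSE]
  if (nrow(mat) < 2) {
    abort("PCA needs at least 2 proteins with complete ratio profiles.")
  }
  fit <- prcomp(t(mat), center = TRUE, scale. = FALSE)
  ev <- fit$sdev^2
  scores <- tibble::as_tibble(fit$x, rownames = "run")
  structure(list(scores = scores,
                 explained_variance = ev / sum(ev),
                 n_proteins = nrow(mat)),
            class = "nsp_pca")
}

#' @export
print.nsp_pca <- function(x, ...) {
  cat("<nsp_pca> ", nrow(x$scores), " samples, ", x$n_proteins,
      " complete-case proteins\n", sep = "")
  ev <- x$explained_variance
  cat("  explained variance: ",
      paste0("PC", seq_along(ev), " ", sprintf("%.1f%%", 100 * ev),
             collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @method tidy nsp_pca
#' @export
tidy.nsp_pca <- function(x, ...) x$scores

#' @method glance nsp_pca
#' @export
glance.nsp_pca <- function(x, ...) {
  tibble::tibble(n_samples = nrow(x$scores), n_proteins = x$n_proteins,
                 pc1_var = x$explained_variance[1],
                 pc2_var = if (length(x$explained_variance) > 1)
                   x$explained_variance[2] else NA_real_)
}

#' Fold enrichment between two label-ratio distributions
#'
#' Ratio of medians (linear scale) of an enriched over a non-enriched
#' distribution of labeled/unlabeled intensity ratios — the headline
#' metric for how strongly covalent capture enriches newly synthesized
#' protein signal.
#'
#' @param enriched,non_enriched Numeric vectors of linear-scale
#'   labeled/unlabeled ratios.
#' @return `median(enriched) / median(non_enriched)`, or `NA` with a
#'   warning when the non-enriched median is zero.
#' @export
#' @examples
#' enrichment_fold(rep(6.5, 5), rep(0.25, 5))  # 26
enrichment_fold <- function(enriched, non_enriched) {
  if (length(enriched) == 0 || length(non_enriched) == 0) {
    abort("Both distributions must be non-empty.")
  }
  m0 <- median(non_enriched, na.rm = TRUE)
  if (m0 == 0) {
    warn("Non-enriched median is 0; enrichment fold undefined.")
    return(NA_real_)
  }
  median(enriched, na.rm = TRUE) / m0
}

#' Benchmark quality summary for one condition
#'
#' Bundles the quality metrics used to compare acquisition and
#' quantification methods: quantified-protein counts, median replicate CV,
#' median accuracy deviation from the theoretical mixing ratio, and the
#' missing-value rate.
#'
#' @param ratios A ratio tibble from [compute_ratios()].
#' @param runs Optional `run`/`condition` mapping for CVs.
#' @param theoretical_log2 Theoretical log2 ratio of the design (default 0,
#'   the equimolar heavy/intermediate case).
#' @return A one-row tibble of summary metrics plus list-columns with the
#'   per-protein CV and deviation tables.
#' @export
benchmark_summary <- function(ratios, runs = NULL, theoretical_log2 = 0) {
  cvs <- ratio_cv(ratios, runs)
  dev <- accuracy_deviation(ratios, theoretical_log2)
  tibble::tibble(
    n_quantified = count_quantified(ratios),
    median_cv = median(cvs$cv, na.rm = TRUE),
    median_deviation = attr(dev, "median_deviation"),
    missing_rate = missing_rate(ratios),
    cv_table = list(cvs),
    deviation_table = list(dev))
}
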