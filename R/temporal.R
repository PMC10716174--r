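#' Combine per-time-point DE results into one long table
#'
#' @param de_list Named list of `nsp_defit` objects (or tidied tibbles),
#'   names being time-point labels.
#' @return Long tibble with a `time_point` column prepended to each
#'   result's `protein_group`, `gene`, `log2_fc`, `p_adj`, ... columns.
#' @export
bind_de_results <- function(de_list) {
  if (is.null(names(de_list)) || any(!nzchar(names(de_list)))) {
    abort("`de_list` must be named by time point.")
  }
  purrr::imap(de_list, function(fit, tp) {
    tbl <- if (inherits(fit, "nsp_defit")) tidy.nsp_defit(fit) else
      tibble::as_tibble(fit)
    dplyr::mutate(tbl, time_point = tp, .before = 1)
  }) |>
    dplyr::bind_rows()
}

#' Replicate CV of a protein's SILAC ratios across the time course
#'
#' Three readings of "CV < 20% across all time points" are available.
#' `"mean"` (the default) computes the replicate CV within each time point
#' and averages over time points — a precision filter that does not
#' penalize genuine temporal regulation and is robust to the sampling
#' noise of a CV estimated from few replicates. `"max"` takes the worst
#' per-time-point CV instead (stricter, but with 3 replicates a noisy
#' estimate often exceeds the threshold by chance). `"pooled"` computes
#' one CV over all time points' replicate ratios pooled, which conflates
#' temporal change with noise (a step-regulated protein necessarily shows
#' a large pooled CV) and is provided for comparison.
#'
#' @param ratios A ratio tibble covering all time-course runs.
#' @param runs Tibble mapping `run` to `condition` (time-point label).
#' @param mode `"mean"`, `"max"` or `"pooled"`.
#' @param min_n Minimum replicate values per CV (default 2).
#' @return Tibble `protein_group`, `cv_time` (percent; `NA` when no
#'   condition has enough replicates).
#' @export
cv_across_time <- function(ratios, runs, mode = c("mean", "max", "pooled"),
                           min_n = 2) {
  mode <- match.arg(mode)
  if (mode == "pooled") {
    per <- ratio_cv(ratios, runs = NULL, min_n = min_n)
    return(dplyr::select(per, "protein_group", cv_time = "cv"))
  }
  agg <- if (mode == "max") max else mean
  ratio_cv(ratios, runs = runs, min_n = min_n) |>
    dplyr::group_by(.data$protein_group) |>
    dplyr::summarise(cv_time = if (all(is.na(.data$cv))) NA_real_ else
      agg(.data$cv, na.rm = TRUE), .groups = "drop")
}

check_time_points <- function(de_long, time_points) {
  found <- unique(de_long$time_point)
  missing <- setdiff(time_points, found)
  if (length(missing) > 0) {
    abort(paste0("DE results missing for time point(s): ",
                 paste(missing, collapse = ", "), "; expected ",
                 paste(time_points, collapse = ", "), ", found ",
                 paste(found, collapse = ", "), "."))
  }
}

#' Select robustly regulated proteins across a time course
#'
#' A protein is selected when it shows a strong significant change at any
#' time point (|log2 fold change| > `fc_threshold` and adjusted p <
#' `alpha`) and its ratios are precise across the whole time course
#' (CV < `cv_threshold`%, see [cv_across_time()]). Proteins with an
#' undefined CV are not selected.
#'
#' @param de_long Long DE table from [bind_de_results()] (columns
#'   `protein_group`, `time_point`, `log2_fc`, `p_adj`).
#' @param cv Tibble `protein_group`, `cv_time` from [cv_across_time()].
#' @param time_points Ordered time-point labels expected in `de_long`
#'   (a missing time point is an error).
#' @param fc_threshold Absolute log2 fold-change threshold (default 1).
#' @param alpha Adjusted-p threshold (default 0.05).
#' @param cv_threshold CV threshold in percent (default 20).
#' @return Tibble `protein_group`, `max_abs_fc`, `cv_time`, `selected`.
#' @export
select_candidates <- function(de_long, cv, time_points,
                              fc_threshold = 1, alpha = 0.05,
                              cv_threshold = 20) {
  check_time_points(de_long, time_points)
  hits <- de_long |>
    dplyr::filter(.data$time_point %in% time_points) |>
    dplyr::group_by(.data$protein_group) |>
    dplyr::summarise(
      max_abs_fc = max(abs(.data$log2_fc), na.rm = TRUE),
      any_strong = any(!is.na(.data$p_adj) & .data$p_adj < alpha &
                         abs(.data$log2_fc) > fc_threshold),
      .groups = "drop")
  hits |>
    dplyr::left_join(cv, by = "protein_group") |>
    dplyr::mutate(selected = .data$any_strong & !is.na(.data$cv_time) &
                    .data$cv_time < cv_threshold) |>
    dplyr::select("protein_group", "max_abs_fc", "cv_time", "selected")
}

default_class_map <- function(time_points) {
  n <- length(time_points)
  if (n < 3) abort("Need at least 3 time points for early/intermediate/late classes.")
  list(early = time_points[1],
       intermediate = time_points[2:(n - 1)],
       late = time_points[n])
}

#' Assign early/intermediate/late response classes
#'
#' For each selected protein, finds the earliest time point (in the
#' configured order, not file order) at which the change is significant at
#' the classification thresholds (|log2 fold change| > `fc_threshold`,
#' adjusted p < `alpha`; defaults 0.585 and 0.05) and maps it through
#' `class_map` (default: first time point = early, last = late, all in
#' between = intermediate). Untested time points count as non-significant.
#' A selected protein with no significant time point at these thresholds
#' gets class `"none"` with a warning (impossible when the selection
#' threshold is at least as strict as the classification threshold).
#'
#' @param de_long Long DE table from [bind_de_results()].
#' @param selection Output of [select_candidates()].
#' @param time_points Ordered time-point labels.
#' @param class_map Named list class -> time-point labels.
#' @param fc_threshold,alpha Classification thresholds.
#' @return Tibble `protein_group`, `selected`, `earliest_sig_timepoint`,
#'   `response_class`.
#' @export
classify_response <- function(de_long, selection, time_points,
                              class_map = default_class_map(time_points),
                              fc_threshold = 0.585, alpha = 0.05) {
  check_time_points(de_long, time_points)
  tp_class <- unlist(lapply(names(class_map), function(cls)
    setNames(rep(cls, length(class_map[[cls]])), class_map[[cls]])))
  unknown <- setdiff(time_points, names(tp_class))
  if (length(unknown) > 0) {
    abort(paste0("`class_map` does not cover time point(s): ",
                 paste(unknown, collapse = ", ")))
  }
  earliest <- de_long |>
    dplyr::filter(!is.na(.data$p_adj), .data$p_adj < alpha,
                  abs(.data$log2_fc) > fc_threshold,
                  .data$time_point %in% time_points) |>
    dplyr::mutate(tp_order = match(.data$time_point, time_points)) |>
    dplyr::group_by(.data$protein_group) |>
    dplyr::summarise(earliest_sig_timepoint =
                       time_points[min(.data$tp_order)], .groups = "drop")
  out <- selection |>
    dplyr::select("protein_group", "selected") |>
    dplyr::left_join(earliest, by = "protein_group") |>
    dplyr::mutate(
      earliest_sig_timepoint = ifelse(.data$selected,
                                      .data$earliest_sig_timepoint, NA),
      response_class = dplyr::case_when(
        !.data$selected ~ "none",
        is.na(.data$earliest_sig_timepoint) ~ "none",
        TRUE ~ unname(tp_class[.data$earliest_sig_timepoint])))
  orphan <- out$selected & out$response_class == "none"
  if (any(orphan)) {
    warn(paste0(sum(orphan), " selected protein(s) pass no time point at ",
                "the classification thresholds; class set to \"none\"."))
  }
  out
}

#' Heatmap-ready time-course report
#'
#' One row per selected, classified protein: log2 fold changes per time
#' point with per-cell significance flags (classification thresholds),
#' sorted by class (earliest first) then earliest significant time point.
#'
#' @inheritParams classify_response
#' @param classes Output of [classify_response()].
#' @return Tibble `protein_group`, `gene`, `response_class`,
#'   `earliest_sig_timepoint`, then `fc_<tp>` and `sig_<tp>` columns.
#' @export
timecourse_report <- function(de_long, classes, time_points,
                              fc_threshold = 0.585, alpha = 0.05) {
  check_time_points(de_long, time_points)
  keep <- classes[classes$response_class != "none", , drop = FALSE]
  cells <- de_long |>
    dplyr::filter(.data$protein_group %in% keep$protein_group) |>
    dplyr::mutate(sig = !is.na(.data$p_adj) & .data$p_adj < alpha &
                    abs(.data$log2_fc) > fc_threshold)
  genes <- dplyr::distinct(cells, .data$protein_group, .data$gene)
  fc_wide <- tidyr::pivot_wider(cells, id_cols = "protein_group",
                                names_from = "time_point",
                                values_from = "log2_fc",
                                names_prefix = "fc_")
  sig_wide <- tidyr::pivot_wider(cells, id_cols = "protein_group",
                                 names_from = "time_point",
                                 values_from = "sig",
                                 names_prefix = "sig_")
  class_order <- unique(c("early", "intermediate", "late",
                          sort(unique(keep$response_class))))
  keep |>
    dplyr::left_join(genes, by = "protein_group") |>
    dplyr::left_join(fc_wide, by = "protein_group") |>
    dplyr::left_join(sig_wide, by = "protein_group") |>
    dplyr::mutate(.cls = match(.data$response_class, class_order),
                  .tp = match(.data$earliest_sig_timepoint, time_points)) |>
    dplyr::arrange(.data$.cls, .data$.tp, .data$protein_group) |>
    dplyr::select("protein_group", "gene", "response_class",
                  "earliest_sig_timepoint",
                  dplyr::all_of(paste0("fc_", time_points)),
                  dplyr::all_of(paste0("sig_", time_points)))
}

#' Full time-course classification in one call
#'
#' Runs [cv_across_time()], [select_candidates()] and
#' [classify_response()] and returns the joined per-protein table.
#'
#' @inheritParams select_candidates
#' @inheritParams classify_response
#' @param ratios Ratio tibble covering all time-course runs (for the CV).
#' @param runs `run`/`condition` mapping; conditions are time points.
#' @param cv_mode Passed to [cv_across_time()].
#' @param select_fc Selection fold-change threshold (default 1).
#' @param class_fc Classification fold-change threshold (default 0.585).
#' @param cv_threshold CV threshold in percent (default 20).
#' @return Tibble `protein_group`, `max_abs_fc`, `cv_time`, `selected`,
#'   `earliest_sig_timepoint`, `response_class`.
#' @export
classify_timecourse <- function(de_long, ratios, runs, time_points,
                                class_map = default_class_map(time_points),
                                select_fc = 1, class_fc = 0.585,
                                alpha = 0.05, cv_threshold = 20,
                                cv_mode = c("mean", "max", "pooled")) {
  cv <- cv_across_time(ratios, runs, mode = cv_mode)
  selection <- select_candidates(de_long, cv, time_points,
                                 fc_threshold = select_fc, alpha = alpha,
                                 cv_threshold = cv_threshold)
  classes <- classify_response(de_long, selection, time_points,
                               class_map = class_map,
                               fc_threshold = class_fc, alpha = alpha)
  dplyr::left_join(selection,
                   dplyr::select(classes, "protein_group",
                                 "earliest_sig_timepoint", "response_class"),
                   by = "protein_group")
}
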