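#' Read a pipeline configuration file
#'
#' YAML-style key/value configuration describing one end-to-end analysis:
#' either a `simulate` block (a design for the synthetic-data generator)
#' or an `input` block (`report` path + `dialect`), a `samples` list
#' mapping runs to conditions, the SILAC `channels` used as ratio
#' numerator and denominator, `filters`, `de` and `classify` thresholds,
#' an optional `gene_sets` GMT path, `output` directory and `seed`.
#'
#' @param path Path to a YAML config file.
#' @return A `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(paste0("Config file not found: ", path))
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "pipeline_config")
}

validate_pipeline_config <- function(config) {
  if (is.null(config$simulate) && is.null(config$input)) {
    abort("Config must provide either a `simulate` block or an `input` block.")
  }
  ch <- config$channels %||% list(numerator = "H", denominator = "M")
  if (is.null(ch$numerator) || is.null(ch$denominator) ||
      identical(ch$numerator, ch$denominator)) {
    abort("Config `channels` must name distinct numerator and denominator channels.")
  }
  if (!is.null(config$input)) {
    if (is.null(config$input$report)) {
      abort("Config `input` block must name a `report` path.")
    }
    if (!file.exists(config$input$report)) {
      abort(paste0("Input report not found: ", config$input$report))
    }
    if (is.null(config$samples)) {
      abort("Config must map every run to a condition via `samples` when reading an input report.")
    }
  }
  invisible(config)
}

config_design <- function(sim, seed) {
  kind <- sim$kind %||% "benchmark"
  args <- sim[setdiff(names(sim), "kind")]
  args$seed <- args$seed %||% seed
  if (kind == "benchmark") {
    do.call(benchmark_design, args)
  } else if (kind == "timecourse") {
    do.call(timecourse_design, args)
  } else {
    abort("`simulate.kind` must be \"benchmark\" or \"timecourse\".")
  }
}

config_filters <- function(f) {
  ids <- character()
  if (!is.null(f$contaminants)) ids <- read_contaminant_ids(f$contaminants)
  filter_config(max_q = f$max_q %||% 0.01,
                max_channel_q = f$max_channel_q %||% 0.01,
                max_translated_q = f$max_translated_q %||% 0.01,
                contaminant_ids = ids,
                contaminant_prefix = f$contaminant_prefix)
}

#' Run the full analysis pipeline from a configuration
#'
#' Executes read/simulate, contaminant and q-value filtering, per-channel
#' MaxLFQ quantification, SILAC ratio formation, benchmark metrics,
#' per-condition moderated differential expression, time-course
#' classification (when the conditions are time points) and
#' over-representation analysis (when gene sets are configured). Every
#' stage writes a TSV into the output directory, and a machine-readable
#' `manifest.json` records the package version, config hash, seed and
#' per-stage row counts. All randomness flows from the config seed, so
#' rerunning an identical config reproduces identical outputs.
#'
#' @param config A `pipeline_config` (see [read_pipeline_config()]) or an
#'   equivalently structured list.
#' @param output_dir Output directory (default `config$output`).
#' @return Invisibly, a list of the in-memory stage results.
#' @export
run_pipeline <- function(config, output_dir = config$output) {
  validate_pipeline_config(config)
  if (is.null(output_dir)) abort("No output directory configured.")
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  quant_source <- tolower(config$quant_source %||% "ms2")
  counts <- list()
  manifest_path <- file.path(output_dir, "manifest.json")

  # --- input stage: simulate or read -----------------------------------
  if (!is.null(config$simulate)) {
    design <- config_design(config$simulate, seed)
    truth <- simulate_ground_truth(design)
    table <- simulate_precursor_report(truth)
    runs <- truth$runs
    write_simulation(truth, file.path(output_dir, "simulation"))
    time_points <- design$time_points
  } else {
    table <- read_precursor_report(config$input$report,
                                   quant_source = quant_source,
                                   dialect = config$input$dialect %||% "diann_channels")
    truth <- NULL
    runs <- dplyr::bind_rows(lapply(config$samples, tibble::as_tibble))
    if (!all(c("run", "condition") %in% names(runs))) {
      abort("Each `samples` entry must name `run` and `condition`.")
    }
    missing_runs <- setdiff(unique(table$run), runs$run)
    if (length(missing_runs) > 0) {
      abort(paste0("Run(s) without a configured condition: ",
                   paste(missing_runs, collapse = ", ")))
    }
    time_points <- config$classify$time_points
  }
  counts$input <- nrow(table)

  # --- filtering --------------------------------------------------------
  fcfg <- config_filters(config$filters %||% list())
  table <- remove_contaminants(table, fcfg)
  counts$after_contaminant_removal <- nrow(table)
  table <- apply_qvalue_filters(table, fcfg)
  counts$after_qvalue_filters <- nrow(table)
  write_precursor_report(table, file.path(output_dir, "precursors_filtered.tsv"))

  # --- quantification and ratios ---------------------------------------
  quants <- quantify_channels(table, quant_source = quant_source,
                              mode = config$lfq_mode %||% "joint")
  readr::write_tsv(quants, file.path(output_dir, "protein_lfq.tsv"))
  counts$protein_channel_quants <- nrow(quants)

  ch <- config$channels %||% list(numerator = "H", denominator = "M")
  ratios <- compute_ratios(quants, ch$numerator, ch$denominator)
  readr::write_tsv(ratios, file.path(output_dir, "protein_ratios.tsv"))
  counts$protein_ratios <- nrow(ratios)

  # --- benchmark metrics ------------------------------------------------
  summary <- benchmark_summary(ratios, runs,
                               theoretical_log2 = config$theoretical_log2 %||% 0)
  readr::write_tsv(summary[, !vapply(summary, is.list, logical(1))],
                   file.path(output_dir, "benchmark_summary.tsv"))
  pca <- tryCatch(pca_ratios(ratios), error = function(e) NULL)
  if (!is.null(pca)) {
    readr::write_tsv(pca$scores, file.path(output_dir, "pca_scores.tsv"))
  }

  # --- differential expression per condition ---------------------------
  pc <- dplyr::distinct(quants[, c("protein_group", "n_precursors")])
  conditions <- unique(runs$condition)
  de_cfg <- config$de %||% list()
  de_fits <- list()
  for (cond in conditions) {
    cond_runs <- runs$run[runs$condition == cond]
    fit <- tryCatch(
      moderated_de(ratios, pc, runs = cond_runs,
                   span = de_cfg$span %||% 0.75,
                   fc_threshold = de_cfg$fc_threshold %||% 0.585,
                   alpha = de_cfg$alpha %||% 0.05),
      error = function(e) {
        warn(paste0("DE skipped for condition ", cond, ": ",
                    conditionMessage(e)))
        NULL
      })
    if (is.null(fit)) next
    de_fits[[cond]] <- fit
    readr::write_tsv(tidy.nsp_defit(fit),
                     file.path(output_dir, paste0("de_", cond, ".tsv")))
  }
  counts$de_conditions <- length(de_fits)

  # --- time-course classification --------------------------------------
  classes <- NULL
  if (!is.null(time_points) && length(de_fits) > 0 &&
      all(time_points %in% names(de_fits))) {
    cls_cfg <- config$classify %||% list()
    de_long <- bind_de_results(de_fits[time_points])
    classes <- classify_timecourse(
      de_long, ratios, runs, time_points,
      select_fc = cls_cfg$select_fc %||% 1,
      class_fc = cls_cfg$class_fc %||% 0.585,
      alpha = cls_cfg$alpha %||% 0.05,
      cv_threshold = cls_cfg$cv_threshold %||% 20,
      cv_mode = cls_cfg$cv_mode %||% "max")
    readr::write_tsv(classes, file.path(output_dir, "timecourse_classes.tsv"))
    report <- timecourse_report(de_long,
                                classes[classes$selected, , drop = FALSE],
                                time_points,
                                fc_threshold = cls_cfg$class_fc %||% 0.585,
                                alpha = cls_cfg$alpha %||% 0.05)
    readr::write_tsv(report, file.path(output_dir, "timecourse_report.tsv"))
    counts$classified <- sum(classes$response_class != "none")
  }

  # --- over-representation analysis ------------------------------------
  ora <- NULL
  if (!is.null(config$gene_sets) && length(de_fits) > 0) {
    sets <- read_gene_sets(config$gene_sets)
    ora <- purrr::imap(de_fits, function(fit, cond) {
      r <- fit$results
      query <- r$gene[r$significant_up]
      bg <- r$gene[!is.na(r$p)]
      if (length(query) == 0) return(NULL)
      dplyr::mutate(run_ora(query, sets, bg,
                            q_threshold = config$ora_q %||% 0.05),
                    condition = cond, .before = 1)
    }) |>
      purrr::compact() |>
      dplyr::bind_rows()
    if (!is.null(ora) && nrow(ora) > 0) {
      readr::write_tsv(dplyr::select(ora, -"hits"),
                       file.path(output_dir, "ora.tsv"))
    }
  }

  manifest <- list(
    package = "nspquant",
    version = as.character(utils::packageVersion("nspquant")),
    config_hash = rlang::hash(config[sort(setdiff(names(config), "output"))]),
    seed = seed,
    quant_source = quant_source,
    row_counts = counts)
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)

  invisible(list(table = table, quants = quants, ratios = ratios,
                 summary = summary, pca = pca, de = de_fits,
                 classes = classes, ora = ora, truth = truth,
                 manifest = manifest))
}
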