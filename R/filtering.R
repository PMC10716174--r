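#' Filtering configuration for precursor tables
#'
#' Default thresholds follow standard plexDIA practice: precursor FDR,
#' channel q-value and translated q-value all `< 0.01` (strict: a q-value
#' exactly at the threshold is removed).
#'
#' @param max_q,max_channel_q,max_translated_q Upper (exclusive) q-value
#'   thresholds, each in (0, 1].
#' @param contaminant_ids Character vector of contaminant accessions.
#' @param contaminant_prefix Optional accession prefix (e.g. `"CON_"`)
#'   marking contaminants.
#' @return A `filter_config` list.
#' @export
filter_config <- function(max_q = 0.01, max_channel_q = 0.01,
                          max_translated_q = 0.01,
                          contaminant_ids = character(),
                          contaminant_prefix = NULL) {
  for (t in c(max_q, max_channel_q, max_translated_q)) {
    if (!is_scalar_number(t) || t <= 0 || t > 1) {
      abort("q-value thresholds must lie in (0, 1].")
    }
  }
  structure(list(max_q = max_q, max_channel_q = max_channel_q,
                 max_translated_q = max_translated_q,
                 contaminant_ids = as.character(contaminant_ids),
                 contaminant_prefix = contaminant_prefix),
            class = "filter_config")
}

group_is_contaminant <- function(protein_group, ids, prefix) {
  vapply(strsplit(protein_group, ";", fixed = TRUE), function(members) {
    members <- trimws(members)
    any(members %in% ids) ||
      (!is.null(prefix) && any(startsWith(members, prefix)))
  }, logical(1))
}

#' Remove contaminant protein groups
#'
#' A (possibly multi-accession, `;`-separated) protein group is removed if
#' *any* member accession is listed in `contaminant_ids`, matches
#' `contaminant_prefix`, or the record's `is_contaminant` flag is set.
#'
#' @param table A precursor tibble.
#' @param config A [filter_config()].
#' @return The filtered tibble; the number of removed records is reported
#'   via a message and recorded in the `n_contaminants_removed` attribute.
#' @export
remove_contaminants <- function(table, config = filter_config()) {
  check_precursor_table(table)
  flagged <- if ("is_contaminant" %in% names(table))
    table$is_contaminant %in% TRUE else FALSE
  hit <- flagged | group_is_contaminant(table$protein_group,
                                        config$contaminant_ids,
                                        config$contaminant_prefix)
  inform(paste0("remove_contaminants: removed ", sum(hit), " of ",
                nrow(table), " records."))
  out <- table[!hit, , drop = FALSE]
  attr(out, "quant_source") <- attr(table, "quant_source")
  attr(out, "n_contaminants_removed") <- sum(hit)
  out
}

#' Apply precursor, channel and translated q-value filters
#'
#' Retains exactly the records with `q_value < max_q` AND
#' `channel_q_value < max_channel_q` AND
#' `translated_q_value < max_translated_q`. Absent (NA) q-values pass, so
#' inputs lacking channel-level confidence scores are usable; per-filter
#' removal counts are reported.
#'
#' @inheritParams remove_contaminants
#' @return The filtered tibble with a `filter_counts` attribute recording
#'   per-filter removals.
#' @export
apply_qvalue_filters <- function(table, config = filter_config()) {
  check_precursor_table(table)
  pass <- function(q, thr) is.na(q) | q < thr
  p1 <- pass(table$q_value, config$max_q)
  p2 <- pass(table$channel_q_value, config$max_channel_q)
  p3 <- pass(table$translated_q_value, config$max_translated_q)
  counts <- c(q_value = sum(!p1), channel_q_value = sum(!p2),
              translated_q_value = sum(!p3))
  keep <- p1 & p2 & p3
  inform(paste0("apply_qvalue_filters: removed ", sum(!keep), " of ",
                nrow(table), " records (q: ", counts[1], ", channel q: ",
                counts[2], ", translated q: ", counts[3], ")."))
  out <- table[keep, , drop = FALSE]
  attr(out, "quant_source") <- attr(table, "quant_source")
  attr(out, "filter_counts") <- counts
  out
}

#' Contaminant removal and q-value filtering in one call
#'
#' @inheritParams remove_contaminants
#' @return The filtered precursor tibble.
#' @export
filter_precursors <- function(table, config = filter_config()) {
  table |>
    remove_contaminants(config) |>
    apply_qvalue_filters(config)
}
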