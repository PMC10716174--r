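# column mapping between the DIA-NN channel-resolved dialect and the
# package-internal snake_case (simple) dialect
diann_column_map <- c(
  protein_group      = "Protein.Group",
  gene               = "Genes",
  stripped_sequence  = "Stripped.Sequence",
  modified_sequence  = "Modified.Sequence",
  charge             = "Precursor.Charge",
  channel            = "Channel",
  run                = "Run",
  ms1_quantity       = "Ms1.Translated",
  ms2_quantity       = "Precursor.Translated",
  q_value            = "Q.Value",
  channel_q_value    = "Channel.Q.Value",
  translated_q_value = "Translated.Q.Value")

#' Read a channel-resolved precursor report
#'
#' Reads a tab-separated precursor matrix in either the DIA-NN
#' channel-resolved dialect (`"diann_channels"`; columns `Protein.Group`,
#' `Genes`, `Stripped.Sequence`, `Modified.Sequence`, `Precursor.Charge`,
#' `Channel`, `Run`, `Ms1.Translated`, `Precursor.Translated`, `Q.Value`,
#' `Channel.Q.Value`, `Translated.Q.Value`) or the equivalent snake_case
#' `"simple"` dialect. Channel labels are normalized to `L`/`M`/`H`
#' through `channel_map`. Rows in which both quantities are absent are
#' dropped with a message. In the simple dialect, absent q-value columns
#' are tolerated with a prominent warning and treated as passing all
#' q-value filters.
#'
#' @param path Path to a TSV file.
#' @param quant_source Which quantity downstream quantification should use:
#'   `"ms2"` (precursor/MS2-level translated quantity, the default) or
#'   `"ms1"`. Recorded as the `quant_source` attribute.
#' @param dialect `"diann_channels"` or `"simple"`.
#' @param channel_map Named character vector mapping raw channel labels to
#'   `L`, `M`, `H` (default identity on `L`/`M`/`H`).
#' @return A tibble of precursor records (simple-dialect columns plus
#'   `is_contaminant`), with attributes `quant_source` and `source_file`.
#' @export
read_precursor_report <- function(path,
                                  quant_source = c("ms2", "ms1"),
                                  dialect = c("diann_channels", "simple"),
                                  channel_map = c(L = "L", M = "M", H = "H")) {
  quant_source <- match.arg(tolower(quant_source), c("ms2", "ms1"))
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)

  map <- if (dialect == "diann_channels") diann_column_map else
    setNames(names(diann_column_map), names(diann_column_map))
  optional <- if (dialect == "simple")
    c("q_value", "channel_q_value", "translated_q_value", "gene") else "gene"
  missing <- map[!map %in% names(raw)]
  hard_missing <- missing[!names(missing) %in% optional]
  if (length(hard_missing) > 0) {
    abort(paste0("Precursor report ", path, " lacks required column(s): ",
                 paste(hard_missing, collapse = ", ")))
  }
  if (any(names(missing) %in% c("q_value", "channel_q_value",
                                "translated_q_value"))) {
    warn(paste0("Report lacks q-value column(s) ",
                paste(missing[names(missing) != "gene"], collapse = ", "),
                "; these records will PASS all q-value filters."))
  }

  tbl <- tibble::tibble(.rows = nrow(raw))
  for (field in names(map)) {
    col <- map[[field]]
    tbl[[field]] <- if (col %in% names(raw)) raw[[col]] else NA_character_
  }
  numeric_fields <- c("charge", "ms1_quantity", "ms2_quantity", "q_value",
                      "channel_q_value", "translated_q_value")
  for (field in numeric_fields) {
    parsed <- suppressWarnings(as.numeric(tbl[[field]]))
    bad <- which(!is.na(tbl[[field]]) & is.na(parsed))
    if (length(bad) > 0) {
      abort(paste0("Unparseable numeric value in column `", map[[field]],
                   "` at data line(s) ",
                   paste(head(bad, 5), collapse = ", "), " of ", path))
    }
    tbl[[field]] <- parsed
  }
  tbl$charge <- as.integer(tbl$charge)

  unknown <- setdiff(unique(tbl$channel), names(channel_map))
  if (length(unknown) > 0) {
    abort(paste0("Unknown channel label(s) ", paste(unknown, collapse = ", "),
                 "; extend `channel_map` to map them onto L/M/H."))
  }
  tbl$channel <- unname(channel_map[tbl$channel])

  both_absent <- is.na(tbl$ms1_quantity) & is.na(tbl$ms2_quantity)
  if (any(both_absent)) {
    inform(paste0("Dropped ", sum(both_absent),
                  " record(s) with no MS1 and no MS2 quantity."))
    tbl <- tbl[!both_absent, , drop = FALSE]
  }
  tbl$is_contaminant <- if ("is_contaminant" %in% names(raw))
    as.logical(raw$is_contaminant)[!both_absent] else FALSE

  dup <- duplicated(tbl[, c("stripped_sequence", "modified_sequence",
                            "charge", "channel", "run")])
  if (any(dup)) {
    warn(paste0(sum(dup), " duplicate (precursor, channel, run) record(s); ",
                "kept all, downstream rollup aggregates by maximum."))
  }
  attr(tbl, "quant_source") <- quant_source
  attr(tbl, "source_file") <- path
  tbl
}

#' Write a precursor table as TSV
#'
#' @param table A precursor tibble in the simple dialect.
#' @param path Output path.
#' @param dialect Column dialect to write (see [read_precursor_report()]).
#' @return Invisibly, `path`.
#' @export
write_precursor_report <- function(table, path,
                                   dialect = c("simple", "diann_channels")) {
  dialect <- match.arg(dialect)
  check_precursor_table(table)
  out <- table
  if (dialect == "diann_channels") {
    out <- out[, names(diann_column_map)]
    names(out) <- unname(diann_column_map)
  }
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' GMT is tab-separated: set name, description, then member gene symbols.
#' Symbols are upper-cased for case-insensitive matching.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors of gene symbols.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(parts) < 3
  if (any(short)) {
    abort(paste0("Malformed GMT line(s) ", paste(which(short), collapse = ", "),
                 ": need at least name, description and one gene."))
  }
  sets <- lapply(parts, function(p) unique(toupper(p[-(1:2)])))
  names(sets) <- vapply(parts, `[[`, character(1), 1)
  if (anyDuplicated(names(sets))) {
    abort("Duplicate gene-set names in GMT file.")
  }
  sets
}

#' Read a contaminant accession list
#'
#' One accession per line; blank lines and `#` comments ignored.
#'
#' @param path Path to a text file.
#' @return Character vector of accessions.
#' @export
read_contaminant_ids <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  x <- trimws(readr::read_lines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}
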