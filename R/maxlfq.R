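#' MaxLFQ protein quantification from a peptide matrix
#'
#' Implements the MaxLFQ estimator on one protein's precursor-by-column
#' intensity matrix. For every pair of columns sharing at least
#' `min_shared` precursors, the pairwise log2 ratio is estimated as the
#' median over shared precursors of their log2 intensity differences
#' (ties with an even count use the mean of the central values). Column
#' log2 abundances then solve the least-squares system
#' \eqn{\min \sum_{(a,b)} (x_b - x_a - r_{ab})^2}. The solution is defined
#' up to an additive constant per connected component (columns are
#' connected when a qualifying pair links them); each component is
#' anchored so that the sum of its linear-scale abundances equals the
#' component's total observed precursor intensity. Columns in singleton
#' components are quantified by their summed intensity. Zero intensities
#' are treated as absent.
#'
#' @param matrix Numeric matrix, rows = precursor species, columns =
#'   (sample, channel) columns; `NA` marks absent observations.
#' @param min_shared Minimum number of shared precursors for a column pair
#'   to contribute a ratio equation (default 1).
#' @return Named numeric vector of linear-scale abundances, one per column
#'   of `matrix` (`NA` for columns with no observations).
#' @export
#' @examples
#' m <- rbind(c(100, 200, 400), c(50, 100, 200))
#' maxlfq(m)  # abundances in ratio 1:2:4
maxlfq <- function(matrix, min_shared = 1) {
  if (is.null(dim(matrix)) || length(matrix) == 0 || nrow(matrix) == 0 ||
      ncol(matrix) == 0) {
    abort("`matrix` must be a non-empty precursor-by-column matrix.")
  }
  m <- matrix
  m[!is.na(m) & m <= 0] <- NA
  nc <- ncol(m)
  observed <- colSums(!is.na(m)) > 0
  out <- rep(NA_real_, nc)
  names(out) <- colnames(m)
  if (!any(observed)) return(out)
  if (sum(observed) == 1) {
    out[observed] <- sum(m[, observed], na.rm = TRUE)
    return(out)
  }

  lm2 <- log2(m)
  present <- !is.na(lm2)
  shared <- crossprod(present)          # shared precursors per column pair
  adj <- shared >= min_shared
  diag(adj) <- FALSE
  adj[!observed, ] <- FALSE
  adj[, !observed] <- FALSE

  # connected components over qualifying pairs
  comp <- rep(NA_integer_, nc)
  cid <- 0L
  for (start in which(observed)) {
    if (!is.na(comp[start])) next
    cid <- cid + 1L
    queue <- start
    comp[start] <- cid
    while (length(queue) > 0) {
      v <- queue[[1]]
      queue <- queue[-1]
      nb <- which(adj[v, ] & is.na(comp))
      comp[nb] <- cid
      queue <- c(queue, nb)
    }
  }

  for (k in seq_len(cid)) {
    cols <- which(comp == k)
    total <- sum(m[, cols], na.rm = TRUE)
    if (length(cols) == 1) {
      out[cols] <- total
      next
    }
    nk <- length(cols)
    A <- matrix(0, nk, nk)
    rhs <- numeric(nk)
    for (i in seq_len(nk - 1)) {
      for (j in seq((i + 1), nk)) {
        a <- cols[i]; b <- cols[j]
        if (!adj[a, b]) next
        r <- median(lm2[, b] - lm2[, a], na.rm = TRUE)
        A[i, i] <- A[i, i] + 1
        A[j, j] <- A[j, j] + 1
        A[i, j] <- A[i, j] - 1
        A[j, i] <- A[j, i] - 1
        rhs[i] <- rhs[i] - r
        rhs[j] <- rhs[j] + r
      }
    }
    # sum-zero solution of the singular normal equations
    x <- solve(A + 1 / nk, rhs)
    x <- x - mean(x)
    shift <- log2(total) - log2(sum(2^x))
    out[cols] <- 2^(x + shift)
  }
  out
}

#' Build one protein's precursor-by-column intensity matrix
#'
#' Rows are precursor species (modified sequence x charge); columns are
#' (run, channel) pairs, named `run|channel`. Duplicate observations of
#' one (precursor, column) cell are aggregated by maximum; columns with no
#' observation are omitted.
#'
#' @param table A (filtered) precursor tibble.
#' @param protein_group Protein group identifier to extract.
#' @param quant_source `"ms2"` or `"ms1"` (defaults to the table's
#'   `quant_source` attribute).
#' @return Numeric matrix with dimnames (precursor, column).
#' @export
build_peptide_matrix <- function(table, protein_group,
                                 quant_source = attr(table, "quant_source") %||% "ms2") {
  check_precursor_table(table)
  rows <- table[table$protein_group == protein_group, , drop = FALSE]
  if (nrow(rows) == 0) {
    abort(paste0("Protein group not found in table: ", protein_group))
  }
  qcol <- quant_column(quant_source)
  val <- rows[[qcol]]
  prec <- paste(rows$modified_sequence, rows$charge, sep = "/")
  col <- paste(rows$run, rows$channel, sep = "|")
  keep <- !is.na(val) & val > 0
  if (!any(keep)) abort(paste0("No usable ", toupper(quant_source),
                               " intensities for ", protein_group))
  val <- val[keep]; prec <- prec[keep]; col <- col[keep]
  pr <- factor(prec); cl <- factor(col)
  m <- matrix(NA_real_, nlevels(pr), nlevels(cl),
              dimnames = list(levels(pr), levels(cl)))
  o <- order(val)                      # ascending: last assignment wins = max
  m[cbind(as.integer(pr)[o], as.integer(cl)[o])] <- val[o]
  m
}

#' Protein-level abundances per SILAC channel for every protein group
#'
#' Applies [maxlfq()] independently per protein group over all
#' (run, channel) columns. By default all columns of a protein enter one
#' joint MaxLFQ solve, which keeps the per-channel LFQ values mutually
#' comparable for ratio formation; `mode = "per_channel"` instead solves
#' each SILAC channel separately. The precursor count attached to every
#' record is the number of distinct (modified sequence, charge) species of
#' the protein group — SILAC channels do not multiply the count.
#'
#' @param table A filtered precursor tibble.
#' @param quant_source `"ms2"` or `"ms1"`.
#' @param mode `"joint"` (default) or `"per_channel"`.
#' @param min_shared Passed to [maxlfq()].
#' @return A tibble: `protein_group`, `gene`, `run`, `channel`,
#'   `lfq_intensity`, `n_precursors`, with attributes `quant_source` and
#'   `mode`.
#' @export
quantify_channels <- function(table,
                              quant_source = attr(table, "quant_source") %||% "ms2",
                              mode = c("joint", "per_channel"),
                              min_shared = 1) {
  check_precursor_table(table)
  mode <- match.arg(mode)
  quant_source <- match.arg(tolower(quant_source), c("ms2", "ms1"))
  qcol <- quant_column(quant_source)
  empty <- tibble::tibble(protein_group = character(), gene = character(),
                          run = character(), channel = character(),
                          lfq_intensity = numeric(), n_precursors = integer())
  if (nrow(table) == 0) return(empty)

  val <- table[[qcol]]
  keep <- !is.na(val) & val > 0
  tab <- table[keep, , drop = FALSE]
  val <- val[keep]
  if (nrow(tab) == 0) return(empty)

  prec <- paste(tab$modified_sequence, tab$charge, sep = "/")
  colkey <- paste(tab$run, tab$channel, sep = "|")
  groups <- split(seq_len(nrow(tab)), tab$protein_group)
  gene_of <- tapply(tab$gene, tab$protein_group, `[[`, 1)

  res <- lapply(names(groups), function(pg) {
    idx <- groups[[pg]]
    pr <- factor(prec[idx]); cl <- factor(colkey[idx])
    m <- matrix(NA_real_, nlevels(pr), nlevels(cl),
                dimnames = list(levels(pr), levels(cl)))
    v <- val[idx]
    o <- order(v)
    m[cbind(as.integer(pr)[o], as.integer(cl)[o])] <- v[o]
    parts <- strsplit(colnames(m), "|", fixed = TRUE)
    ch <- vapply(parts, `[[`, character(1), 2)
    lfq <- if (mode == "joint") {
      maxlfq(m, min_shared = min_shared)
    } else {
      out <- rep(NA_real_, ncol(m))
      for (c0 in unique(ch)) {
        sel <- ch == c0
        out[sel] <- maxlfq(m[, sel, drop = FALSE], min_shared = min_shared)
      }
      out
    }
    ok <- !is.na(lfq) & lfq > 0
    tibble::tibble(protein_group = pg,
                   run = vapply(parts, `[[`, character(1), 1)[ok],
                   channel = ch[ok],
                   lfq_intensity = unname(lfq[ok]),
                   n_precursors = nlevels(pr))
  })
  out <- dplyr::bind_rows(res) |>
    dplyr::mutate(gene = as.character(gene_of[.data$protein_group]),
                  .after = "protein_group")
  attr(out, "quant_source") <- quant_source
  attr(out, "mode") <- mode
  out
}

#' Per-sample protein-group SILAC ratios from channel LFQ values
#'
#' For every protein group and run where both channels of the pair carry an
#' LFQ intensity, computes `log2(numerator / denominator)`; no value is
#' imputed where either channel is absent.
#'
#' @param quants Output of [quantify_channels()].
#' @param numerator,denominator SILAC channels (`"L"`, `"M"`, `"H"`).
#' @return A tibble `protein_group`, `gene`, `run`, `log2_ratio` with
#'   attributes `pair` and `quant_source`.
#' @export
#' @examples
#' q <- tibble::tibble(protein_group = "P1", gene = "G1",
#'                     run = c("a", "a"), channel = c("H", "M"),
#'                     lfq_intensity = c(2000, 1000), n_precursors = 2L)
#' compute_ratios(q, "H", "M")
compute_ratios <- function(quants, numerator = "H", denominator = "M") {
  if (identical(numerator, denominator)) {
    abort("`numerator` and `denominator` must be different channels.")
  }
  num <- quants[quants$channel == numerator, , drop = FALSE]
  den <- quants[quants$channel == denominator, , drop = FALSE]
  out <- dplyr::inner_join(
    dplyr::select(num, "protein_group", "gene", "run", num = "lfq_intensity"),
    dplyr::select(den, "protein_group", "run", den = "lfq_intensity"),
    by = c("protein_group", "run")) |>
    dplyr::filter(.data$num > 0, .data$den > 0) |>
    dplyr::mutate(log2_ratio = log2(.data$num / .data$den)) |>
    dplyr::select("protein_group", "gene", "run", "log2_ratio") |>
    dplyr::arrange(.data$protein_group, .data$run)
  attr(out, "pair") <- c(numerator = numerator, denominator = denominator)
  attr(out, "quant_source") <- attr(quants, "quant_source")
  out
}

#' Replicate CV (%) of protein SILAC ratios per condition
#'
#' @param ratios Output of [compute_ratios()].
#' @param runs Tibble mapping `run` to `condition` (e.g. from
#'   [design_runs()]); `NULL` treats all runs as one condition.
#' @param min_n Minimum replicate ratios required (default 2).
#' @return Tibble `protein_group`, `condition`, `n`, `cv` (percent, on
#'   linear-scale ratios).
#' @export
ratio_cv <- function(ratios, runs = NULL, min_n = 2) {
  x <- ratios
  if (is.null(runs)) {
    x$condition <- "all"
  } else {
    x$condition <- NULL
    x <- dplyr::left_join(x, runs[, c("run", "condition")], by = "run")
  }
  x |>
    dplyr::group_by(.data$protein_group, .data$condition) |>
    dplyr::summarise(n = sum(!is.na(.data$log2_ratio)),
                     cv = cv_percent(2^.data$log2_ratio, min_n = min_n),
                     .groups = "drop")
}

#' Precursor-level labeled-over-unlabeled intensity ratios
#'
#' For every precursor and run with both the labeled (H or M) and the
#' light (L) intensity present, computes the log2 labeled/light intensity
#' ratio — the enrichment diagnostic comparing newly synthesized
#' (labeled) to pre-existing (light) signal.
#'
#' @param table A precursor tibble.
#' @param quant_source `"ms2"` or `"ms1"`.
#' @return Tibble `run`, `modified_sequence`, `charge`, `labeled_channel`
#'   (`"H"` or `"M"`), `log2_ratio`; per-run medians in the `medians`
#'   attribute. Runs without light intensities yield no rows (reported via
#'   a message).
#' @export
precursor_label_ratio <- function(table,
                                  quant_source = attr(table, "quant_source") %||% "ms2") {
  check_precursor_table(table)
  qcol <- quant_column(quant_source)
  x <- table[, c("run", "modified_sequence", "charge", "channel")]
  x$intensity <- table[[qcol]]
  x <- x[!is.na(x$intensity) & x$intensity > 0, , drop = FALSE]
  wide <- tidyr::pivot_wider(x, names_from = "channel",
                             values_from = "intensity",
                             values_fn = max)
  for (ch in c("L", "M", "H")) if (!ch %in% names(wide)) wide[[ch]] <- NA_real_
  no_light <- setdiff(unique(x$run), unique(wide$run[!is.na(wide$L)]))
  if (length(no_light) > 0) {
    inform(paste0("No light-channel intensities in run(s): ",
                  paste(no_light, collapse = ", ")))
  }
  out <- wide |>
    tidyr::pivot_longer(cols = c("M", "H"), names_to = "labeled_channel",
                        values_to = "labeled") |>
    dplyr::filter(!is.na(.data$labeled), !is.na(.data$L)) |>
    dplyr::mutate(log2_ratio = log2(.data$labeled / .data$L)) |>
    dplyr::select("run", "modified_sequence", "charge", "labeled_channel",
                  "log2_ratio")
  attr(out, "medians") <- out |>
    dplyr::group_by(.data$run, .data$labeled_channel) |>
    dplyr::summarise(median_log2_ratio = median(.data$log2_ratio),
                     .groups = "drop")
  out
}
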