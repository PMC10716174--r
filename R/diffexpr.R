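#' Per-protein replicate statistics of log2 SILAC ratios
#'
#' One-sample summary per protein group over the replicate runs of one
#' condition/time point: the log2 fold change is the mean of the replicate
#' log2 ratios (treatment channel over control channel within each
#' replicate), `s2` the sample variance and `df = n - 1`. Proteins with a
#' single ratio are carried with their fold change but no variance and are
#' excluded from testing (the minimum-two-ratios rule).
#'
#' @param ratios A ratio tibble from [compute_ratios()], restricted to the
#'   replicate runs of one condition (use `runs` to subset).
#' @param runs Optional character vector of run names to restrict to.
#' @param precursor_counts Optional tibble `protein_group`,
#'   `n_precursors` to attach (from [quantify_channels()] output).
#' @return Tibble `protein_group`, `gene`, `n`, `log2_fc`, `s2`, `df`
#'   (plus `n_precursors` when supplied).
#' @export
fit_protein_stats <- function(ratios, runs = NULL, precursor_counts = NULL) {
  x <- ratios[!is.na(ratios$log2_ratio), , drop = FALSE]
  if (!is.null(runs)) x <- x[x$run %in% runs, , drop = FALSE]
  out <- x |>
    dplyr::group_by(.data$protein_group) |>
    dplyr::summarise(gene = .data$gene[1],
                     n = dplyr::n(),
                     log2_fc = mean(.data$log2_ratio),
                     s2 = var(.data$log2_ratio),
                     .groups = "drop") |>
    dplyr::mutate(df = .data$n - 1L)
  if (!is.null(precursor_counts)) {
    out <- dplyr::left_join(
      out, dplyr::distinct(precursor_counts[, c("protein_group", "n_precursors")]),
      by = "protein_group")
  }
  out
}

# Newton inversion of the trigamma function (for the moments estimate of
# the prior degrees of freedom)
trigamma_inverse <- function(x) {
  vapply(x, function(xi) {
    if (!is.finite(xi) || xi <= 0) return(NA_real_)
    if (xi > 1e7) return(1 / sqrt(xi))
    if (xi < 1e-6) return(1 / xi)
    y <- 0.5 + 1 / xi
    for (i in 1:50) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / xi) / psigamma(y, deriv = 2)
      y <- y + dif
      if (-dif / y < 1e-8) break
    }
    y
  }, numeric(1))
}

#' Estimate a precursor-count-dependent variance prior
#'
#' Models per-protein residual variances as scaled F-deviates around a
#' count-dependent prior: a loess curve of the (degree-of-freedom
#' corrected) log variances on log precursor count gives the prior trend
#' `s2_prior(count)`, and the prior degrees of freedom `d0` follow by
#' method-of-moments from the residual scatter on the log scale (the
#' excess of the residual variance over the expected log-chi-square
#' scatter, inverted through the trigamma function). With no excess
#' scatter `d0 = Inf` (full shrinkage); with identical counts the trend
#' collapses to a single pooled prior.
#'
#' @param stats Output of [fit_protein_stats()] including `n_precursors`.
#' @param span Loess span for the count trend (default 0.75).
#' @param min_proteins Minimum number of proteins with `df >= 1` required
#'   (default 20).
#' @param s2_floor Variances are floored at this value before logging
#'   (default 1e-12) so exact-zero variances do not dominate the fit.
#' @return An object of class `nsp_var_prior`: list with `d0`, function
#'   `s2_prior(count)`, the fitted `trend` tibble, and `span`.
#' @export
estimate_variance_prior <- function(stats, span = 0.75, min_proteins = 20,
                                    s2_floor = 1e-12) {
  need <- c("s2", "df", "n_precursors")
  if (!all(need %in% names(stats))) {
    abort("`stats` must carry s2, df and n_precursors (see fit_protein_stats()).")
  }
  ok <- !is.na(stats$s2) & stats$df >= 1 & !is.na(stats$n_precursors)
  if (sum(ok) < min_proteins) {
    abort(paste0("Only ", sum(ok), " proteins with df >= 1; at least ",
                 min_proteins, " are needed to estimate the variance prior. ",
                 "Consider the unmoderated t-test instead."))
  }
  df1 <- stats$df[ok]
  s2 <- pmax(stats$s2[ok], s2_floor)
  counts <- stats$n_precursors[ok]
  x <- log(counts)
  # remove the expected log-chi-square bias so e estimates log(sigma0^2)
  # up to the d0 term
  e <- log(s2) - digamma(df1 / 2) + log(df1 / 2)

  constant <- length(unique(counts)) == 1L
  if (constant) {
    ehat_fun <- local({
      v <- mean(e)
      function(xx) rep(v, length(xx))
    })
  } else {
    lo <- loess(e ~ x, span = span, degree = 1,
                family = "gaussian",
                control = stats::loess.control(surface = "direct"))
    rng <- range(x)
    ehat_fun <- function(xx) predict(lo, pmin(pmax(xx, rng[1]), rng[2]))
  }
  resid <- e - ehat_fun(x)
  evar <- var(resid) - mean(trigamma(df1 / 2))
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    offset <- digamma(d0 / 2) - log(d0 / 2)
  } else {
    # no excess scatter beyond chi-square sampling noise: full shrinkage.
    # With a single pooled prior the arithmetic mean of the variances is
    # used, so the exactly-degenerate limit (all s2 equal) returns the
    # observed value; with a count trend the corrected log-scale fit
    # already estimates log(sigma0^2) unbiasedly.
    d0 <- Inf
    offset <- 0
    if (constant) {
      ehat_fun <- local({
        v <- log(mean(s2))
        function(xx) rep(v, length(xx))
      })
    }
  }
  s2_prior <- function(count) {
    exp(ehat_fun(log(pmax(count, 1))) + offset)
  }
  grid <- sort(unique(counts))
  structure(list(d0 = d0, s2_prior = s2_prior,
                 trend = tibble::tibble(n_precursors = grid,
                                        s2_prior = s2_prior(grid)),
                 span = span, n_proteins = sum(ok), constant = constant),
            class = "nsp_var_prior")
}

#' @export
print.nsp_var_prior <- function(x, ...) {
  cat("<nsp_var_prior> d0 = ", format(x$d0), ", fitted on ", x$n_proteins,
      " proteins", if (x$constant) " (pooled, constant counts)", "\n", sep = "")
  invisible(x)
}

#' Moderated one-sample t-test with a count-dependent prior
#'
#' Shrinks each protein's variance toward the count-conditional prior by
#' the usual squeeze
#' \eqn{s^2_{post} = (d_0 s^2_{prior} + df\, s^2) / (d_0 + df)}
#' (with \eqn{s^2_{post} = s^2_{prior}} at \eqn{d_0 = \infty} and
#' \eqn{s^2_{post} = s^2} at \eqn{d_0 = 0}), forms the moderated t
#' statistic `log2_fc / sqrt(s2_post / n)` and two-sided p-values from the
#' t distribution with `df + d0` degrees of freedom (capped at 1e6 when
#' `d0` is infinite). Proteins failing the minimum-two-ratios rule keep
#' their fold change but get no test statistics.
#'
#' @param stats Output of [fit_protein_stats()] with `n_precursors`.
#' @param prior An `nsp_var_prior` from [estimate_variance_prior()].
#' @return `stats` extended with `s2_prior`, `s2_post`, `t_mod`, `p`.
#' @export
moderate_and_test <- function(stats, prior) {
  if (!inherits(prior, "nsp_var_prior")) {
    abort("`prior` must come from estimate_variance_prior().")
  }
  d0 <- prior$d0
  out <- stats
  out$s2_prior <- prior$s2_prior(out$n_precursors)
  tested <- !is.na(out$s2) & out$df >= 1 & !is.na(out$s2_prior)
  s2_post <- rep(NA_real_, nrow(out))
  if (is.infinite(d0)) {
    s2_post[tested] <- out$s2_prior[tested]
  } else if (d0 == 0) {
    s2_post[tested] <- out$s2[tested]
  } else {
    s2_post[tested] <- (d0 * out$s2_prior[tested] +
                          out$df[tested] * out$s2[tested]) / (d0 + out$df[tested])
  }
  out$s2_post <- s2_post
  out$d0 <- d0
  zero <- tested & s2_post == 0
  if (any(zero)) {
    warn(paste0(sum(zero), " protein(s) with zero posterior variance; ",
                "t statistic infinite, p left absent."))
  }
  out$t_mod <- ifelse(tested & s2_post > 0,
                      out$log2_fc / sqrt(s2_post / out$n), NA_real_)
  total_df <- pmin(out$df + d0, 1e6)
  out$p <- ifelse(!is.na(out$t_mod),
                  2 * pt(-abs(out$t_mod), total_df), NA_real_)
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment (via
#' [stats::p.adjust()]), with input validation; `NA` p-values propagate.
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same order as the input.
#' @export
adjust_bh <- function(pvals) {
  finite <- pvals[!is.na(pvals)]
  if (any(finite < 0 | finite > 1)) {
    abort("p-values must lie in [0, 1].")
  }
  p.adjust(pvals, method = "BH")
}

#' Significance calls at volcano thresholds
#'
#' Flags a protein up-regulated when `p_adj < alpha` and
#' `log2_fc > fc_threshold`, down-regulated when `p_adj < alpha` and
#' `log2_fc < -fc_threshold` (defaults 0.05 and 0.585, i.e. 1.5-fold).
#' Only unique protein groups (a single accession, no `;`) are eligible
#' for significance.
#'
#' @param results A tibble with `protein_group`, `log2_fc`, `p_adj`.
#' @param fc_threshold Absolute log2 fold-change threshold (default 0.585).
#' @param alpha Adjusted-p threshold (default 0.05).
#' @return `results` with added `unique_group`, `significant_up`,
#'   `significant_down` and `call` (`"up"`, `"down"`, `"ns"`,
#'   `"not_tested"`).
#' @export
call_significance <- function(results, fc_threshold = 0.585, alpha = 0.05) {
  out <- results
  out$unique_group <- !grepl(";", out$protein_group, fixed = TRUE)
  tested <- !is.na(out$p_adj)
  out$significant_up <- tested & out$unique_group &
    out$p_adj < alpha & out$log2_fc > fc_threshold
  out$significant_down <- tested & out$unique_group &
    out$p_adj < alpha & out$log2_fc < -fc_threshold
  out$call <- dplyr::case_when(
    !tested ~ "not_tested",
    out$significant_up ~ "up",
    out$significant_down ~ "down",
    TRUE ~ "ns")
  out
}

#' Moderated differential expression for one condition/time point
#'
#' Convenience pipeline: [fit_protein_stats()] on the condition's replicate
#' runs, [estimate_variance_prior()], [moderate_and_test()],
#' [adjust_bh()] (within this condition, i.e. per volcano panel) and
#' [call_significance()].
#'
#' @inheritParams fit_protein_stats
#' @inheritParams estimate_variance_prior
#' @inheritParams call_significance
#' @param prior Optionally a pre-estimated `nsp_var_prior` to reuse.
#' @return An object of class `nsp_defit` with elements `results` (the
#'   per-protein tibble), `prior`, `fc_threshold`, `alpha`.
#' @export
moderated_de <- function(ratios, precursor_counts, runs = NULL,
                         span = 0.75, fc_threshold = 0.585, alpha = 0.05,
                         prior = NULL) {
  stats <- fit_protein_stats(ratios, runs = runs,
                             precursor_counts = precursor_counts)
  if (is.null(prior)) prior <- estimate_variance_prior(stats, span = span)
  results <- moderate_and_test(stats, prior)
  results$p_adj <- adjust_bh(results$p)
  results <- call_significance(results, fc_threshold = fc_threshold,
                               alpha = alpha)
  structure(list(results = results, prior = prior,
                 fc_threshold = fc_threshold, alpha = alpha),
            class = "nsp_defit")
}

#' @export
print.nsp_defit <- function(x, ...) {
  r <- x$results
  cat("<nsp_defit> ", nrow(r), " proteins (", sum(!is.na(r$p)), " tested), ",
      sum(r$significant_up), " up / ", sum(r$significant_down),
      " down at |log2FC| > ", x$fc_threshold, ", adj. p < ", x$alpha,
      "; d0 = ", format(x$prior$d0), "\n", sep = "")
  invisible(x)
}

#' @method tidy nsp_defit
#' @export
tidy.nsp_defit <- function(x, ...) {
  dplyr::select(x$results, "protein_group", "gene", "log2_fc", "t_mod",
                "p", "p_adj", "n", "n_precursors", "call")
}

#' @method glance nsp_defit
#' @export
glance.nsp_defit <- function(x, ...) {
  r <- x$results
  tibble::tibble(n_proteins = nrow(r), n_tested = sum(!is.na(r$p)),
                 n_up = sum(r$significant_up),
                 n_down = sum(r$significant_down),
                 d0 = x$prior$d0,
                 fc_threshold = x$fc_threshold, alpha = x$alpha)
}
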