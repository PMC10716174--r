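#' @importFrom rlang abort warn inform %||% .data
#' @importFrom stats median prcomp pt var loess predict phyper p.adjust
#'   rnorm rlnorm runif rnbinom sd setNames quantile digamma trigamma rchisq
#' @importFrom utils head modifyList
NULL

# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env) else
      if (exists(".Random.seed", envir = env, inherits = FALSE))
        rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

# fields required of a precursor table in the package-internal (simple) dialect
precursor_columns <- function() {
  c("protein_group", "gene", "stripped_sequence", "modified_sequence",
    "charge", "channel", "run", "ms1_quantity", "ms2_quantity",
    "q_value", "channel_q_value", "translated_q_value", "is_contaminant")
}

check_precursor_table <- function(table, call = rlang::caller_env()) {
  if (!is.data.frame(table)) {
    abort("`table` must be a data frame of precursor records.", call = call)
  }
  missing <- setdiff(setdiff(precursor_columns(), "is_contaminant"),
                     names(table))
  if (length(missing) > 0) {
    abort(paste0("Precursor table lacks column(s): ",
                 paste(missing, collapse = ", ")), call = call)
  }
  invisible(table)
}

quant_column <- function(quant_source = c("ms2", "ms1")) {
  quant_source <- tolower(quant_source)
  quant_source <- match.arg(quant_source)
  c(ms1 = "ms1_quantity", ms2 = "ms2_quantity")[[quant_source]]
}

# first gene symbol of a (possibly multi-gene) group, upper-cased
first_symbol <- function(x) {
  toupper(sub(";.*$", "", trimws(x)))
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}
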