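# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so generators are deterministic without clobbering the
#' session stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

#' Percentage of a count, rounded for reporting
#'
#' Shared arithmetic behind the pipeline's headline percentages: the
#' unique-marker percentage is reported to one decimal, the cluster
#' annotation rate and phenotype fraction to the nearest integer.
#'
#' @param k Numerator count.
#' @param n Denominator count.
#' @param digits Decimal places to round to.
#' @return `round(100 * k / n, digits)`; 0 when `n` is 0.
#' @examples
#' fraction_percent(331, 4528, 1)
#' fraction_percent(138, 183, 0)
#' @export
fraction_percent <- function(k, n, digits = 1) {
  stopifnot(length(k) == 1, length(n) == 1, k >= 0, n >= 0)
  if (n == 0) return(0)
  round(100 * k / n, digits)
}

# stop() with sprintf formatting and no call in the condition
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# require named columns on a data.frame
need_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0)
    stopf("%s is missing required column(s): %s", what,
          paste(miss, collapse = ", "))
  invisible(df)
}
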