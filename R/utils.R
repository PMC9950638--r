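#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stop with a classed condition
#'
#' Errors are classed so callers (in particular the batch pipeline, which must
#' not die on one degenerate trait) can distinguish configuration problems,
#' malformed input and analysis-stage failures.
#' @noRd
mr_abort <- function(msg, class = "bidirmr_error", ...) {
  stop(structure(
    class = c(class, "bidirmr_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

config_error <- function(msg, ...) mr_abort(msg, class = "bidirmr_config_error", ...)
input_error <- function(msg, ...) mr_abort(msg, class = "bidirmr_input_error", ...)
analysis_error <- function(msg, ...) mr_abort(msg, class = "bidirmr_analysis_error", ...)

#' Deterministic per-analysis seed
#'
#' Derives a reproducible 31-bit seed from the run seed and the identity of an
#' exposure-outcome analysis, so each trait pair gets randomness that is
#' independent of which other traits are in the batch.
#'
#' @param seed integer run seed.
#' @param ... character labels identifying the analysis (trait ids, direction).
#' @return An integer in [0, 2^31).
#' @export
seed_for <- function(seed, ...) {
  labs <- paste(c(...), collapse = "\r")
  h <- 0
  for (v in utf8ToInt(labs)) h <- (h * 31 + v) %% 2147480009
  as.integer((as.numeric(seed) * 69621 + h) %% 2147480009)
}

#' Two-sided normal p-value from an estimate and its standard error
#' @noRd
z_pval <- function(beta, se) 2 * stats::pnorm(-abs(beta / se))

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
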