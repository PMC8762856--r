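## Internal helpers shared across modules.

#' @importFrom methods new is validObject slot
#' @importFrom stats rnbinom rlnorm optim plogis
#' @importFrom utils read.table write.csv read.csv packageVersion
NULL

## Classed errors so callers can distinguish failure modes programmatically.
ctStop <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(class, "scTypeTree_error")))
}

ctWarn <- function(class, fmt, ...) {
  warning(warningCondition(sprintf(fmt, ...),
                           class = c(class, "scTypeTree_warning")))
}

## Numerically stable sigmoid p = 1 / (1 + exp(x)).
invLogitNeg <- function(x) stats::plogis(-x)

assertScalarNumber <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    ctStop("validity_error", "'%s' must be a single finite number", name)
  invisible(x)
}

## Marker used for an undefined metric (empty denominator).
undefinedRate <- function() NA_real_
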