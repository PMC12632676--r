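#' @importFrom rlang abort warn .data
#' @importFrom stats pnorm qnorm pchisq rnorm rbinom runif plogis coef lm
#'   setNames complete.cases sd cor var
NULL

# log(sum(exp(x))) without overflow
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# two-sided normal p-value from an estimate and its SE
wald_p <- function(beta, se) 2 * stats::pnorm(-abs(beta / se))

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(ok, msg) if (!isTRUE(ok)) rlang::abort(msg)
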