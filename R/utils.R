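# Internal helpers shared across modules.

#' @importFrom rlang abort hash %||% .data
#' @importFrom stats rnorm runif
#' @import tibble
NULL

ws_abort <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "wardsim_error"), ...)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

is_prob <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 0 && x <= 1

is_count <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 0 && x == floor(x)

# stable content digest used for config and floor-plan identity
ws_digest <- function(x) rlang::hash(x)
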