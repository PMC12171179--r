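#' @keywords internal
"_PACKAGE"

#' @importFrom stats predict rnorm runif sd var median quantile aggregate
#'   wilcox.test chisq.test glm binomial setNames
#' @importFrom utils head tail
#' @importFrom Rcpp evalCpp
#' @useDynLib cadfuse, .registration = TRUE
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_cadfuse <- function(..., class = "cadfuse_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

assert_that <- function(ok, ...) {
  if (!isTRUE(ok)) stop_cadfuse(...)
  invisible(TRUE)
}

#' Derive a stage- or component-specific seed from a base seed
#'
#' Hashes a base seed together with a label into a new 31-bit seed, so that
#' independent pipeline stages (simulation, feature screening, training, ...)
#' consume independent but reproducible random streams.
#'
#' @param seed integer base seed.
#' @param label character tag of the consuming component.
#' @return A single integer in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483647)
}

## min-max scaling with statistics learned on a reference (training) block
minmax_fit <- function(x) {
  lo <- apply(x, 2, min)
  hi <- apply(x, 2, max)
  hi <- ifelse(hi > lo, hi, lo + 1)  # constant column -> maps to 0
  list(lo = lo, hi = hi)
}

minmax_apply <- function(x, sc) {
  sweep(sweep(x, 2, sc$lo, "-"), 2, sc$hi - sc$lo, "/")
}

## stable top-k index selection: ties broken by earlier position
top_k_idx <- function(score, k) {
  order(-score, seq_along(score))[seq_len(k)]
}

## file md5, returned unnamed
file_md5 <- function(path) unname(tools::md5sum(path))
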