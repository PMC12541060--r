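#' @keywords internal
"_PACKAGE"

#' @import Matrix
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data
#' @importFrom stats cor cophenetic cutree dist hclust p.adjust pnorm rbinom
#'   rgamma rlnorm rnorm rpois runif sd quantile uniroot var as.dist
#'   complete.cases ks.test setNames
#' @importFrom methods as is
#' @useDynLib creglink, .registration = TRUE
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# column sums that stay plain numeric for sparse or dense input
col_totals <- function(m) {
  if (inherits(m, "Matrix")) Matrix::colSums(m) else colSums(m)
}

row_totals <- function(m) {
  if (inherits(m, "Matrix")) Matrix::rowSums(m) else rowSums(m)
}

# deterministic per-stage seed derived from one master seed; kept < 2^31
derive_seed <- function(seed, stage) {
  (as.integer(seed) + 7919L * as.integer(stage)) %% 2147483647L
}
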