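#' @import data.table
#' @importFrom stats pbinom p.adjust fisher.test cor.test wilcox.test dist hclust cutree sd rnorm rpois rbinom runif complete.cases setNames
#' @importFrom utils head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stopf <- function(...) stop(sprintf(...), call. = FALSE)

assert_that <- function(ok, ...) if (!isTRUE(ok)) stopf(...)

#' Check a numeric vector lies in a closed range
#' @noRd
assert_in_range <- function(x, lo, hi, what) {
  if (anyNA(x) || any(x < lo | x > hi))
    stopf("%s must lie in [%s, %s]", what, lo, hi)
  invisible(x)
}

site_key <- function(chrom, pos, alt = NULL) {
  if (is.null(alt)) paste(chrom, pos, sep = ":") else paste(chrom, pos, alt, sep = ":")
}

BASES <- c("A", "C", "G", "T")

# complement of a base vector
comp_base <- function(b) c(A = "T", C = "G", G = "C", T = "A", N = "N")[b]

STAGES <- c("oocyte", "pronucleus", "zygote", "2cell", "4cell", "8cell", "morula")
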