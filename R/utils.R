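#' @keywords internal
"_PACKAGE"

#' @importFrom methods as is new
#' @importFrom stats rnbinom rbinom rpois rlnorm runif rnorm setNames
#'   p.adjust wilcox.test median quantile sd var cor hclust cutree cophenetic
#'   as.dist dist kmeans prcomp ks.test dnbinom dbinom
#' @importFrom utils head tail write.table read.table
NULL

# Run an expression under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# Derive a stream-specific seed from a master seed, kept inside 32-bit range.
derive_seed <- function(seed, stream) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(stream)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop2 <- function(...) stop(..., call. = FALSE)

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop2(msg)
  invisible(TRUE)
}
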