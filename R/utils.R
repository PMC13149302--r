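#' Derive a child seed from a master seed
#'
#' All stochastic operations in the package draw their seed from a single
#' master seed through this counter-based split, so that one integer pins
#' down the whole pipeline while stages remain independently reproducible.
#'
#' @param master integer master seed.
#' @param stream non-negative integer stream counter (one per consumer).
#' @return An integer seed strictly below 2^31.
#' @export
seed_stream <- function(master, stream) {
  stopifnot(is.numeric(master), length(master) == 1L,
            is.numeric(stream), length(stream) == 1L, stream >= 0)
  # multiplicative congruential mix; constants are the classic MINSTD pair
  m <- 2147483647
  x <- (abs(as.double(master)) %% m) + 1
  x <- (x * 48271) %% m
  x <- (x + (as.double(stream) + 1) * 104729) %% m
  x <- (x * 48271) %% m
  as.integer(x)
}

# run code under a temporary RNG seed, restoring global RNG state afterwards
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# stop() with call.=FALSE and sprintf-style formatting
abort <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

assert_that <- function(ok, fmt, ...) {
  if (!isTRUE(ok)) abort(fmt, ...)
  invisible(TRUE)
}

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == round(x)
}

is_fraction <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
}

# coerce to a cell x gene sparse dgCMatrix, keeping dimnames
as_cell_gene_matrix <- function(counts) {
  if (is.matrix(counts)) {
    m <- Matrix::Matrix(counts * 1.0, sparse = TRUE)
  } else {
    m <- counts
  }
  m <- methods::as(methods::as(methods::as(m, "dMatrix"), "generalMatrix"),
                   "CsparseMatrix")
  assert_that(all(m@x >= 0), "counts must be non-negative")
  m
}
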