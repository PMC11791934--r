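## Internal helpers shared across modules.

#' @useDynLib pseudomri, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats median mad rnorm runif quantile setNames dist
NULL

# Classed condition so callers can test on error class rather than message.
pmri_stop <- function(class, msg, call. = FALSE) {
  cond <- structure(
    class = c(class, "pseudomri_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  )
  stop(cond)
}

# Run code with a temporary RNG state; restores the caller's stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

as_point_matrix <- function(x, arg = "points") {
  if (is.null(dim(x))) {
    if (length(x) != 3L)
      pmri_stop("invalid_points", sprintf("'%s' must be an n x 3 matrix", arg))
    x <- matrix(as.numeric(x), 1L, 3L)
  }
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) != 3L)
    pmri_stop("invalid_points", sprintf("'%s' must have 3 columns", arg))
  if (nrow(x) > 0L && !all(is.finite(x)))
    pmri_stop("invalid_points", sprintf("'%s' contains non-finite coordinates", arg))
  dimnames(x) <- NULL
  x
}

row_norms <- function(m) sqrt(rowSums(m * m))
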