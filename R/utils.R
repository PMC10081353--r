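# internal helpers shared across modules

# coerce a 3-vector or n x 3 matrix to n x 3 matrix; remember original shape
as_points <- function(x) {
  if (is.matrix(x)) {
    if (ncol(x) != 3L) stop("point matrix must have 3 columns")
    storage.mode(x) <- "double"
    x
  } else {
    if (length(x) != 3L) stop("a point must be a 3-vector")
    matrix(as.double(x), nrow = 1L)
  }
}

# return in the shape of the input: vector in -> vector out
restore_shape <- function(pts, x) {
  if (is.matrix(x)) pts else drop(pts)
}

row_norms <- function(m) sqrt(rowSums(m * m))

spectral_norm <- function(m) {
  # largest singular value; norm(, "2") errors on all-zero NA edge cases we never hit
  norm(m, type = "2")
}

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name))
  if (positive && x <= 0) stop(sprintf("'%s' must be > 0", name))
  invisible(x)
}

# parameter grid for sampling a curve defined on params `t` at steps <= spacing,
# always including every knot parameter
sampling_params <- function(t, spacing) {
  stopifnot_scalar(spacing, "spacing", positive = TRUE)
  n <- length(t)
  if (n == 1L) return(t)
  out <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    len <- t[i + 1L] - t[i]
    m <- max(1L, ceiling(len / spacing - 1e-9))
    out[[i]] <- t[i] + (seq_len(m) - 1L) / m * len
  }
  c(unlist(out), t[n])
}
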