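#' Polyline branches
#'
#' A `polyline_branch` is a non-branching, arc-length-parameterized piecewise
#' linear curve: an ordered set of distinct 3D knots (microns) together with
#' parameters `params` equal to cumulative chord length, so the curve has unit
#' speed in the piecewise-linear sense.
#'
#' @param knots numeric `n x 3` matrix of knot positions in microns.
#' @param params optional numeric vector of cumulative chord-length
#'   parameters; computed from `knots` when `NULL`. Must start at 0, be
#'   strictly increasing, and match the chord lengths.
#' @param source_ids optional integer vector of originating SWC node ids.
#' @return An object of class `polyline_branch` with elements `knots`,
#'   `params` and optionally `source_ids`.
#' @seealso [arc_length_parameterize()] to build a branch from raw knots with
#'   duplicate repair, [downsample_branch()], [decompose_to_branches()].
#' @export
polyline_branch <- function(knots, params = NULL, source_ids = NULL) {
  knots <- as_points(knots)
  n <- nrow(knots)
  if (n < 2L) stop("a polyline branch needs at least 2 knots")
  seg <- row_norms(knots[-1L, , drop = FALSE] - knots[-n, , drop = FALSE])
  if (any(seg == 0)) stop("consecutive knots must be distinct (|c'| > 0)")
  chord <- c(0, cumsum(seg))
  if (is.null(params)) {
    params <- chord
  } else {
    if (length(params) != n) stop("params length must match number of knots")
    if (params[1L] != 0) stop("params must start at 0")
    if (max(abs(params - chord)) > 1e-6 * max(1, chord[n]))
      stop("params must equal cumulative chord length (arc-length parameterization)")
  }
  out <- list(knots = knots, params = as.double(params))
  if (!is.null(source_ids)) {
    if (length(source_ids) != n) stop("source_ids length must match knots")
    out$source_ids <- as.integer(source_ids)
  }
  structure(out, class = "polyline_branch")
}

#' @export
print.polyline_branch <- function(x, ...) {
  cat(sprintf("<polyline_branch: %d knots, length %.3f um>\n",
              nrow(x$knots), x$params[length(x$params)]))
  invisible(x)
}

#' Arc-length parameterization of a knot sequence
#'
#' Builds a [polyline_branch()] from raw knot positions, assigning each knot
#' the cumulative chord length from the first knot. Consecutive duplicate
#' knots violate curve regularity (`|c'| > 0`) and are dropped with a
#' warning; real SWC files occasionally contain them.
#'
#' @param knots numeric `n x 3` matrix (n >= 2) of knot positions, microns.
#' @param source_ids optional node ids carried through (duplicates dropped
#'   alongside their knots).
#' @return A `polyline_branch`. The attribute `"kept"` records the indices of
#'   the input knots that survived duplicate removal.
#' @export
arc_length_parameterize <- function(knots, source_ids = NULL) {
  knots <- as_points(knots)
  n <- nrow(knots)
  if (n < 2L) stop("need at least 2 knots")
  seg <- row_norms(knots[-1L, , drop = FALSE] - knots[-n, , drop = FALSE])
  keep <- c(TRUE, seg > 0)
  if (!all(keep)) {
    warning(sprintf("dropped %d duplicate consecutive knot(s)", sum(!keep)))
    knots <- knots[keep, , drop = FALSE]
    if (!is.null(source_ids)) source_ids <- source_ids[keep]
  }
  if (nrow(knots) < 2L) stop("degenerate curve: all knots identical")
  br <- polyline_branch(knots, source_ids = source_ids)
  attr(br, "kept") <- which(keep)
  br
}

#' Downsample a branch by an integer period
#'
#' Retains the first knot, every interior knot whose (0-based) index is
#' divisible by `period`, and the last knot; parameters are recomputed as
#' cumulative chord length of the retained knots. This is the downsampling
#' protocol used when studying coarse traces: both end knots plus every one
#' out of `period` knots in between.
#'
#' @param branch a `polyline_branch`.
#' @param period positive integer retention period; `1` returns the branch
#'   unchanged.
#' @return A `polyline_branch` over the retained knots.
#' @export
downsample_branch <- function(branch, period) {
  stopifnot(inherits(branch, "polyline_branch"))
  if (!is.numeric(period) || length(period) != 1L || period < 1 ||
      period != round(period))
    stop("'period' must be a positive integer")
  n <- nrow(branch$knots)
  idx <- unique(c(which((seq_len(n) - 1L) %% period == 0L), n))
  arc_length_parameterize(branch$knots[idx, , drop = FALSE],
                          source_ids = branch$source_ids[idx])
}

# piecewise-linear evaluation of a branch at parameters t (vectorized)
polyline_point <- function(branch, t) {
  p <- branch$params
  n <- length(p)
  i <- findInterval(t, p, rightmost.closed = TRUE)
  i[i < 1L] <- 1L
  i[i >= n] <- n - 1L
  w <- (t - p[i]) / (p[i + 1L] - p[i])
  branch$knots[i, , drop = FALSE] * (1 - w) +
    branch$knots[i + 1L, , drop = FALSE] * w
}

#' Export branches to CSV
#'
#' Writes one row per knot with columns `branch_id`, `knot_index`, `t`, `x`,
#' `y`, `z`.
#'
#' @param branches list of `polyline_branch`.
#' @param path output CSV path.
#' @return Invisibly, the data frame written.
#' @export
export_branches_csv <- function(branches, path) {
  rows <- lapply(seq_along(branches), function(b) {
    br <- branches[[b]]
    data.frame(branch_id = b,
               knot_index = seq_len(nrow(br$knots)) - 1L,
               t = br$params,
               x = br$knots[, 1L], y = br$knots[, 2L], z = br$knots[, 3L])
  })
  df <- do.call(rbind, rows)
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}
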