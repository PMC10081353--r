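#' Map a neuron tree through a transformation
#'
#' Decomposes the tree into non-branching branches, maps each with the
#' requested order, and returns the mapped tree (knot positions transformed
#' in place; ids, topology, type codes and radii preserved). Optionally also
#' returns a densely resampled version of the mapped curves and a sidecar
#' table of the mapped one-sided derivatives (SWC has no derivative
#' fields).
#'
#' Knot positions are identical under both orders — the orders differ in
#' the interpolant between knots, which the dense output realizes.
#'
#' @param tree a [neuron_tree()].
#' @param transform a `transform`.
#' @param order mapping order, 0 or 1.
#' @param dense_spacing optional sampling step, microns, for a densely
#'   resampled mapped tree.
#' @return A list of class `mapped_neuron`: `tree` (mapped `neuron_tree`),
#'   `dense` (`neuron_tree` or `NULL`), and `derivatives` (data frame
#'   `node_id, side, dx, dy, dz` for order 1, else `NULL`).
#' @export
map_neuron <- function(tree, transform, order = 0L, dense_spacing = NULL) {
  stopifnot(inherits(tree, "neuron_tree"))
  order <- as.integer(order)
  nodes <- tree$nodes
  pos <- as.matrix(nodes[, c("x", "y", "z")])
  mapped <- tryCatch(as_points(tf_evaluate(transform, pos)), error = function(e) {
    bad <- integer(0)
    for (i in seq_len(nrow(pos))) {
      ok <- tryCatch({ tf_evaluate(transform, pos[i, ]); TRUE },
                     error = function(e2) FALSE)
      if (!ok) bad <- c(bad, nodes$id[i])
    }
    stop("node(s) outside transform domain: ", paste(bad, collapse = ", "),
         call. = FALSE)
  })
  out <- nodes
  out$x <- mapped[, 1L]; out$y <- mapped[, 2L]; out$z <- mapped[, 3L]
  result <- list(tree = neuron_tree(out), dense = NULL, derivatives = NULL)

  branches <- decompose_to_branches(tree)
  if (order >= 1L && length(branches)) {
    rows <- lapply(branches, function(br) {
      js <- apply_jet_action(jet_extension_from_polyline(br, 1L), transform)
      n <- nrow(js$x0)
      data.frame(node_id = rep(br$source_ids, 2L),
                 side = rep(c("right", "left"), each = n),
                 dx = c(js$d_right[, 1L], js$d_left[, 1L]),
                 dy = c(js$d_right[, 2L], js$d_left[, 2L]),
                 dz = c(js$d_right[, 3L], js$d_left[, 3L]))
    })
    deriv <- do.call(rbind, rows)
    result$derivatives <- deriv[!is.na(deriv$dx), , drop = FALSE]
  }
  if (!is.null(dense_spacing) && length(branches))
    result$dense <- dense_mapped_tree(tree, branches, transform, order,
                                      dense_spacing)
  structure(result, class = "mapped_neuron")
}

# reassemble densely sampled mapped branches into one SWC tree; interior
# sample points inherit the type/radius of the preceding original knot
# (radius interpolation is out of scope)
dense_mapped_tree <- function(tree, branches, transform, order, spacing) {
  nodes <- tree$nodes
  meta <- nodes[match(unlist(lapply(branches, `[[`, "source_ids")), nodes$id), ]
  rows <- list()
  next_id <- 1L
  knot_new_id <- new.env(hash = TRUE)  # original node id -> emitted dense id
  for (b in seq_along(branches)) {
    br <- branches[[b]]
    mc <- if (order == 0L) map_zeroth(br, transform) else map_first(br, transform)
    samp <- sample_curve(mc, spacing)
    sp <- attr(samp, "source_params")
    pts <- samp$knots
    # nearest original knot at or before each sample parameter
    ki <- findInterval(sp + 1e-9, br$params)
    ki[ki < 1L] <- 1L
    src_ids <- br$source_ids[ki]
    at_knot <- abs(sp - br$params[ki]) < 1e-9
    first_src <- br$source_ids[1L]
    parent_prev <- if (!is.null(knot_new_id[[as.character(first_src)]]))
      knot_new_id[[as.character(first_src)]] else -1L
    start <- if (parent_prev != -1L) 2L else 1L  # junction already emitted
    for (r in start:nrow(pts)) {
      id <- next_id; next_id <- next_id + 1L
      ref <- nodes[match(src_ids[r], nodes$id), ]
      rows[[length(rows) + 1L]] <- data.frame(
        id = id, type = ref$type,
        x = pts[r, 1L], y = pts[r, 2L], z = pts[r, 3L],
        radius = ref$radius, parent = parent_prev)
      parent_prev <- id
      if (at_knot[r]) knot_new_id[[as.character(src_ids[r])]] <- id
    }
  }
  neuron_tree(do.call(rbind, rows))
}

#' Compare mapping orders against dense ground truth, per branch
#'
#' For every branch of the tree: the ground truth is the dense mapping of
#' the original piecewise linear branch (2-micron sampling by default).
#' Optionally the branch is then downsampled; both zeroth- and first-order
#' mappings of the (possibly downsampled) branch are sampled at the same
#' spacing and compared to the ground truth with discrete Frechet distance.
#' Both orders see the same information, the knot positions.
#'
#' The summary reports the median error difference (order 0 minus order 1;
#' positive means first order was closer to truth) and the Pearson
#' correlation between the error difference and the branch mean sampling
#' period, tested at `alpha`.
#'
#' @param tree a [neuron_tree()] (or a list of `polyline_branch`).
#' @param transform a `transform`.
#' @param downsample_period optional integer knot-retention period applied
#'   before mapping (see [downsample_branch()]).
#' @param spacing sampling step for ground truth and mapped splines,
#'   microns (default 2).
#' @param alpha significance level for the correlation test (default 0.01).
#' @return A list of class `mapping_evaluation`: `rows` (data frame with
#'   `branch_id`, `n_knots`, `mean_sampling_period`, `frechet_order0`,
#'   `frechet_order1`, `error_difference`) and `summary`.
#' @export
evaluate_mapping <- function(tree, transform, downsample_period = NULL,
                             spacing = 2, alpha = 0.01) {
  branches <- if (inherits(tree, "neuron_tree")) decompose_to_branches(tree)
              else tree
  rows <- list()
  for (b in seq_along(branches)) {
    br <- branches[[b]]
    truth <- map_dense_reference(br, transform, spacing)
    br_use <- if (!is.null(downsample_period))
      downsample_branch(br, downsample_period) else br
    if (nrow(br_use$knots) < 2L) {
      warning(sprintf("branch %d has < 2 knots after downsampling; skipped", b))
      next
    }
    s0 <- sample_curve(map_zeroth(br_use, transform), spacing)
    s1 <- sample_curve(map_first(br_use, transform), spacing)
    f0 <- discrete_frechet(s0, truth)$distance
    f1 <- discrete_frechet(s1, truth)$distance
    rows[[length(rows) + 1L]] <- data.frame(
      branch_id = b, n_knots = nrow(br_use$knots),
      mean_sampling_period = mean(diff(br_use$params)),
      frechet_order0 = f0, frechet_order1 = f1,
      error_difference = f0 - f1)
  }
  rows <- do.call(rbind, rows)
  summary <- list(n_branches = nrow(rows),
                  median_error_difference = median(rows$error_difference),
                  alpha = alpha)
  if (nrow(rows) >= 3L && stats::sd(rows$mean_sampling_period) > 0 &&
      stats::sd(rows$error_difference) > 0) {
    ct <- cor.test(rows$error_difference, rows$mean_sampling_period,
                   method = "pearson")
    summary$pearson_r <- unname(ct$estimate)
    summary$pearson_p <- ct$p.value
    summary$significant <- ct$p.value < alpha
  }
  structure(list(rows = rows, summary = summary), class = "mapping_evaluation")
}

#' @export
print.mapping_evaluation <- function(x, ...) {
  cat(sprintf("<mapping_evaluation: %d branches, median (order0 - order1) = %.4g um>\n",
              x$summary$n_branches, x$summary$median_error_difference))
  invisible(x)
}

#' Per-branch error-bound reports and the length-linear corollary
#'
#' Emits the piecewise-C1 and piecewise-linear zeroth-order bounds for every
#' branch, plus the transform's length-linear constants `(a, b)` and the
#' maximal straight-segment length `L*(e)` (see
#' [affine_bound_in_length()]).
#'
#' @param tree a [neuron_tree()] or list of `polyline_branch`.
#' @param transform a `transform`.
#' @param points domain sample points (matrix or grid spec) for the
#'   length-linear constants.
#' @param e error budget for `L*`, microns.
#' @param path optional JSON output path.
#' @return A list of class `bounds_reports`: `branches` (list with
#'   `bound_c1` and `bound_piecewise_linear` per branch) and `length_bound`.
#' @export
compute_bounds <- function(tree, transform, points, e = 1, path = NULL) {
  branches <- if (inherits(tree, "neuron_tree")) decompose_to_branches(tree)
              else tree
  reports <- lapply(branches, function(br)
    list(bound_c1 = bound_c1(br, transform),
         bound_piecewise_linear = bound_piecewise_linear(br, transform)))
  lb <- affine_bound_in_length(transform, points, e)
  out <- structure(list(branches = reports, length_bound = lb),
                   class = "bounds_reports")
  if (!is.null(path)) {
    ser <- list(
      length_bound = list(slope = lb$slope, intercept = lb$intercept,
                          e = lb$e,
                          l_star = if (is.finite(lb$l_star)) lb$l_star else "Inf"),
      branches = lapply(reports, function(r)
        list(bound_c1 = r$bound_c1$overall,
             bound_piecewise_linear = r$bound_piecewise_linear$overall)))
    jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Generate reproducible curve and field fixtures on disk
#'
#' Realizes JSON curve/field specs into an SWC trace and a JSON
#' displacement-field file. Deterministic given the seeds in the specs.
#'
#' @param curve_config path to a JSON curve spec (arguments of
#'   [make_curve()] plus `knot_period` for [sample_knots()]).
#' @param field_config path to a JSON field spec (arguments of
#'   [make_field()]).
#' @param out_dir output directory (created if missing).
#' @return Invisibly, a list with the written `swc` and `field` paths.
#' @export
simulate_fixtures <- function(curve_config, field_config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cs <- jsonlite::fromJSON(curve_config)
  fs <- jsonlite::fromJSON(field_config)
  knot_period <- if (!is.null(cs$knot_period)) cs$knot_period else 10
  cs$knot_period <- NULL
  curve <- do.call(make_curve, cs)
  branch <- sample_knots(curve, knot_period)
  swc_path <- file.path(out_dir, "curve.swc")
  write_swc(chain_tree(branch$knots), swc_path)
  fs$realize <- "grid"
  field <- do.call(make_field, fs)
  field_path <- file.path(out_dir, "field.json")
  write_transform(field, field_path)
  invisible(list(swc = swc_path, field = field_path))
}
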