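#' Representational dissimilarity matrix (1 - Pearson r)
#'
#' Pairwise Pearson correlation distance between condition patterns. The
#' result is symmetric with a zero diagonal and entries in `[0, 2]`.
#'
#' @param patterns numeric matrix (voxels x conditions) or a
#'   [pattern_set()].
#' @param conditions optional data frame with `target` and `state` columns
#'   (taken from the pattern set when given one).
#' @return Object of class `rdm`: the distance matrix with the condition
#'   table in attribute `conditions`.
#' @export
compute_rdm <- function(patterns, conditions = NULL) {
  if (inherits(patterns, "pattern_set")) {
    conditions <- patterns$conditions
    patterns <- patterns$data
  }
  patterns <- as.matrix(patterns)
  if (ncol(patterns) < 2) stop("need at least 2 conditions")
  if (nrow(patterns) < 3) stop("patterns must have length >= 3")
  sds <- apply(patterns, 2, sd)
  if (any(sds == 0)) {
    bad <- colnames(patterns)[sds == 0] %||% which(sds == 0)
    stop("constant (zero-variance) pattern for condition(s): ",
         paste(bad, collapse = ", "))
  }
  d <- 1 - cor(patterns)
  diag(d) <- 0
  structure(d, class = c("rdm", "matrix"), conditions = conditions)
}

#' Mean within-target dissimilarity (the distinctiveness statistic)
#'
#' Averages the lower-triangle entries of the RDM restricted to one
#' target's states: the mean pairwise pattern dissimilarity among that
#' target's mental states. Cross-target entries never contribute. Higher
#' values mean more differentiated (more distinct) state representations.
#'
#' @param rdm a [compute_rdm()] result whose conditions carry a `target`
#'   column.
#' @param target target label.
#' @param fisher_z average on the Fisher-z scale of the correlation
#'   (1 minus the distance) instead of averaging distances directly (off
#'   by default; distances are averaged raw).
#' @return Scalar mean dissimilarity.
#' @export
average_target_dissimilarity <- function(rdm, target, fisher_z = FALSE) {
  conds <- attr(rdm, "conditions")
  if (is.null(conds) || is.null(conds$target))
    stop("rdm has no target-labelled conditions")
  sel <- which(conds$target == target)
  if (length(sel) < 2)
    stop("need at least 2 states for target '", target, "'")
  sub <- unclass(rdm)[sel, sel, drop = FALSE]
  v <- sub[lower.tri(sub)]
  if (fisher_z) 1 - tanh(mean(atanh(pmin(pmax(1 - v, -1 + 1e-12),
                                         1 - 1e-12))))
  else mean(v)
}

# lattice offsets within a Euclidean sphere of given voxel radius
sphere_offsets <- function(radius) {
  r <- floor(radius)
  g <- expand.grid(x = -r:r, y = -r:r, z = -r:r)
  g <- g[g$x^2 + g$y^2 + g$z^2 <= radius^2, , drop = FALSE]
  as.matrix(g)
}

#' Searchlight centers and neighborhoods
#'
#' For every in-mask voxel, collects the in-mask voxels within a Euclidean
#' sphere of `radius_voxels` on the integer lattice. Neighborhoods smaller
#' than `min_voxels` are recorded as skipped and excluded from downstream
#' maps.
#'
#' @param mask logical 3D array.
#' @param radius_voxels sphere radius in voxel units (>= 0).
#' @param min_voxels minimum neighborhood size.
#' @return List with `centers` (1-based linear indices), `neighbors`
#'   (list over the full grid; entries for centers hold linear indices),
#'   `skipped` (centers whose neighborhood was too small), `dims`.
#' @export
searchlight_centers <- function(mask, radius_voxels = 4, min_voxels = 30) {
  mask <- array(as.logical(mask), dim = dim(mask))
  if (!any(mask)) stop("mask is empty")
  if (radius_voxels < 0) stop("radius must be nonnegative")
  res <- sl_build_cpp(as.vector(mask), dim(mask),
                      sphere_offsets(radius_voxels))
  sizes <- vapply(res$centers, function(v) length(res$neighbors[[v]]), 1L)
  list(centers = res$centers[sizes >= min_voxels],
       neighbors = res$neighbors,
       skipped = res$centers[sizes < min_voxels],
       dims = dim(mask))
}

#' Searchlight map of per-target distinctiveness
#'
#' At every searchlight center, computes the RDM over the neighborhood's
#' voxels and averages the within-target lower-triangle distances,
#' producing one volume per target. Conditions that are constant within a
#' neighborhood are dropped there; neighborhoods losing more than
#' `max_drop_frac` of their conditions, or smaller than `min_voxels`, are
#' skipped (NA).
#'
#' @param patterns a [pattern_set()].
#' @param mask logical array; default all voxels.
#' @param radius_voxels searchlight radius in voxel units.
#' @param min_voxels minimum neighborhood size.
#' @param max_drop_frac maximum tolerated fraction of dropped conditions.
#' @param lights optional precomputed [searchlight_centers()] result
#'   (reused across subjects for speed).
#' @return Named list (one 3D array per target) of mean within-target
#'   dissimilarities, class `distinctiveness_maps`, with attributes
#'   `subject` and `n_skipped`.
#' @export
searchlight_distinctiveness <- function(patterns, mask = NULL,
                                        radius_voxels = 4, min_voxels = 30,
                                        max_drop_frac = 0.1, lights = NULL) {
  stopifnot(inherits(patterns, "pattern_set"))
  tg <- unique(patterns$conditions$target)
  nst <- table(patterns$conditions$target)
  if (any(nst < 2)) stop("need at least 2 states per target")
  if (is.null(mask)) mask <- array(TRUE, dim = patterns$dims)
  if (is.null(lights))
    lights <- searchlight_centers(mask, radius_voxels, min_voxels)
  grp <- match(patterns$conditions$target, tg) - 1L
  res <- sl_distinct_cpp(patterns$data, lights$neighbors,
                         lights$centers, grp, length(tg), min_voxels,
                         max_drop_frac)
  out <- setNames(lapply(seq_along(tg), function(g)
    array(res[, g], dim = patterns$dims)), tg)
  structure(out, class = "distinctiveness_maps",
            subject = patterns$subject,
            n_skipped = sum(attr(res, "skipped") > 0))
}

#' ROI distinctiveness per target
#'
#' The searchlight statistic computed once over a fixed voxel set: patterns
#' are restricted to the ROI, correlated across conditions, and the
#' within-target distances averaged.
#'
#' @param patterns a [pattern_set()].
#' @param roi_mask logical array selecting the ROI voxels.
#' @param fisher_z passed to [average_target_dissimilarity()].
#' @return Data frame with one row per target: `target`,
#'   `mean_dissimilarity`, and its companion mean-correlation form
#'   `mean_correlation = 1 - mean_dissimilarity`.
#' @export
roi_distinctiveness <- function(patterns, roi_mask, fisher_z = FALSE) {
  stopifnot(inherits(patterns, "pattern_set"))
  sel <- as.vector(roi_mask)
  if (length(sel) != nrow(patterns$data))
    stop("roi_mask does not match the pattern grid")
  rdm <- compute_rdm(patterns$data[sel, , drop = FALSE],
                     patterns$conditions)
  tg <- unique(patterns$conditions$target)
  d <- vapply(tg, function(t)
    average_target_dissimilarity(rdm, t, fisher_z = fisher_z), 1.0)
  data.frame(target = tg, mean_dissimilarity = unname(d),
             mean_correlation = 1 - unname(d), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Remove design-induced structure from a condition similarity matrix
#'
#' Blocked trial designs induce correlations among condition estimators
#' that contaminate pattern similarity. This residualizes the off-diagonal
#' neural similarities on the design-induced estimator similarities
#' ([design_induced_similarity()]) by least squares across condition pairs.
#' When the induced similarities are constant across pairs (orthogonal
#' design) the fit reduces to an intercept, i.e. the similarities are
#' simply centered. The diagonal is untouched.
#'
#' @param similarity condition x condition neural similarity (correlation)
#'   matrix, labelled.
#' @param induced matching design-induced similarity matrix.
#' @return Adjusted symmetric similarity matrix.
#' @export
correct_block_structure <- function(similarity, induced) {
  similarity <- as.matrix(similarity)
  induced <- as.matrix(induced)
  if (!identical(dim(similarity), dim(induced)))
    stop("similarity and induced matrices must have the same dimension")
  if (!is.null(rownames(similarity)) && !is.null(rownames(induced)) &&
      !identical(rownames(similarity), rownames(induced)))
    stop("condition labels of similarity and induced matrices differ")
  lt <- lower.tri(similarity)
  y <- similarity[lt]
  x <- induced[lt]
  res <- if (sd(x) == 0) y - mean(y) else resid(lm(y ~ x))
  out <- similarity
  out[lt] <- res
  out[upper.tri(out)] <- t(out)[upper.tri(out)]
  out
}
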