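#' Classical MDS embedding of one target's state dissimilarities
#'
#' Torgerson scaling: 2-D coordinates from the double-centered squared
#' distance matrix (via [stats::cmdscale()]), deterministic up to rotation
#' and reflection. The embedding carries a circle radius equal to the mean
#' within-target dissimilarity, the summary statistic visualized alongside
#' the state layout.
#'
#' @param rdm a square dissimilarity matrix for one target (state labels in
#'   dimnames), or a [compute_rdm()] result together with `target`.
#' @param target optional target label used to subset a multi-target RDM.
#' @param k embedding dimension.
#' @return Object of class `embedding`: list with `target`, `coords`
#'   (states x k, centered), `radius`.
#' @export
mds_embed <- function(rdm, target = NULL, k = 2) {
  conds <- attr(rdm, "conditions")
  d <- unclass(as.matrix(rdm))
  if (!is.null(target) && !is.null(conds)) {
    sel <- which(conds$target == target)
    d <- d[sel, sel, drop = FALSE]
    dimnames(d) <- list(conds$state[sel], conds$state[sel])
  }
  if (nrow(d) < 3) stop("need at least 3 states to embed")
  coords <- cmdscale(stats::as.dist(d), k = k)
  coords <- scale(coords, center = TRUE, scale = FALSE)
  attr(coords, "scaled:center") <- NULL
  rownames(coords) <- rownames(d)
  structure(list(target = target %||% "all", coords = coords,
                 radius = mean(d[lower.tri(d)])),
            class = "embedding")
}

#' Orthogonal Procrustes alignment of one embedding onto another
#'
#' Rotates (and possibly reflects) the moving embedding to minimize the
#' summed squared coordinate discrepancy with the reference over their
#' shared state labels. No isotropic scaling is applied, so circle radii
#' and within-target distances stay meaningful: the transform is
#' `R = U V'` from the SVD of the cross-covariance of the centered shared
#' coordinates.
#'
#' @param reference,moving [mds_embed()] results.
#' @param labels optional state labels to align on; default the shared
#'   rownames.
#' @return The moving embedding with rotated coordinates; attributes
#'   `rotation` (the orthogonal matrix) and `disparity` (mean squared
#'   discrepancy over shared labels).
#' @export
procrustes_align <- function(reference, moving, labels = NULL) {
  stopifnot(inherits(reference, "embedding"), inherits(moving, "embedding"))
  labels <- labels %||% intersect(rownames(reference$coords),
                                  rownames(moving$coords))
  if (length(labels) < 2) stop("need at least 2 shared state labels")
  X <- reference$coords[labels, , drop = FALSE]
  Y <- moving$coords[labels, , drop = FALSE]
  X <- scale(X, center = TRUE, scale = FALSE)
  Y <- scale(Y, center = TRUE, scale = FALSE)
  if (sum(Y^2) == 0 || sum(X^2) == 0)
    stop("degenerate configuration: all points coincident")
  sv <- svd(crossprod(Y, X))
  R <- sv$u %*% t(sv$v)
  out <- moving
  out$coords <- moving$coords %*% R
  rownames(out$coords) <- rownames(moving$coords)
  attr(out, "rotation") <- R
  attr(out, "disparity") <- mean(rowSums((Y %*% R - X)^2))
  out
}

#' @exportS3Method print embedding
print.embedding <- function(x, ...) {
  cat(sprintf("<embedding> target %s: %d states in %dD, circle radius %.3f\n",
              x$target, nrow(x$coords), ncol(x$coords), x$radius))
  invisible(x)
}
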