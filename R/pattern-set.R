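#' Construct a pattern set
#'
#' A pattern set holds one beta volume per (target, state) condition for a
#' single subject, on a shared voxel grid. It is the unit of input to all
#' representational similarity analyses.
#'
#' @param data numeric matrix (`prod(dims)` voxels by conditions) or a 4D
#'   array whose fourth dimension indexes conditions.
#' @param targets character vector of target labels, one per condition.
#' @param states character vector of state labels, one per condition.
#' @param dims integer(3) voxel grid shape.
#' @param voxel_size_mm voxel edge length(s) in mm (scalar or length 3).
#' @param subject subject identifier.
#' @return An object of class `pattern_set`: a list with elements `data`
#'   (voxels x conditions matrix), `conditions` (data frame with `target`,
#'   `state`, `label`), `dims`, `voxel_size_mm`, `subject`.
#' @export
pattern_set <- function(data, targets, states, dims,
                        voxel_size_mm = 2, subject = "s01") {
  if (is.array(data) && length(dim(data)) == 4) {
    dims <- dim(data)[1:3]
    data <- matrix(data, nrow = prod(dims))
  }
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3, nrow(data) == prod(dims))
  targets <- as.character(targets)
  states <- as.character(states)
  if (length(targets) != ncol(data) || length(states) != ncol(data))
    stop("need one target and one state label per condition column")
  label <- paste(targets, states, sep = ":")
  if (anyDuplicated(label))
    stop("duplicate (target, state) condition labels: ",
         paste(unique(label[duplicated(label)]), collapse = ", "))
  if (length(voxel_size_mm) == 1) voxel_size_mm <- rep(voxel_size_mm, 3)
  structure(list(
    data = `colnames<-`(as.matrix(data), label),
    conditions = data.frame(target = targets, state = states, label = label,
                            stringsAsFactors = FALSE),
    dims = dims, voxel_size_mm = voxel_size_mm, subject = subject
  ), class = "pattern_set")
}

#' @exportS3Method print pattern_set
print.pattern_set <- function(x, ...) {
  cat(sprintf("<pattern_set> subject %s: %d conditions (%d targets x states) on a %s grid (%s mm voxels)\n",
              x$subject, ncol(x$data), length(unique(x$conditions$target)),
              paste(x$dims, collapse = "x"),
              paste(unique(x$voxel_size_mm), collapse = "x")))
  invisible(x)
}

#' Extract one condition volume from a pattern set
#'
#' @param ps a [pattern_set()].
#' @param target,state condition labels.
#' @return 3D numeric array.
#' @export
condition_volume <- function(ps, target, state) {
  stopifnot(inherits(ps, "pattern_set"))
  j <- which(ps$conditions$target == target & ps$conditions$state == state)
  if (length(j) != 1) stop("no such condition: ", target, ":", state)
  array(ps$data[, j], dim = ps$dims)
}
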