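#' Canonical double-gamma hemodynamic response function
#'
#' The de-facto standard impulse response: a gamma density peaking at
#' `peak` seconds minus a later gamma undershoot scaled by `1/ratio`,
#' normalized to unit peak height.
#'
#' @param t time in seconds (vector).
#' @param peak time-to-peak parameter (gamma shape, dispersion 1), seconds.
#' @param undershoot undershoot shape parameter, seconds.
#' @param dispersion,u_dispersion dispersions (gamma scale) of response and
#'   undershoot.
#' @param ratio peak-to-undershoot amplitude ratio.
#' @return Numeric vector of HRF values at `t`.
#' @export
hrf_double_gamma <- function(t, peak = 6, undershoot = 16, dispersion = 1,
                             u_dispersion = 1, ratio = 6) {
  h <- dgamma(t, shape = peak / dispersion, scale = dispersion) -
    dgamma(t, shape = undershoot / u_dispersion, scale = u_dispersion) / ratio
  h[t < 0] <- 0
  pk <- max(h)
  if (pk > 0) h / pk else h
}

#' Build a first-level design matrix
#'
#' One HRF-convolved boxcar regressor per (target, state) condition, shared
#' across runs, plus per-run intercept and centered linear-trend nuisance
#' columns and any supplied motion regressors (centered per run). Boxcars
#' are built on a fine time grid, convolved with the canonical double-gamma
#' response, and sampled at frame-acquisition times.
#'
#' @param events data frame with columns `run`, `onset`, `duration`,
#'   `target`, `state` (seconds; onsets relative to run start).
#' @param TR repetition time in seconds.
#' @param n_TRs frames per run: scalar or one value per run.
#' @param motion optional numeric matrix (total frames x parameters) of
#'   motion covariates, row-bound across runs.
#' @param dt fine-grid resolution for convolution, seconds.
#' @param hrf_length HRF support in seconds.
#' @return An object of class `design_matrix`: list with `X` (frames x
#'   regressors), `labels`, `condition_cols`, `nuisance_cols`, `TR`, `run`
#'   (frame-to-run index).
#' @export
build_design_matrix <- function(events, TR, n_TRs, motion = NULL, dt = 0.1,
                                hrf_length = 32) {
  need <- c("run", "onset", "duration", "target", "state")
  if (!all(need %in% names(events)))
    stop("events must have columns: ", paste(need, collapse = ", "))
  runs <- if (nrow(events) > 0) sort(unique(events$run))
          else seq_along(n_TRs)   # nuisance-only design
  if (length(n_TRs) == 1) n_TRs <- rep(n_TRs, length(runs))
  if (length(n_TRs) != length(runs))
    stop("n_TRs must be scalar or one value per run")
  if (any(events$onset < 0)) stop("event onsets must be nonnegative")
  if (anyDuplicated(events[, c("run", "onset")]))
    stop("duplicate (run, onset) events")

  cond <- unique(events[, c("target", "state")])
  cond <- cond[order(cond$target, cond$state), , drop = FALSE]
  clab <- paste(cond$target, cond$state, sep = ":")
  hrf_t <- seq(0, hrf_length, by = dt)
  hrf <- hrf_double_gamma(hrf_t)

  blocks <- vector("list", length(runs))
  for (ri in seq_along(runs)) {
    nT <- n_TRs[ri]
    run_len <- nT * TR
    ev <- events[events$run == runs[ri], , drop = FALSE]
    if (nrow(ev) > 0 && any(ev$onset + ev$duration > run_len + 1e-9))
      stop("event extends past the end of run ", runs[ri])
    n_fine <- ceiling(run_len / dt)
    Xr <- matrix(0, nT, length(clab))
    for (ci in seq_along(clab)) {
      sel <- ev$target == cond$target[ci] & ev$state == cond$state[ci]
      if (!any(sel)) next
      box <- numeric(n_fine)
      for (k in which(sel)) {
        i0 <- floor(ev$onset[k] / dt) + 1
        i1 <- min(n_fine, ceiling((ev$onset[k] + ev$duration[k]) / dt))
        box[i0:i1] <- 1
      }
      conv <- convolve(box, rev(hrf), type = "open")[seq_len(n_fine)] * dt
      frame_idx <- pmin(n_fine, floor((seq_len(nT) - 1) * TR / dt) + 1)
      Xr[, ci] <- conv[frame_idx]
    }
    blocks[[ri]] <- Xr
  }
  Xc <- do.call(rbind, blocks)
  total <- sum(n_TRs)
  run_idx <- rep(seq_along(runs), n_TRs)

  # per-run intercept + centered linear trend
  nuis <- NULL
  nlab <- character()
  for (ri in seq_along(runs)) {
    ind <- as.numeric(run_idx == ri)
    tr_line <- ind * scale(seq_len(total), center = TRUE, scale = FALSE)
    tr_line[run_idx != ri] <- 0
    tr_line <- tr_line - ind * mean(tr_line[run_idx == ri])
    nuis <- cbind(nuis, ind, tr_line)
    nlab <- c(nlab, sprintf("run%02d_mean", runs[ri]),
              sprintf("run%02d_trend", runs[ri]))
  }
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    if (nrow(motion) != total)
      stop("motion must have one row per frame (", total, ")")
    for (ri in seq_along(runs)) {
      sel <- run_idx == ri
      motion[sel, ] <- scale(motion[sel, , drop = FALSE], center = TRUE,
                             scale = FALSE)
    }
    colnames(motion) <- colnames(motion) %||%
      sprintf("motion%02d", seq_len(ncol(motion)))
    nuis <- cbind(nuis, motion)
    nlab <- c(nlab, colnames(motion))
  }

  X <- cbind(Xc, nuis)
  labels <- c(clab, nlab)
  if (anyDuplicated(labels))
    stop("duplicate regressor labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  colnames(X) <- labels
  structure(list(X = X, labels = labels,
                 condition_cols = seq_along(clab),
                 nuisance_cols = length(clab) + seq_along(nlab),
                 TR = TR, run = run_idx,
                 conditions = cbind(cond, label = clab)),
            class = "design_matrix")
}

#' @exportS3Method print design_matrix
print.design_matrix <- function(x, ...) {
  cat(sprintf("<design_matrix> %d frames x %d regressors (%d condition, %d nuisance), TR = %gs\n",
              nrow(x$X), ncol(x$X), length(x$condition_cols),
              length(x$nuisance_cols), x$TR))
  invisible(x)
}

#' Fit a voxelwise ordinary least-squares GLM
#'
#' Estimates betas for every regressor at every voxel and returns the
#' condition betas as a [pattern_set()]. Rank deficiency is reported as an
#' error naming the collinear columns.
#'
#' @param series numeric matrix (frames x voxels) or 4D array (x, y, z,
#'   frames).
#' @param design a [build_design_matrix()] result.
#' @param dims voxel grid shape; taken from `series` when it is a 4D array
#'   or carries a `dims` attribute.
#' @param mask optional logical array; out-of-mask voxels get NA betas.
#' @param voxel_size_mm,subject metadata passed to the pattern set.
#' @return A [pattern_set()] of condition betas, with the full coefficient
#'   matrix in attribute `all_betas`.
#' @export
fit_glm <- function(series, design, dims = NULL, mask = NULL,
                    voxel_size_mm = 2, subject = "s01") {
  stopifnot(inherits(design, "design_matrix"))
  if (is.array(series) && length(dim(series)) == 4) {
    dims <- dim(series)[1:3]
    series <- t(matrix(series, nrow = prod(dims)))
  }
  dims <- dims %||% attr(series, "dims")
  series <- as.matrix(series)
  if (is.null(dims)) dims <- c(ncol(series), 1L, 1L)
  X <- design$X
  if (nrow(series) != nrow(X))
    stop("series length (", nrow(series), ") != design rows (", nrow(X), ")")
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- design$labels[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  B <- qr.coef(qr_x, series)            # K x V
  if (!is.null(mask)) B[, !as.vector(mask)] <- NA_real_
  cond_b <- t(B[design$condition_cols, , drop = FALSE])  # V x C
  ps <- pattern_set(cond_b, targets = design$conditions$target,
                    states = design$conditions$state, dims = dims,
                    voxel_size_mm = voxel_size_mm, subject = subject)
  attr(ps, "all_betas") <- B
  ps
}

#' Correlation structure among condition estimators implied by a design
#'
#' The covariance of OLS condition-beta estimators is proportional to the
#' condition block of `(X'X)^-1`; this returns that block as a correlation
#' matrix. Blocked trial designs induce nonzero estimator correlations that
#' leak into pattern similarity and can be removed downstream with
#' [correct_block_structure()].
#'
#' @param design a [build_design_matrix()] result with >= 2 condition
#'   columns.
#' @return Symmetric unit-diagonal correlation matrix over conditions.
#' @export
design_induced_similarity <- function(design) {
  stopifnot(inherits(design, "design_matrix"))
  if (length(design$condition_cols) < 2)
    stop("need at least 2 condition columns")
  XtX <- crossprod(design$X)
  inv <- tryCatch(solve(XtX), error = function(e)
    stop("X'X is singular; design columns are collinear"))
  cc <- inv[design$condition_cols, design$condition_cols, drop = FALSE]
  out <- stats::cov2cor(cc)
  dimnames(out) <- list(design$conditions$label, design$conditions$label)
  out
}
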