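# mirror (half-sample reflection) index for positions outside 1..n
reflect_idx <- function(i, n) {
  per <- 2L * n
  j <- ((i - 1L) %% per + per) %% per  # 0 .. 2n-1
  ifelse(j < n, j + 1L, per - j)
}

smooth_axis <- function(vol, axis, w, boundary) {
  R <- (length(w) - 1L) / 2L
  n <- dim(vol)[axis]
  out <- array(0, dim = dim(vol))
  for (k in -R:R) {
    idx <- seq_len(n) + k
    idx <- switch(boundary,
                  reflect = reflect_idx(idx, n),
                  periodic = ((idx - 1L) %% n) + 1L)
    shifted <- switch(axis,
                      vol[idx, , , drop = FALSE],
                      vol[, idx, , drop = FALSE],
                      vol[, , idx, drop = FALSE])
    out <- out + w[k + R + 1L] * shifted
  }
  out
}

#' Gaussian spatial smoothing of a volume
#'
#' Separable Gaussian smoothing with `sigma = fwhm / (2 sqrt(2 ln 2))`
#' converted to voxel units per axis. Boundaries are handled by mirror
#' reflection (default) or periodic wrap-around; both conserve the
#' volume's total mass for the symmetric kernel used here.
#'
#' Undefined (NA) voxels -- e.g. skipped searchlight centers -- are handled
#' by normalized convolution: values and the defined-voxel indicator are
#' smoothed with the same kernel and their ratio taken, so defined voxels
#' never bleed NA; NA positions stay NA in the output.
#'
#' @param volume numeric 3D array.
#' @param fwhm_mm full width at half maximum in mm (0 = identity).
#' @param voxel_size_mm voxel edge lengths (scalar or length 3).
#' @param boundary `"reflect"` or `"periodic"`.
#' @return Smoothed array of the same shape.
#' @export
smooth_map <- function(volume, fwhm_mm, voxel_size_mm = 2,
                       boundary = c("reflect", "periodic")) {
  boundary <- match.arg(boundary)
  if (fwhm_mm < 0) stop("fwhm must be nonnegative")
  if (fwhm_mm == 0) return(volume)
  if (length(voxel_size_mm) == 1) voxel_size_mm <- rep(voxel_size_mm, 3)
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size_mm
  pass <- function(vol) {
    for (ax in 1:3) {
      s <- sigma_vox[ax]
      if (s == 0) next
      R <- max(1L, ceiling(3.5 * s))
      w <- dnorm(-R:R, sd = s)
      vol <- smooth_axis(vol, ax, w / sum(w), boundary)
    }
    vol
  }
  na <- is.na(volume)
  if (!any(na)) return(pass(volume))
  v0 <- volume
  v0[na] <- 0
  out <- pass(v0) / pass(array(as.numeric(!na), dim = dim(volume)))
  out[na] <- NA_real_
  out
}

# stack a list of 3D arrays into subjects x voxels
stack_maps <- function(maps) {
  if (is.matrix(maps)) return(maps)
  do.call(rbind, lapply(maps, as.vector))
}

#' Voxelwise paired t-test map
#'
#' @param maps_a,maps_b per-subject volumes (lists of 3D arrays, or
#'   subjects x voxels matrices) for the two conditions, same subjects in
#'   the same order.
#' @return Object of class `stat_map`: list with `values` (3D array or
#'   vector of t), `kind = "t"`, `df = n - 1`, `n_undefined` (voxels with
#'   zero-variance differences, returned as NA).
#' @export
paired_t_map <- function(maps_a, maps_b) {
  dims <- if (!is.matrix(maps_a)) dim(maps_a[[1]])
  A <- stack_maps(maps_a); B <- stack_maps(maps_b)
  if (!identical(dim(A), dim(B)))
    stop("map sets differ in subjects or geometry")
  n <- nrow(A)
  if (n < 2) stop("need at least 2 subjects")
  D <- A - B
  m <- colMeans(D)
  s <- sqrt(colSums(sweep(D, 2, m)^2) / (n - 1))
  t <- ifelse(s > 0, m / (s / sqrt(n)), NA_real_)
  vals <- if (is.null(dims)) t else array(t, dim = dims)
  structure(list(values = vals, kind = "t", df = n - 1,
                 n_undefined = sum(s == 0 | is.na(s))),
            class = "stat_map")
}

#' Voxelwise one-way repeated-measures ANOVA map
#'
#' Within-subject F for a single factor (target) with `k` levels measured
#' on the same subjects, `df = (k - 1, (k - 1)(n - 1))`.
#'
#' @param maps_by_target named list (one element per target level) of
#'   per-subject volumes as in [paired_t_map()].
#' @return A `stat_map` with `kind = "F"`.
#' @export
repeated_anova_map <- function(maps_by_target) {
  k <- length(maps_by_target)
  if (k < 2) stop("need at least 2 levels")
  dims <- if (!is.matrix(maps_by_target[[1]])) dim(maps_by_target[[1]][[1]])
  X <- lapply(maps_by_target, stack_maps)  # each n x V
  n <- nrow(X[[1]])
  V <- ncol(X[[1]])
  grand <- Reduce(`+`, X) / k                    # n x V subject means
  mt <- t(vapply(X, colMeans, numeric(V)))       # k x V target means
  gm <- colMeans(grand)                          # V grand means
  ss_t <- n * colSums(sweep(mt, 2, gm)^2)
  ss_e <- numeric(V)
  for (j in seq_len(k)) {
    resid <- sweep(X[[j]] - grand, 2, mt[j, ] - gm)
    ss_e <- ss_e + colSums(resid^2)
  }
  df1 <- k - 1
  df2 <- (k - 1) * (n - 1)
  Fv <- ifelse(ss_e > 0, (ss_t / df1) / (ss_e / df2), NA_real_)
  vals <- if (is.null(dims)) Fv else array(Fv, dim = dims)
  structure(list(values = vals, kind = "F", df = c(df1, df2),
                 n_undefined = sum(ss_e == 0)),
            class = "stat_map")
}

#' TFCE parameters
#'
#' Field-standard defaults: extent exponent `E = 0.5`, height exponent
#' `H = 2`, 26-voxel connectivity, and a step `dh` of 1/100 of the map
#' maximum when `dh = NULL`.
#'
#' @param E,H extent and height exponents (>= 0).
#' @param dh threshold step (> 0), or `NULL` to use `max(|stat|)/100`.
#' @param connectivity 6, 18 or 26.
#' @return A `tfce_params` list.
#' @export
tfce_params <- function(E = 0.5, H = 2, dh = NULL, connectivity = 26) {
  stopifnot(E >= 0, H >= 0, is.null(dh) || dh > 0,
            connectivity %in% c(6, 18, 26))
  structure(list(E = E, H = H, dh = dh, connectivity = connectivity),
            class = "tfce_params")
}

tfce_one_tail <- function(stat_vec, dims, params, dh) {
  n_steps <- max(1L, ceiling(max(stat_vec) / dh))
  tfce_cpp(stat_vec, as.integer(dims), params$E, params$H, dh, n_steps,
           as.integer(params$connectivity))
}

#' Threshold-free cluster enhancement
#'
#' Integrates cluster extent and height over all thresholds:
#' `TFCE(v) = sum_h e_h(v)^E * h^H * dh`, where `e_h(v)` is the size of the
#' suprathreshold connected component containing `v`. Negative statistics
#' are enhanced separately on the negated map and returned with negative
#' sign, so the output is signed. NA values (and out-of-mask voxels) are
#' treated as zero.
#'
#' @param stat a `stat_map` or a 3D numeric array.
#' @param params a [tfce_params()].
#' @param mask optional logical array.
#' @return Signed enhanced 3D array.
#' @export
tfce_enhance <- function(stat, params = tfce_params(), mask = NULL) {
  vol <- if (inherits(stat, "stat_map")) stat$values else stat
  dims <- dim(vol)
  v <- as.vector(vol)
  v[is.na(v)] <- 0
  if (!is.null(mask)) v[!as.vector(mask)] <- 0
  mx <- max(abs(v))
  if (mx == 0) return(array(0, dim = dims))
  dh <- params$dh %||% (mx / 100)
  pos <- tfce_one_tail(pmax(v, 0), dims, params, dh)
  out <- pos
  if (any(v < 0)) out <- out - tfce_one_tail(pmax(-v, 0), dims, params, dh)
  array(out, dim = dims)
}

#' Permutation scheme
#'
#' @param n_perms number of permutations (the identity is always the
#'   first).
#' @param seed integer seed for the permutation draws.
#' @param type `"sign-flip"` (paired differences) or `"target-relabel"`
#'   (within-subject shuffles of target labels, for the ANOVA).
#' @return A `perm_scheme` list.
#' @export
perm_scheme <- function(n_perms = 5000, seed = 1L,
                        type = c("sign-flip", "target-relabel")) {
  stopifnot(n_perms >= 1)
  structure(list(n_perms = as.integer(n_perms), seed = as.integer(seed),
                 type = match.arg(type)),
            class = "perm_scheme")
}

# t statistics for every row of a sign matrix S (P x n) applied to D (n x V)
sign_flip_t <- function(S, D, SS) {
  n <- ncol(S)
  m <- (S %*% D) / n
  vr <- sweep(-n * m^2, 2, SS, `+`) / (n - 1)
  t <- m / sqrt(vr / n)
  t[!is.finite(t)] <- 0
  t
}

#' Maximal-statistic permutation FWE correction with TFCE
#'
#' Compares the observed TFCE-enhanced map against the permutation
#' distribution of the image-wide maximum enhanced statistic. For the
#' paired-t contrast the null is generated by per-subject sign flips of the
#' difference maps; for the ANOVA, by independent within-subject
#' permutations of the target labels. Two-sided paired tests enhance the
#' positive and negative tails separately and Bonferroni-combine them.
#' Corrected p values are `#\{perm max >= observed\} / n_perms` with the
#' identity permutation always included, so the smallest attainable p is
#' `1 / n_perms`.
#'
#' @param maps_by_target named list, one element per target, each a list of
#'   per-subject 3D arrays (or an n x V matrix). Paired-t uses exactly two
#'   targets (first minus second).
#' @param contrast `"paired-t"` or `"anova"`.
#' @param tfce a [tfce_params()]; `dh` is fixed from the observed map and
#'   reused for all permutations.
#' @param scheme a [perm_scheme()]. If the number of distinct sign flips
#'   `2^n` is at most `n_perms`, they are enumerated exhaustively (with a
#'   warning).
#' @param mask optional logical array.
#' @param two_sided two-sided inference for the paired-t contrast?
#' @return Object of class `corrected_p_map`: list with `p` (FWE-corrected
#'   p array), `stat` (observed `stat_map`), `enhanced`, `max_dist`
#'   (permutation maxima), `scheme`, `n_perms`.
#' @export
permutation_fwe <- function(maps_by_target,
                            contrast = c("paired-t", "anova"),
                            tfce = tfce_params(), scheme = perm_scheme(),
                            mask = NULL, two_sided = TRUE) {
  contrast <- match.arg(contrast)
  if (contrast == "paired-t") {
    if (length(maps_by_target) != 2)
      stop("paired-t contrast needs exactly two targets")
    A <- stack_maps(maps_by_target[[1]])
    B <- stack_maps(maps_by_target[[2]])
    dims <- if (!is.matrix(maps_by_target[[1]]))
      dim(maps_by_target[[1]][[1]]) else c(ncol(A), 1L, 1L)
    D <- A - B
    n <- nrow(D)
    keep <- !is.na(colSums(D))
    if (!is.null(mask)) keep <- keep & as.vector(mask)
    D[, !keep] <- 0
    SS <- colSums(D^2)

    n_perms <- scheme$n_perms
    exhaustive <- 2^n <= n_perms
    if (exhaustive) {
      if (2^n < n_perms)
        warning("requested ", n_perms, " permutations but only ", 2^n,
                " distinct sign flips exist; enumerating exhaustively")
      n_perms <- 2^n
      S <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
      # put the identity first
      id <- which(rowSums(S) == n)[1]
      S <- rbind(S[id, ], S[-id, ])
    } else {
      S <- with_seed(scheme$seed,
                     matrix(sample(c(-1, 1), n_perms * n, replace = TRUE),
                            n_perms, n))
      S[1, ] <- 1
    }

    obs <- sign_flip_t(S[1, , drop = FALSE], D, SS)[1, ]
    mx <- max(abs(obs[keep]), 0)
    dh <- tfce$dh %||% (if (mx > 0) mx / 100 else 1)
    tf <- tfce_params(tfce$E, tfce$H, dh, tfce$connectivity)

    enh <- function(tvec, sign) {
      v <- if (sign > 0) pmax(tvec, 0) else pmax(-tvec, 0)
      v[!keep] <- 0
      if (max(v) == 0) numeric(length(v))
      else tfce_one_tail(v, dims, tf, dh)
    }
    obs_pos <- enh(obs, 1)
    obs_neg <- if (two_sided) enh(obs, -1) else NULL
    max_pos <- numeric(n_perms)
    max_neg <- numeric(n_perms)
    block <- 64L
    for (b in seq(1, n_perms, by = block)) {
      rows <- b:min(n_perms, b + block - 1L)
      tmat <- sign_flip_t(S[rows, , drop = FALSE], D, SS)
      for (i in seq_along(rows)) {
        max_pos[rows[i]] <- max(enh(tmat[i, ], 1))
        if (two_sided) max_neg[rows[i]] <- max(enh(tmat[i, ], -1))
      }
    }
    p_pos <- vapply(obs_pos, function(o) mean(max_pos >= o), 1.0)
    if (two_sided) {
      p_neg <- vapply(obs_neg, function(o) mean(max_neg >= o), 1.0)
      p <- pmin(1, 2 * pmin(p_pos, p_neg))
    } else p <- p_pos
    p[!keep] <- NA_real_
    tvals <- obs
    tvals[!keep] <- NA_real_
    stat <- structure(list(values = array(tvals, dims), kind = "t",
                           df = n - 1), class = "stat_map")
    enhanced <- array(obs_pos - (if (two_sided) obs_neg else 0), dims)
    structure(list(p = array(p, dims), stat = stat, enhanced = enhanced,
                   max_dist = if (two_sided) pmax(max_pos, max_neg)
                              else max_pos,
                   scheme = scheme, n_perms = n_perms,
                   exhaustive = exhaustive),
              class = "corrected_p_map")
  } else {
    k <- length(maps_by_target)
    if (k < 2) stop("anova contrast needs >= 2 targets")
    X <- lapply(maps_by_target, stack_maps)
    dims <- if (!is.matrix(maps_by_target[[1]]))
      dim(maps_by_target[[1]][[1]]) else c(ncol(X[[1]]), 1L, 1L)
    n <- nrow(X[[1]])
    keep <- Reduce(`&`, lapply(X, function(m) !is.na(colSums(m))))
    if (!is.null(mask)) keep <- keep & as.vector(mask)
    X <- lapply(X, function(m) { m[, !keep] <- 0; m })

    f_of <- function(Xl) {
      sm <- repeated_anova_map(Xl)
      v <- as.vector(sm$values)
      v[!is.finite(v)] <- 0
      v
    }
    obs <- f_of(X)
    mx <- max(obs[keep], 0)
    dh <- tfce$dh %||% (if (mx > 0) mx / 100 else 1)
    tf <- tfce_params(tfce$E, tfce$H, dh, tfce$connectivity)
    enh <- function(fvec) {
      v <- pmax(fvec, 0)
      v[!keep] <- 0
      if (max(v) == 0) numeric(length(v))
      else tfce_one_tail(v, dims, tf, dh)
    }
    obs_enh <- enh(obs)
    n_perms <- scheme$n_perms
    max_dist <- numeric(n_perms)
    max_dist[1] <- max(obs_enh)
    with_seed(scheme$seed, {
      arr <- array(unlist(X), dim = c(n, ncol(X[[1]]), k))  # n x V x k
      for (pidx in seq.int(2, length.out = n_perms - 1)) {
        Xp <- vector("list", k)
        perm <- t(vapply(seq_len(n), function(s) sample(k), integer(k)))
        for (j in seq_len(k)) {
          Xj <- matrix(0, n, ncol(X[[1]]))
          for (s in seq_len(n)) Xj[s, ] <- arr[s, , perm[s, j]]
          Xp[[j]] <- Xj
        }
        max_dist[pidx] <- max(enh(f_of(Xp)))
      }
    })
    p <- vapply(obs_enh, function(o) mean(max_dist >= o), 1.0)
    p[!keep] <- NA_real_
    fvals <- obs
    fvals[!keep] <- NA_real_
    stat <- structure(list(values = array(fvals, dims), kind = "F",
                           df = c(k - 1, (k - 1) * (n - 1))),
                      class = "stat_map")
    structure(list(p = array(p, dims), stat = stat,
                   enhanced = array(obs_enh, dims), max_dist = max_dist,
                   scheme = scheme, n_perms = n_perms, exhaustive = FALSE),
              class = "corrected_p_map")
  }
}

#' Pairwise paired t-tests between targets with Cohen's d
#'
#' For every pair of targets, tests the within-subject difference in the
#' ROI distinctiveness scalar: paired t, Cohen's d (mean difference over SD
#' of differences), the mean difference of distances, its
#' mean-correlation form `delta_r` (difference in mean pattern correlation,
#' `r_bar = 1 - mean dissimilarity`), and raw plus Bonferroni-adjusted p.
#'
#' @param roi_scalars subjects x targets numeric matrix of mean
#'   within-target dissimilarities (column names = targets), or a data
#'   frame with `subject`, `target`, `mean_dissimilarity`.
#' @param bonferroni_m correction factor; defaults to the number of pairs.
#' @return Data frame, one row per target pair.
#' @export
pairwise_target_tests <- function(roi_scalars, bonferroni_m = NULL) {
  if (is.data.frame(roi_scalars)) {
    wide <- tapply(roi_scalars$mean_dissimilarity,
                   list(roi_scalars$subject, roi_scalars$target), mean)
    roi_scalars <- wide[, unique(roi_scalars$target), drop = FALSE]
  }
  tg <- colnames(roi_scalars)
  if (length(tg) < 2) stop("need at least 2 targets")
  pairs <- combn(tg, 2)
  m <- bonferroni_m %||% ncol(pairs)
  out <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    diff <- roi_scalars[, a] - roi_scalars[, b]
    sdd <- sd(diff)
    if (sdd == 0 && mean(diff) != 0)
      stop("zero-variance nonzero differences for ", a, " vs ", b,
           "; Cohen's d undefined")
    if (sdd == 0) {
      # all differences exactly zero: no evidence either way
      tstat <- 0; df <- length(diff) - 1; pval <- 1; dval <- 0
    } else {
      tt <- t.test(diff)
      tstat <- unname(tt$statistic); df <- unname(tt$parameter)
      pval <- tt$p.value; dval <- mean(diff) / sdd
    }
    data.frame(target_a = a, target_b = b,
               mean_diff = mean(diff), delta_r = -mean(diff),
               cohen_d = dval, t = tstat, df = df, p = pval,
               p_bonferroni = min(1, pval * m),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
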