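#' Generate a randomized trial design
#'
#' Builds the trial list for one participant: either all unordered pairs of
#' states for every target (the similarity-rating task) or one trial per
#' (target, state) per run (the scanner judgment task). Blocked designs group
#' trials by target within each run, with block order and within-block order
#' randomized; intermixed designs shuffle all trials within run.
#'
#' @param n_states number of mental states (>= 2), or a character vector of
#'   state labels.
#' @param targets character vector of target labels.
#' @param pairing `"pairs"` for all unordered state pairs per target,
#'   `"states"` for one trial per state per target per run.
#' @param blocked logical; group trials by target within run?
#' @param n_runs number of runs (trials are split evenly across runs).
#' @param seed integer seed for the per-participant randomization.
#' @return Data frame with columns `run`, `trial` (order within run),
#'   `target`, and either `state` or `state_i`/`state_j`.
#' @export
generate_trial_design <- function(n_states, targets,
                                  pairing = c("pairs", "states"),
                                  blocked = FALSE, n_runs = 1, seed = 1L) {
  pairing <- match.arg(pairing)
  states <- if (is.character(n_states)) n_states
            else sprintf("state%02d", seq_len(n_states))
  if (length(states) < 2) stop("invalid design: need at least 2 states")
  targets <- as.character(targets)
  if (length(targets) < 1) stop("invalid design: need at least one target")

  if (pairing == "pairs") {
    pr <- t(combn(states, 2))
    per_target <- data.frame(state_i = pr[, 1], state_j = pr[, 2],
                             stringsAsFactors = FALSE)
    rows <- do.call(rbind, lapply(targets, function(tg)
      cbind(target = tg, per_target, stringsAsFactors = FALSE)))
  } else {
    rows <- expand.grid(state = states, target = targets,
                        stringsAsFactors = FALSE)[, c("target", "state")]
    rows <- do.call(rbind, replicate(n_runs, rows, simplify = FALSE))
  }

  with_seed(seed, {
    if (pairing == "pairs") {
      # split each target's trials across runs, then order within run
      rows$run <- unlist(lapply(targets, function(tg) {
        n <- sum(rows$target == tg)
        sort(rep_len(seq_len(n_runs), n))
      }))
    } else {
      rows$run <- rep(seq_len(n_runs),
                      each = nrow(rows) / n_runs)
    }
    out <- do.call(rbind, lapply(seq_len(n_runs), function(r) {
      rr <- rows[rows$run == r, , drop = FALSE]
      if (blocked) {
        border <- sample(targets)
        rr <- do.call(rbind, lapply(border, function(tg) {
          b <- rr[rr$target == tg, , drop = FALSE]
          b[sample(nrow(b)), , drop = FALSE]
        }))
      } else {
        rr <- rr[sample(nrow(rr)), , drop = FALSE]
      }
      rr$trial <- seq_len(nrow(rr))
      rr
    }))
    rownames(out) <- NULL
    out[, c("run", "trial", "target",
            setdiff(names(out), c("run", "trial", "target")))]
  })
}

#' Assign onsets to a trial design
#'
#' Turns a trial list into an event table by laying trials out sequentially
#' within each run: each trial occupies `prompt_dur + stim_dur` seconds and
#' is followed by a jittered inter-trial interval drawn as
#' `iti_increment * min(Poisson(iti_mean / iti_increment), max_increments)`.
#'
#' @param design output of [generate_trial_design()] (must have a `state`
#'   column, i.e. a `pairing = "states"` design).
#' @param prompt_dur,stim_dur prompt and stimulus durations in seconds.
#' @param iti_mean mean jitter in seconds.
#' @param iti_increment jitter granularity in seconds.
#' @param max_increments cap on the number of jitter increments.
#' @param seed integer seed for the jitter draws.
#' @return The design with `onset` and `duration` columns added (seconds).
#' @export
schedule_events <- function(design, prompt_dur = 0.75, stim_dur = 3.45,
                            iti_mean = 1.4, iti_increment = 1.4,
                            max_increments = 3, seed = 1L) {
  if (!"state" %in% names(design))
    stop("schedule_events needs a pairing = 'states' design")
  trial_dur <- prompt_dur + stim_dur
  with_seed(seed, {
    out <- do.call(rbind, lapply(split(design, design$run), function(rr) {
      rr <- rr[order(rr$trial), , drop = FALSE]
      jit <- iti_increment *
        pmin(rpois(nrow(rr), iti_mean / iti_increment), max_increments)
      gaps <- c(0, head(trial_dur + jit, -1))
      rr$onset <- cumsum(gaps)
      rr$duration <- trial_dur
      rr
    }))
    rownames(out) <- NULL
    out
  })
}

#' Simulate condition-wise beta patterns for one subject
#'
#' Draws one beta volume per (target, state) under the shared-geometry
#' dispersion model of [sim_config()]: each target has a mean pattern and
#' each state a latent direction shared across targets; the state direction
#' is scaled by the target's dispersion inside the effect region and by the
#' common baseline dispersion outside, then i.i.d. Gaussian noise is added.
#' The subject's stream is derived deterministically from the master seed,
#' so identical (config, subject_id) calls agree bit-for-bit.
#'
#' @param config a [sim_config()].
#' @param subject_id integer subject index (1-based).
#' @return A [pattern_set()] with conditions ordered target-major.
#' @export
simulate_subject_betas <- function(config, subject_id = 1L) {
  stopifnot(inherits(config, "sim_config"))
  V <- prod(config$grid_shape)
  inreg <- as.vector(config$effect_region)
  tg <- config$targets
  st <- sprintf("state%02d", seq_len(config$n_states))
  with_seed(derive_seed(config$seed, subject_id), {
    mean_pat <- matrix(rnorm(V * length(tg), sd = config$mean_sd), V)
    state_dir <- matrix(rnorm(V * length(st)), V)
    cols <- vector("list", length(tg) * length(st))
    k <- 0
    for (i in seq_along(tg)) {
      scale_vec <- ifelse(inreg, config$dispersion_by_target[[tg[i]]],
                          config$baseline_dispersion)
      for (j in seq_along(st)) {
        k <- k + 1
        cols[[k]] <- mean_pat[, i] + scale_vec * state_dir[, j] +
          rnorm(V, sd = config$noise_sd)
      }
    }
    pattern_set(do.call(cbind, cols),
                targets = rep(tg, each = length(st)),
                states = rep(st, times = length(tg)),
                dims = config$grid_shape,
                voxel_size_mm = config$voxel_size_mm,
                subject = sprintf("s%02d", subject_id))
  })
}

#' Simulate a full dataset of subject pattern sets
#'
#' @param config a [sim_config()].
#' @return List of [pattern_set()]s, one per subject.
#' @export
simulate_dataset <- function(config) {
  lapply(seq_len(config$n_subjects),
         function(s) simulate_subject_betas(config, s))
}

#' Simulate a BOLD-like series from a design matrix and true betas
#'
#' Produces `Y = X B + E` voxelwise, where the condition columns of the
#' design are matched by label to the conditions of the pattern set,
#' nuisance columns carry zero weight, and `E` is white Gaussian noise.
#'
#' @param design a [build_design_matrix()] result.
#' @param true_betas a [pattern_set()] whose condition labels match the
#'   design's condition columns.
#' @param noise_sd white-noise standard deviation.
#' @param seed integer seed.
#' @return Numeric matrix (time points x voxels) with attribute `dims`.
#' @export
simulate_bold <- function(design, true_betas, noise_sd = 0, seed = 1L) {
  stopifnot(inherits(design, "design_matrix"),
            inherits(true_betas, "pattern_set"))
  lab <- design$labels[design$condition_cols]
  if (!setequal(lab, true_betas$conditions$label) ||
      length(lab) != ncol(true_betas$data))
    stop("design condition columns do not match pattern-set conditions")
  B <- true_betas$data[, lab, drop = FALSE]   # V x C, design order
  X <- design$X[, design$condition_cols, drop = FALSE]
  Y <- X %*% t(B)
  if (noise_sd > 0)
    Y <- Y + with_seed(seed, matrix(rnorm(length(Y), sd = noise_sd),
                                    nrow(Y)))
  attr(Y, "dims") <- true_betas$dims
  Y
}

#' Simulate pairwise state-similarity ratings
#'
#' One rating per (participant, target, unordered state pair) under the
#' random-intercept/random-slope generative model of [rating_sim_config()].
#' Ratings are continuous by default; `discretize = TRUE` rounds and clips
#' to the integer rating scale (which attenuates the planted fixed effect).
#'
#' @param config a [rating_sim_config()].
#' @param discretize round and clip to the integer scale?
#' @return Data frame with columns `participant`, `target`, `target_code`,
#'   `state_i`, `state_j`, `pair`, `rating`.
#' @export
simulate_ratings <- function(config, discretize = FALSE) {
  stopifnot(inherits(config, "rating_sim_config"))
  st <- sprintf("state%02d", seq_len(config$n_states))
  pr <- t(combn(st, 2))
  pairs <- paste(pr[, 1], pr[, 2], sep = "-")
  tg <- config$targets
  with_seed(config$seed, {
    a_part <- rnorm(config$n_participants, sd = config$sd_participant_intercept)
    s_part <- rnorm(config$n_participants, sd = config$sd_participant_slope)
    a_pair <- rnorm(length(pairs), sd = config$sd_pair_intercept)
    s_pair <- rnorm(length(pairs), sd = config$sd_pair_slope)
    out <- expand.grid(pair_idx = seq_along(pairs), target = tg,
                       participant = seq_len(config$n_participants),
                       stringsAsFactors = FALSE)
    code <- as.numeric(out$target != tg[1])
    mu <- config$grand_mean + config$fixed_target_effect * code +
      a_part[out$participant] + s_part[out$participant] * code +
      a_pair[out$pair_idx] + s_pair[out$pair_idx] * code
    rating <- mu + rnorm(nrow(out), sd = config$sd_residual)
    if (discretize)
      rating <- pmin(pmax(round(rating), config$rating_scale[1]),
                     config$rating_scale[2])
    data.frame(participant = sprintf("p%03d", out$participant),
               target = out$target, target_code = code,
               state_i = pr[out$pair_idx, 1], state_j = pr[out$pair_idx, 2],
               pair = pairs[out$pair_idx], rating = rating,
               stringsAsFactors = FALSE)
  })
}
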