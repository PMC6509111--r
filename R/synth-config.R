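#' Simulation configuration for synthetic neural data
#'
#' Defines the generative model for per-subject condition patterns. Each
#' mental state has a latent pattern direction shared across targets; inside
#' the designated effect region that direction is scaled by a per-target
#' dispersion, so targets with larger dispersion have more differentiated
#' (more distinct) state patterns. Outside the region every target uses the
#' common baseline dispersion, so no target effect exists there. White
#' measurement noise is added everywhere.
#'
#' Defaults emulate the planted-effect study conditions used throughout the
#' validation suite: 20 subjects, a 12x12x12 grid of 2 mm voxels, three
#' targets at increasing social distance (self, close, far) with dispersions
#' 1.0, 0.6, 0.2, and a central spherical effect region.
#'
#' @param n_subjects number of subjects.
#' @param grid_shape integer(3) voxel counts.
#' @param voxel_size_mm voxel edge length in mm.
#' @param targets ordered target labels (closest first).
#' @param n_states number of mental states per target (>= 2).
#' @param effect_region logical array (grid_shape) marking the voxels where
#'   the per-target dispersions apply; `NULL` for a central sphere of radius
#'   3 voxels.
#' @param dispersion_by_target named nonnegative numeric, one entry per
#'   target: within-target pattern spread inside the effect region.
#' @param baseline_dispersion nonnegative scalar spread outside the region,
#'   identical for all targets.
#' @param noise_sd standard deviation of i.i.d. measurement noise.
#' @param mean_sd standard deviation of the shared per-target mean pattern.
#' @param seed master integer seed; per-subject streams are derived from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_subjects = 20,
                       grid_shape = c(12, 12, 12),
                       voxel_size_mm = 2,
                       targets = c("self", "close", "far"),
                       n_states = 8,
                       effect_region = NULL,
                       dispersion_by_target = c(self = 1.0, close = 0.6,
                                                far = 0.2),
                       baseline_dispersion = 0.2,
                       noise_sd = 0.5,
                       mean_sd = 1,
                       seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 1))
  targets <- as.character(targets)
  if (length(targets) < 1 || anyDuplicated(targets))
    stop("targets must be nonempty and unique")
  if (n_states < 2) stop("need at least 2 states")
  if (is.null(effect_region))
    effect_region <- effect_region_sphere(grid_shape, radius = 3)
  effect_region <- array(as.logical(effect_region), dim = grid_shape)
  dispersion_by_target <- dispersion_by_target[targets]
  if (anyNA(dispersion_by_target))
    stop("dispersion_by_target must name every target")
  if (any(dispersion_by_target < 0) || baseline_dispersion < 0 ||
      noise_sd < 0)
    stop("dispersions and noise_sd must be nonnegative")
  if (!any(effect_region) &&
      length(unique(dispersion_by_target)) > 1)
    stop("empty effect_region but target-specific dispersions requested")
  structure(list(
    n_subjects = as.integer(n_subjects), grid_shape = grid_shape,
    voxel_size_mm = voxel_size_mm, targets = targets,
    n_states = as.integer(n_states), effect_region = effect_region,
    dispersion_by_target = dispersion_by_target,
    baseline_dispersion = baseline_dispersion, noise_sd = noise_sd,
    mean_sd = mean_sd, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Spherical voxel region
#'
#' @param grid_shape integer(3).
#' @param center voxel coordinates (1-based); default grid center.
#' @param radius radius in voxel units.
#' @return Logical array of shape `grid_shape`.
#' @export
effect_region_sphere <- function(grid_shape, center = NULL, radius = 3) {
  grid_shape <- as.integer(grid_shape)
  if (is.null(center)) center <- (grid_shape + 1) / 2
  g <- expand.grid(x = seq_len(grid_shape[1]), y = seq_len(grid_shape[2]),
                   z = seq_len(grid_shape[3]))
  d2 <- (g$x - center[1])^2 + (g$y - center[2])^2 + (g$z - center[3])^2
  array(d2 <= radius^2, dim = grid_shape)
}

#' Simulation configuration for synthetic similarity ratings
#'
#' Generative mirror of the mixed-effects model used for the behavioral
#' analyses: rating = grand mean + b * target code + participant and
#' state-pair random intercepts + participant and state-pair random slopes
#' on the target code + residual. The target code is 0 for the first
#' (socially closest) target and 1 for all others, so `fixed_target_effect`
#' is the increase in rated state similarity for more distant targets.
#'
#' Defaults are the three-target study conditions (46 participants, 15
#' states, b = 0.15); variance components are set so that random effects
#' plus residual reproduce a conditional R-squared near 0.4.
#'
#' @param n_participants number of raters.
#' @param n_states number of mental states (all unordered pairs are rated).
#' @param targets target labels, closest first.
#' @param fixed_target_effect b, on the rating scale.
#' @param sd_participant_intercept,sd_pair_intercept,sd_participant_slope,sd_pair_slope,sd_residual
#'   nonnegative standard deviations of the random components.
#' @param grand_mean intercept on the rating scale.
#' @param rating_scale integer(2) (min, max) of the Likert scale.
#' @param seed integer seed.
#' @return A `rating_sim_config` list.
#' @export
rating_sim_config <- function(n_participants = 46, n_states = 15,
                              targets = c("self", "close", "far"),
                              fixed_target_effect = 0.15,
                              sd_participant_intercept = 0.55,
                              sd_pair_intercept = 0.55,
                              sd_participant_slope = 0.3,
                              sd_pair_slope = 0.15,
                              sd_residual = 1,
                              grand_mean = 3.5,
                              rating_scale = c(1L, 6L),
                              seed = 1L) {
  targets <- as.character(targets)
  if (length(targets) < 2 || anyDuplicated(targets))
    stop("need at least two distinct targets")
  if (n_states < 2) stop("need at least 2 states")
  sds <- c(sd_participant_intercept, sd_pair_intercept,
           sd_participant_slope, sd_pair_slope, sd_residual)
  if (any(sds < 0)) stop("standard deviations must be nonnegative")
  if (rating_scale[1] >= rating_scale[2])
    stop("rating_scale must be (min, max) with min < max")
  structure(list(
    n_participants = as.integer(n_participants),
    n_states = as.integer(n_states), targets = targets,
    fixed_target_effect = fixed_target_effect,
    sd_participant_intercept = sd_participant_intercept,
    sd_pair_intercept = sd_pair_intercept,
    sd_participant_slope = sd_participant_slope,
    sd_pair_slope = sd_pair_slope, sd_residual = sd_residual,
    grand_mean = grand_mean, rating_scale = as.integer(rating_scale),
    seed = as.integer(seed)
  ), class = "rating_sim_config")
}
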