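#' Write a pattern set as a NIfTI stack with a JSON sidecar
#'
#' The condition volumes go into a 4D NIfTI-1 file and the condition labels
#' (plus subject and grid metadata) into `<prefix>.json`, so the round trip
#' is lossless.
#'
#' @param ps a [pattern_set()].
#' @param prefix output path prefix (writes `<prefix>.nii.gz` and
#'   `<prefix>.json`).
#' @return The prefix, invisibly.
#' @export
write_pattern_set <- function(ps, prefix) {
  stopifnot(inherits(ps, "pattern_set"))
  arr <- array(ps$data, dim = c(ps$dims, ncol(ps$data)))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(ps$voxel_size_mm, 1)
  RNifti::writeNifti(img, paste0(prefix, ".nii.gz"))
  jsonlite::write_json(list(subject = ps$subject,
                            target = ps$conditions$target,
                            state = ps$conditions$state,
                            voxel_size_mm = ps$voxel_size_mm),
                       paste0(prefix, ".json"), auto_unbox = FALSE,
                       digits = NA)
  invisible(prefix)
}

#' Read a pattern set written by [write_pattern_set()]
#'
#' @param prefix path prefix used when writing.
#' @return A [pattern_set()].
#' @export
read_pattern_set <- function(prefix) {
  img <- RNifti::readNifti(paste0(prefix, ".nii.gz"))
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  arr <- as.array(img)
  if (length(dim(arr)) != 4) stop("expected a 4D condition stack")
  if (length(meta$target) != dim(arr)[4])
    stop("sidecar labels do not match the number of volumes")
  pattern_set(arr, targets = meta$target, states = meta$state,
              dims = dim(arr)[1:3],
              voxel_size_mm = meta$voxel_size_mm %||% 2,
              subject = meta$subject %||% "s01")
}

#' Assemble a pattern set from per-condition NIfTI files
#'
#' All volumes must share grid shape and affine; a mismatch in any file is
#' an error.
#'
#' @param files character vector of NIfTI paths, one per condition.
#' @param targets,states condition labels, parallel to `files`.
#' @param subject subject id.
#' @return A [pattern_set()].
#' @export
pattern_set_from_files <- function(files, targets, states,
                                   subject = "s01") {
  stopifnot(length(files) == length(targets),
            length(files) == length(states))
  imgs <- lapply(files, RNifti::readNifti)
  dims <- dim(imgs[[1]])
  affine <- RNifti::xform(imgs[[1]])
  for (i in seq_along(imgs)) {
    if (!identical(dim(imgs[[i]]), dims))
      stop("grid mismatch in ", files[i])
    if (max(abs(RNifti::xform(imgs[[i]]) - affine)) > 1e-6)
      stop("affine mismatch in ", files[i])
  }
  vox <- RNifti::pixdim(imgs[[1]])[1:3]
  pattern_set(do.call(cbind, lapply(imgs, as.vector)),
              targets = targets, states = states, dims = dims,
              voxel_size_mm = vox, subject = subject)
}

#' Write / read a BIDS-style events table (TSV)
#'
#' @param events data frame with at least `onset`, `duration`, `run`,
#'   `target`, `state`.
#' @param path file path.
#' @return `read_events` returns the data frame; `write_events` the path,
#'   invisibly.
#' @export
write_events <- function(events, path) {
  write.table(events, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Write / read a rating table (CSV)
#'
#' @param ratings data frame as produced by [simulate_ratings()].
#' @param path file path.
#' @export
write_ratings <- function(ratings, path) {
  write.csv(ratings, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ratings
#' @export
read_ratings <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Read a pipeline run configuration from YAML
#'
#' The YAML file mirrors the arguments of [sim_config()],
#' [rating_sim_config()] and the stage parameters of [run_pipeline()]
#' (searchlight radius, smoothing FWHM, TFCE settings, permutation scheme).
#'
#' @param path YAML file.
#' @return A named list of configuration sections.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}

#' Run the full synthetic analysis pipeline
#'
#' Executes, in order: simulate (subject pattern sets), optionally glm
#' (simulate BOLD from the betas and refit them), rsa (searchlight
#' distinctiveness + smoothing), infer (paired-t permutation FWE between
#' the first and last target, plus ROI pairwise tests), behavior (simulate
#' ratings and fit the mixed model), figure (per-target MDS embeddings
#' aligned to the first target). Every product is written under `out_dir`
#' and recorded in a JSON manifest with the seeds and parameters that
#' produced it.
#'
#' @param config list with sections `sim` ([sim_config()] arguments),
#'   `ratings` ([rating_sim_config()] arguments) and optional `rsa`
#'   (`radius_voxels`, `fwhm_mm`), `infer` (`n_perms`), `glm`
#'   (`enabled`, `TR`, `noise_sd`). See [read_run_config()].
#' @param out_dir output directory (created if needed).
#' @param stages subset of
#'   `c("simulate", "glm", "rsa", "infer", "behavior", "figure")`.
#' @param seed master seed overriding the config seeds.
#' @return The manifest (also written to `manifest.json`), invisibly.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("mindrsa_run"),
                         stages = c("simulate", "rsa", "infer", "behavior",
                                    "figure"),
                         seed = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim_args <- config$sim %||% list()
  rat_args <- config$ratings %||% list()
  if (!is.null(seed)) {
    sim_args$seed <- seed
    rat_args$seed <- derive_seed(seed, 2)
  }
  scfg <- do.call(sim_config, sim_args)
  radius <- config$rsa$radius_voxels %||% 4
  fwhm <- config$rsa$fwhm_mm %||% 6
  n_perms <- config$infer$n_perms %||% 500
  manifest <- list(package_version = as.character(utils::packageVersion("mindrsa")),
                   seed = scfg$seed, parameters = list(
                     radius_voxels = radius, fwhm_mm = fwhm,
                     n_perms = n_perms,
                     targets = scfg$targets, n_states = scfg$n_states,
                     n_subjects = scfg$n_subjects),
                   outputs = list())
  record <- function(name, path) {
    manifest$outputs[[name]] <<- list(
      path = path, md5 = unname(tools::md5sum(path)))
  }

  subjects <- NULL
  if ("simulate" %in% stages) {
    subjects <- simulate_dataset(scfg)
    p <- file.path(out_dir, "betas_s01")
    write_pattern_set(subjects[[1]], p)
    record("betas_s01", paste0(p, ".nii.gz"))
  }

  if ("glm" %in% stages && isTRUE(config$glm$enabled %||% TRUE)) {
    subjects <- subjects %||% simulate_dataset(scfg)
    TR <- config$glm$TR %||% 1.4
    des <- generate_trial_design(scfg$n_states, scfg$targets,
                                 pairing = "states", n_runs = 2,
                                 seed = derive_seed(scfg$seed, 11))
    ev <- schedule_events(des, seed = derive_seed(scfg$seed, 12))
    n_TRs <- ceiling((max(ev$onset + ev$duration) + 16) / TR)
    dm <- build_design_matrix(ev, TR = TR, n_TRs = n_TRs)
    for (i in seq_along(subjects)) {
      Y <- simulate_bold(dm, subjects[[i]],
                         noise_sd = config$glm$noise_sd %||% 0,
                         seed = derive_seed(scfg$seed, 100 + i))
      subjects[[i]] <- fit_glm(Y, dm, dims = scfg$grid_shape,
                               voxel_size_mm = scfg$voxel_size_mm,
                               subject = subjects[[i]]$subject)
    }
    p <- file.path(out_dir, "design_matrix.csv")
    write.csv(dm$X, p, row.names = FALSE)
    record("design_matrix", p)
  }

  maps <- NULL
  if (any(c("rsa", "infer") %in% stages)) {
    subjects <- subjects %||% simulate_dataset(scfg)
    mask <- array(TRUE, dim = scfg$grid_shape)
    lights <- searchlight_centers(mask, radius)
    maps <- lapply(subjects, searchlight_distinctiveness, mask = mask,
                   radius_voxels = radius, lights = lights)
    maps_sm <- lapply(maps, function(m)
      lapply(m, smooth_map, fwhm_mm = fwhm,
             voxel_size_mm = scfg$voxel_size_mm))
    mean_map <- Reduce(`+`, lapply(maps_sm, `[[`, 1)) / length(maps_sm)
    p <- file.path(out_dir, sprintf("distinctiveness_mean_%s.nii.gz",
                                    scfg$targets[1]))
    RNifti::writeNifti(RNifti::asNifti(mean_map), p)
    record("distinctiveness_mean", p)
    maps <- maps_sm
  }

  if ("infer" %in% stages) {
    t1 <- scfg$targets[1]
    t2 <- scfg$targets[length(scfg$targets)]
    fwe <- permutation_fwe(
      list(lapply(maps, `[[`, t1), lapply(maps, `[[`, t2)),
      contrast = "paired-t",
      scheme = perm_scheme(n_perms, seed = derive_seed(scfg$seed, 21)))
    p <- file.path(out_dir, sprintf("pcorr_%s_vs_%s.nii.gz", t1, t2))
    RNifti::writeNifti(RNifti::asNifti(fwe$p), p)
    record("corrected_p", p)
    roi <- t(vapply(subjects, function(s)
      setNames(roi_distinctiveness(s, scfg$effect_region)$mean_dissimilarity,
               scfg$targets), numeric(length(scfg$targets))))
    tests <- pairwise_target_tests(roi)
    p <- file.path(out_dir, "roi_pairwise_tests.csv")
    write.csv(tests, p, row.names = FALSE)
    record("roi_pairwise_tests", p)
    manifest$results$min_p_corr <- min(fwe$p, na.rm = TRUE)
  }

  if ("behavior" %in% stages) {
    rcfg <- do.call(rating_sim_config, rat_args)
    ratings <- simulate_ratings(rcfg)
    p <- file.path(out_dir, "ratings.csv")
    write_ratings(ratings, p)
    record("ratings", p)
    lmm <- fit_state_similarity_lmm(ratings, fixed = if (
      length(rcfg$targets) > 2) "self_other" else "close_far",
      reference = rcfg$targets[1])
    jsonlite::write_json(list(fixed = lmm$fixed, r2 = as.list(lmm$r2),
                              random_structure = lmm$random_structure,
                              singular = lmm$singular),
                         file.path(out_dir, "lmm_result.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    record("lmm_result", file.path(out_dir, "lmm_result.json"))
    manifest$results$lmm_b <- lmm$fixed$b[1]
  }

  if ("figure" %in% stages) {
    subjects <- subjects %||% simulate_dataset(scfg)
    roi_rdm <- compute_rdm(
      subjects[[1]]$data[as.vector(scfg$effect_region), , drop = FALSE],
      subjects[[1]]$conditions)
    embs <- lapply(scfg$targets, function(tg) mds_embed(roi_rdm, tg))
    names(embs) <- scfg$targets
    for (tg in scfg$targets[-1])
      embs[[tg]] <- procrustes_align(embs[[1]], embs[[tg]])
    coords <- do.call(rbind, lapply(scfg$targets, function(tg)
      data.frame(target = tg, state = rownames(embs[[tg]]$coords),
                 dim1 = embs[[tg]]$coords[, 1],
                 dim2 = embs[[tg]]$coords[, 2],
                 radius = embs[[tg]]$radius, row.names = NULL)))
    p <- file.path(out_dir, "mds_coordinates.csv")
    write.csv(coords, p, row.names = FALSE)
    record("mds_coordinates", p)
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}
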