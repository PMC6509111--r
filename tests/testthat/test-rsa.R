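test_that("correlation-distance RDM matches hand-computed Pearson r", {
  a <- c(1, 2, 3, 4)
  b <- c(2, 1, 4, 3)
  d <- c(5, 2, 0, 1)
  rdm <- compute_rdm(cbind(a, b, d))
  expect_equal(rdm[1, 2], 1 - pearson_by_hand(a, b))
  expect_equal(rdm[1, 3], 1 - pearson_by_hand(a, d))
  expect_equal(rdm[2, 3], 1 - pearson_by_hand(b, d))
  # identical patterns -> 0; negated pattern -> 2
  rdm2 <- compute_rdm(cbind(a, a, -a))
  expect_equal(rdm2[1, 2], 0)
  expect_equal(rdm2[1, 3], 2)
})

test_that("RDMs are symmetric, zero-diagonal, bounded, and reject constants", {
  for (s in 1:5) {
    set.seed(s)
    p <- matrix(rnorm(20 * 6, mean = s), 20, 6)
    rdm <- compute_rdm(p)
    expect_equal(unclass(rdm), t(unclass(rdm)))
    expect_equal(unname(diag(rdm)), rep(0, 6))
    expect_true(all(rdm >= 0 & rdm <= 2))
  }
  expect_error(compute_rdm(cbind(a = 1:4, b = rep(2, 4))),
               "constant.*b")
  expect_error(compute_rdm(matrix(1:4, 2, 2)), "length >= 3")
})

test_that("within-target averaging uses only lower-triangle same-target pairs", {
  n <- 30
  labs <- sprintf("s%02d", 1:n)
  conds <- data.frame(target = rep(c("self", "far"), each = n),
                      state = c(labs, labs))
  m <- matrix(0.7, 2 * n, 2 * n)
  diag(m) <- 0
  rdm <- structure(m, class = c("rdm", "matrix"), conditions = conds)
  expect_equal(average_target_dissimilarity(rdm, "self"), 0.7)

  # perturbing one within-target entry moves the mean by delta / C(30,2)
  m2 <- m
  m2[2, 1] <- m2[1, 2] <- 0.7 + 0.435
  rdm2 <- structure(m2, class = c("rdm", "matrix"), conditions = conds)
  expect_equal(average_target_dissimilarity(rdm2, "self"),
               0.7 + 0.435 / choose(30, 2))

  # perturbing cross-target entries changes nothing
  m3 <- m
  m3[n + 1, 1] <- m3[1, n + 1] <- 1.9
  rdm3 <- structure(m3, class = c("rdm", "matrix"), conditions = conds)
  expect_equal(average_target_dissimilarity(rdm3, "self"), 0.7)
  expect_equal(average_target_dissimilarity(rdm3, "far"), 0.7)

  one <- data.frame(target = c("a", "b"), state = c("x", "x"))
  rdm1 <- structure(matrix(c(0, 1, 1, 0), 2), class = c("rdm", "matrix"),
                    conditions = one)
  expect_error(average_target_dissimilarity(rdm1, "a"), "at least 2 states")
})

test_that("searchlight neighborhoods match brute-force lattice enumeration", {
  mask <- array(TRUE, c(11, 11, 11))
  sl <- searchlight_centers(mask, radius_voxels = 4)
  center <- which(array(seq_len(11^3), rep(11, 3)) ==
                    (6 - 1) * 11^2 + (6 - 1) * 11 + 6)
  nb <- sl$neighbors[[center]]
  expect_length(nb, lattice_sphere_count(4))
  expect_length(nb, 257)

  # radius 0: neighborhood is the center itself
  sl0 <- searchlight_centers(mask, 0, min_voxels = 1)
  expect_identical(sl0$neighbors[[center]], center)

  # corner neighborhoods are strictly smaller than interior ones
  expect_lt(length(sl$neighbors[[1]]), 257)
  expect_error(searchlight_centers(array(FALSE, c(3, 3, 3)), 2), "empty")
})

test_that("searchlight values are local: padding the mask changes nothing inside", {
  cfg <- tiny_effect_config(n_subjects = 1)
  ps <- simulate_subject_betas(cfg, 1)
  full <- array(TRUE, cfg$grid_shape)
  cut <- full
  cut[1, 1, 1] <- FALSE  # outside the interior voxel's sphere
  m_full <- searchlight_distinctiveness(ps, full, radius_voxels = 2,
                                        min_voxels = 5)
  m_cut <- searchlight_distinctiveness(ps, cut, radius_voxels = 2,
                                       min_voxels = 5)
  expect_equal(m_full$self[5, 5, 5], m_cut$self[5, 5, 5])
})

test_that("distinctiveness is invariant to a common affine gain and offset", {
  cfg <- tiny_effect_config(n_subjects = 1)
  ps <- simulate_subject_betas(cfg, 1)
  roi <- cfg$effect_region
  base <- roi_distinctiveness(ps, roi)
  ps2 <- ps
  ps2$data <- 3.7 * ps$data + 11
  expect_equal(roi_distinctiveness(ps2, roi), base)
})

test_that("a two-condition neighborhood reduces to the single pair distance", {
  cfg <- sim_config(n_subjects = 1, grid_shape = c(5, 5, 5),
                    targets = "self", n_states = 2,
                    dispersion_by_target = c(self = 1), noise_sd = 0.1,
                    seed = 4)
  ps <- simulate_subject_betas(cfg, 1)
  mask <- array(TRUE, cfg$grid_shape)
  maps <- searchlight_distinctiveness(ps, mask, radius_voxels = 2,
                                      min_voxels = 5)
  sl <- searchlight_centers(mask, 2, min_voxels = 5)
  v <- sl$centers[20]
  nb <- sl$neighbors[[v]]
  expect_equal(maps$self[v],
               1 - pearson_by_hand(ps$data[nb, 1], ps$data[nb, 2]))
})

test_that("ROI distinctiveness reproduces the planted dispersion ordering", {
  cfg <- sim_config(n_subjects = 1, grid_shape = c(8, 8, 8),
                    targets = c("self", "close", "far"), n_states = 8,
                    dispersion_by_target = c(self = 1, close = .6,
                                             far = .2),
                    noise_sd = 0.1, seed = 12)
  ps <- simulate_subject_betas(cfg, 1)
  roi <- roi_distinctiveness(ps, cfg$effect_region)
  d <- setNames(roi$mean_dissimilarity, roi$target)
  expect_gt(d[["self"]], d[["close"]])
  expect_gt(d[["close"]], d[["far"]])
  expect_equal(roi$mean_correlation, 1 - roi$mean_dissimilarity)

  # a one-voxel ROI cannot support correlations
  one <- array(FALSE, cfg$grid_shape)
  one[4, 4, 4] <- TRUE
  expect_error(roi_distinctiveness(ps, one), "length >= 3")

  # identical patterns within a target give zero dissimilarity
  psi <- ps
  cols <- psi$conditions$target == "self"
  psi$data[, cols] <- psi$data[, which(cols)[1]]
  roi_i <- roi_distinctiveness(psi, cfg$effect_region)
  expect_equal(roi_i$mean_dissimilarity[roi_i$target == "self"], 0)
})

test_that("group searchlight maps localize the planted effect", {
  cfg <- tiny_effect_config(n_subjects = 6, noise_sd = 0.3, seed = 31)
  mask <- array(TRUE, cfg$grid_shape)
  lights <- searchlight_centers(mask, 2, min_voxels = 5)
  diff <- Reduce(`+`, lapply(seq_len(6), function(s) {
    m <- searchlight_distinctiveness(simulate_subject_betas(cfg, s), mask,
                                     radius_voxels = 2, min_voxels = 5,
                                     lights = lights)
    m$self - m$far
  })) / 6
  expect_gt(mean(diff[cfg$effect_region]), mean(diff[!cfg$effect_region]))
  expect_gt(mean(diff[cfg$effect_region]), 0)

  # equal dispersions: the difference map hovers around zero
  cfg0 <- sim_config(n_subjects = 6, grid_shape = c(8, 8, 8),
                     targets = c("self", "far"), n_states = 6,
                     dispersion_by_target = c(self = .5, far = .5),
                     noise_sd = 0.3, seed = 32)
  diff0 <- Reduce(`+`, lapply(seq_len(6), function(s) {
    m <- searchlight_distinctiveness(simulate_subject_betas(cfg0, s), mask,
                                     radius_voxels = 2, min_voxels = 5,
                                     lights = lights)
    m$self - m$far
  })) / 6
  expect_lt(abs(mean(diff0)), 0.02)
})

test_that("design-induced similarity is regressed out of neural similarity", {
  # orthogonal design: centering only
  s <- matrix(c(1, .5, .2, .5, 1, .1, .2, .1, 1), 3)
  adj <- correct_block_structure(s, diag(3))
  lt <- lower.tri(s)
  expect_equal(adj[lt], s[lt] - mean(s[lt]))
  expect_equal(diag(adj), diag(s))

  # neural similarity proportional to induced similarity -> all residuals 0
  ind <- matrix(c(1, .4, .2, .4, 1, .3, .2, .3, 1), 3)
  adj2 <- correct_block_structure(0.5 * ind, ind)
  expect_equal(adj2[lower.tri(adj2)], rep(0, 3))

  # hand 3-condition case: residuals of a 2-parameter regression
  y <- c(.6, .3, .2)
  x <- c(.5, .1, .3)
  fit <- lm(y ~ x)
  sm <- diag(3); sm[lower.tri(sm)] <- y
  sm[upper.tri(sm)] <- t(sm)[upper.tri(sm)]
  im <- diag(3); im[lower.tri(im)] <- x
  im[upper.tri(im)] <- t(im)[upper.tri(im)]
  adj3 <- correct_block_structure(sm, im)
  expect_equal(adj3[lower.tri(adj3)], unname(resid(fit)))
  expect_equal(adj3, t(adj3))

  expect_error(correct_block_structure(sm, diag(4)), "same dimension")
})

test_that("fisher-z averaging is available but off by default", {
  conds <- data.frame(target = "a", state = c("x", "y", "z"))
  m <- matrix(c(0, .2, .9, .2, 0, .5, .9, .5, 0), 3)
  rdm <- structure(m, class = c("rdm", "matrix"), conditions = conds)
  plain <- average_target_dissimilarity(rdm, "a")
  expect_equal(plain, mean(c(.2, .9, .5)))
  fz <- average_target_dissimilarity(rdm, "a", fisher_z = TRUE)
  expect_false(isTRUE(all.equal(plain, fz)))
  expect_equal(1 - fz, tanh(mean(atanh(1 - c(.2, .9, .5)))))
})
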