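test_that("gaussian smoothing has the right width and conserves mass", {
  # a delta smoothed with FWHM 6 mm on 2 mm voxels has sd ~ 1.274 voxels
  v <- array(0, c(15, 15, 15))
  v[8, 8, 8] <- 1
  sm <- smooth_map(v, 6, 2)
  prof <- sm[, 8, 8] / sum(sm[, 8, 8])
  sd_emp <- sqrt(sum(prof * (1:15 - 8)^2))
  expect_equal(sd_emp, 6 / (2 * sqrt(2 * log(2))) / 2, tolerance = 1e-3)

  # constants and fwhm = 0 pass through unchanged
  const <- array(3.2, c(6, 6, 6))
  expect_equal(smooth_map(const, 6, 2), const)
  expect_identical(smooth_map(v, 0, 2), v)

  # global mean preserved under both boundary rules
  set.seed(5)
  r <- array(rnorm(8^3), c(8, 8, 8))
  expect_equal(mean(smooth_map(r, 9, 2, "reflect")), mean(r),
               tolerance = 1e-10)
  expect_equal(mean(smooth_map(r, 9, 2, "periodic")), mean(r),
               tolerance = 1e-10)

  # undefined voxels stay NA and do not contaminate defined neighbors
  rn <- r
  rn[1, 1, ] <- NA
  sn <- smooth_map(rn, 6, 2)
  expect_true(all(is.na(sn[1, 1, ])))
  expect_false(anyNA(sn[-1, -1, ]))
  # a constant map with holes smooths back to the same constant
  cn <- array(2.5, c(6, 6, 6))
  cn[3, 3, 3] <- NA
  expect_equal(smooth_map(cn, 8, 2)[-3, , ], array(2.5, c(5, 6, 6)))
})

test_that("paired t map matches the hand formula", {
  # n = 4 differences at a single voxel: t = mean / (sd / sqrt(n))
  a <- c(1.2, 0.8, 1.5, 1.1)
  b <- c(1.0, 0.5, 1.1, 1.0)
  sm <- paired_t_map(matrix(a), matrix(b))
  d <- a - b
  expect_equal(sm$values[1], mean(d) / (sd(d) / 2))
  expect_equal(sm$df, 3)

  # A = B gives NA (zero-variance differences are undefined, logged)
  same <- matrix(rnorm(12), 4)
  eqm <- paired_t_map(same, same)
  expect_true(all(is.na(eqm$values)))
  expect_equal(eqm$n_undefined, 3)
})

test_that("repeated-measures ANOVA agrees with aov and with F = t^2", {
  set.seed(42)
  n <- 6
  vals <- lapply(1:3, function(k) matrix(rnorm(n * 2, mean = k / 10), n))
  sm <- repeated_anova_map(vals)
  long <- data.frame(
    y = c(vals[[1]][, 1], vals[[2]][, 1], vals[[3]][, 1]),
    target = factor(rep(1:3, each = n)), subject = factor(rep(1:n, 3)))
  ref <- summary(stats::aov(y ~ target + Error(subject / target),
                            data = long))
  f_ref <- ref[["Error: subject:target"]][[1]]["target", "F value"]
  expect_equal(sm$values[1], f_ref, tolerance = 1e-10)
  expect_equal(sm$df, c(2, 10))

  # two levels: F equals the square of the paired t
  f2 <- repeated_anova_map(vals[1:2])
  t2 <- paired_t_map(vals[[1]], vals[[2]])
  expect_equal(f2$values, t2$values^2, tolerance = 1e-10)

  # equal target means: F hovers around its null expectation
  null <- lapply(1:3, function(k) matrix(rnorm(40 * 50), 40))
  fn <- repeated_anova_map(null)
  expect_equal(fn$df, c(2, 78))
  expect_lt(abs(mean(fn$values) - 78 / 76), 0.45)  # E[F] = df2/(df2-2)
})

test_that("TFCE matches its analytic values for simple geometries", {
  z <- array(0, c(8, 8, 8))
  expect_equal(tfce_enhance(z), z)

  # isolated voxel of height h: integral of t^2 dt = h^3 / 3
  v <- z; v[4, 4, 4] <- 1.5
  e <- tfce_enhance(v, tfce_params(dh = 1e-4))
  expect_equal(e[4, 4, 4], 1.5^3 / 3, tolerance = 1e-3)
  expect_equal(sum(e != 0), 1)

  # two-voxel plateau: extent 2 at every threshold -> sqrt(2) h^3 / 3
  v2 <- z; v2[4, 4, 4] <- v2[4, 5, 4] <- 1.5
  e2 <- tfce_enhance(v2, tfce_params(dh = 1e-4))
  expect_equal(e2[4, 4, 4], sqrt(2) * 1.5^3 / 3, tolerance = 1e-3)

  # negative blobs are enhanced on the negated map, with sign restored
  vn <- z; vn[2, 2, 2] <- -1.5
  en <- tfce_enhance(vn, tfce_params(dh = 1e-4))
  expect_equal(en[2, 2, 2], -1.5^3 / 3, tolerance = 1e-3)
})

test_that("TFCE equals brute-force per-threshold labeling on random maps", {
  set.seed(7)
  for (i in 1:6) {
    v <- array(rnorm(8^3), c(8, 8, 8))
    v[v < 0.8] <- 0  # sparse positive blobs
    fast <- tfce_enhance(v, tfce_params(dh = max(v) / 40))
    slow <- tfce_brute(v, dh = max(v) / 40)
    expect_equal(fast, slow, tolerance = 1e-10)
  }
  # and for 6-connectivity
  v <- array(pmax(rnorm(6^3), 0), c(6, 6, 6))
  expect_equal(tfce_enhance(v, tfce_params(dh = max(v) / 40,
                                           connectivity = 6)),
               tfce_brute(v, dh = max(v) / 40, connectivity = 6),
               tolerance = 1e-10)
})

test_that("TFCE is monotone in the input statistic", {
  set.seed(8)
  v <- array(pmax(rnorm(6^3), 0), c(6, 6, 6))
  base <- tfce_enhance(v, tfce_params(dh = 0.02))
  for (i in 1:5) {
    v2 <- v
    j <- sample(length(v2), 1)
    v2[j] <- v2[j] + runif(1, 0.1, 1)
    up <- tfce_enhance(v2, tfce_params(dh = 0.02))
    expect_true(all(up - base > -1e-9))
  }
})

test_that("sign-flip permutation p values are exact and exhaustive when possible", {
  set.seed(3)
  n <- 5
  maps <- list(matrix(rnorm(n * 27, mean = 1.5), n),
               matrix(rnorm(n * 27), n))
  expect_warning(
    fwe <- permutation_fwe(maps, "paired-t",
                           scheme = perm_scheme(100, seed = 2)),
    "32 distinct sign flips")
  expect_equal(fwe$n_perms, 32)
  expect_true(all(fwe$p >= 1 / 32 & fwe$p <= 1, na.rm = TRUE))
  # two-sided tail combination can never undercut 2/n_perms
  expect_gte(min(fwe$p, na.rm = TRUE), 2 / 32)
})

test_that("a strong planted effect survives FWE correction where planted", {
  cfg <- sim_config(n_subjects = 10, grid_shape = c(8, 8, 8),
                    targets = c("self", "far"), n_states = 8,
                    dispersion_by_target = c(self = 1.2, far = 0.2),
                    noise_sd = 0.2, seed = 19)
  mask <- array(TRUE, cfg$grid_shape)
  lights <- searchlight_centers(mask, 2, min_voxels = 5)
  maps <- lapply(simulate_dataset(cfg), function(s) {
    m <- searchlight_distinctiveness(s, mask, radius_voxels = 2,
                                     min_voxels = 5, lights = lights)
    lapply(m, smooth_map, fwhm_mm = 4, voxel_size_mm = 2)
  })
  fwe <- permutation_fwe(list(lapply(maps, `[[`, "self"),
                              lapply(maps, `[[`, "far")),
                         scheme = perm_scheme(500, seed = 5))
  center <- c(4, 4, 4)
  expect_lt(fwe$p[4, 4, 4], 0.05)
  # the t map is positive (self more distinct) at the planted center
  expect_gt(fwe$stat$values[4, 4, 4], 0)
  # determinism: same scheme, same p map; new seed, same observed stat
  fwe2 <- permutation_fwe(list(lapply(maps, `[[`, "self"),
                               lapply(maps, `[[`, "far")),
                          scheme = perm_scheme(500, seed = 5))
  expect_identical(fwe$p, fwe2$p)
  fwe3 <- permutation_fwe(list(lapply(maps, `[[`, "self"),
                               lapply(maps, `[[`, "far")),
                          scheme = perm_scheme(500, seed = 6))
  expect_identical(fwe$stat$values, fwe3$stat$values)
  expect_false(identical(fwe$max_dist, fwe3$max_dist))
})

test_that("ANOVA permutation scheme yields valid p values under relabeling", {
  set.seed(9)
  n <- 8
  maps <- lapply(1:3, function(k)
    matrix(rnorm(n * 27, mean = c(0, 0, 0.8)[k]), n))
  fwe <- permutation_fwe(maps, "anova", scheme = perm_scheme(200, seed = 4))
  expect_true(all(fwe$p >= 1 / 200 & fwe$p <= 1, na.rm = TRUE))
  expect_equal(fwe$stat$kind, "F")
  expect_lt(min(fwe$p), 0.05)  # the planted level difference is detected
})

test_that("pairwise target tests compute Cohen's d and Bonferroni by hand rules", {
  diffs <- c(0.1, 0.2, 0.3, 0.2)
  base <- c(0.5, 0.55, 0.48, 0.52)
  scal <- cbind(self = base + diffs, far = base)
  res <- pairwise_target_tests(scal, bonferroni_m = 3)
  expect_equal(res$mean_diff, mean(diffs))
  expect_equal(res$cohen_d, mean(diffs) / sd(diffs))
  expect_equal(res$delta_r, -mean(diffs))
  expect_equal(res$t, mean(diffs) / (sd(diffs) / 2))
  expect_equal(res$p_bonferroni, min(1, res$p * 3))

  # identical scalars: no effect, p = 1
  same <- cbind(a = base, b = base)
  res0 <- pairwise_target_tests(same)
  expect_equal(res0$t, 0)
  expect_equal(res0$p, 1)

  # constant nonzero difference: d undefined
  expect_error(pairwise_target_tests(cbind(a = base + 1, b = base)),
               "undefined")
})
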