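test_that("phantom tensors encode the prescribed geometry and gain", {
  spec <- smallPhantomSpec(k = 1.5)
  ph <- buildTensorPhantom(spec)
  comp <- ph$tensor@components
  ## projection voxel inside the slab: Dxx enhanced, principal axis z
  v <- c(5, 14, 8)
  expect_equal(comp[v[1], v[2], v[3], 1], 1.5 * spec@d_perp)
  expect_equal(comp[v[1], v[2], v[3], 2], spec@d_perp)
  expect_equal(comp[v[1], v[2], v[3], 3], spec@d_parallel)
  ## same column outside the slab: unenhanced
  expect_equal(comp[v[1], v[2], 3, 1], spec@d_perp)
  ## association voxel in slab: Dxx enhanced, principal axis y
  w <- c(9, 20, 8)
  expect_equal(comp[w[1], w[2], w[3], 1], 1.5 * spec@d_perp)
  expect_equal(comp[w[1], w[2], w[3], 2], spec@d_parallel)
  ## CC voxel: principal axis x, never enhanced
  u <- c(10, 26, 8)
  expect_equal(comp[u[1], u[2], u[3], 1], spec@d_parallel)
  ## off-diagonals zero everywhere, ground truth recorded
  expect_true(all(comp[, , , 4:6] == 0))
  expect_equal(ph$ground_truth_alps, 1.5)
})

test_that("gain 1 means no enhancement and ALPS ground truth 1 in ROI means", {
  spec <- smallPhantomSpec(k = 1)
  res <- phantomAlpsPath(spec, noise_sd = 0)
  ## no enhancement: numerator and denominator diffusivities are identical
  expect_equal(alpsBilateral(res$alps), 1, tolerance = 1e-10)
  m <- res$alps@means
  expect_equal(m$Dx_proj, m$Dy_proj, tolerance = 1e-10)
})

test_that("overlapping phantom regions are rejected", {
  expect_error(
    smallPhantomSpec(ventricle_region = rbind(x = c(4L, 7L), y = c(12L, 17L),
                                              z = c(6L, 9L))),
    "overlap")
})

test_that("a slab with no inferior-superior fibers fails projection placement by name", {
  ## move the projection columns out of the slab: only y- and x-oriented
  ## fibers remain at ventricle level, so the |e1 . z| rule finds nothing
  spec <- smallPhantomSpec(
    proj_region = list(left = rbind(x = c(4L, 7L), y = c(12L, 17L), z = c(1L, 4L)),
                       right = rbind(x = c(18L, 21L), y = c(12L, 17L), z = c(1L, 4L))))
  ph <- buildTensorPhantom(spec)
  tv <- ph$tensor
  slab <- ph$masks$slab
  expect_error(
    placeRoisAuto(faMap(tv), principalDirection(tv, mask = slab),
                  smallPlacementParams(spec)),
    "projection")
})

test_that("diffusion-weighted signal follows the single-tensor closed form", {
  ## isotropic D = 1e-3 I at b = 1000: every DW intensity is s0 exp(-1)
  D <- diag(3) * 1e-3
  tv <- singleVoxelVolume(D)
  gtab <- defaultGradientTable(n_dirs = 12L, b = 1000)
  dwi <- phantomToDwi(tv, gtab, s0 = 100, noise_sd = 0)
  expect_equal(as.vector(dwi$dwi[1, 1, 1, 1]), 100)
  expect_equal(as.vector(dwi$dwi[1, 1, 1, -1]),
               rep(100 * exp(-1), 12), tolerance = 1e-12)
})

test_that("DWI simulation is deterministic under a fixed seed", {
  spec <- smallPhantomSpec()
  tv <- buildTensorPhantom(spec)$tensor
  a <- phantomToDwi(tv, noise_sd = 0.05, seed = 9L)
  b <- phantomToDwi(tv, noise_sd = 0.05, seed = 9L)
  c2 <- phantomToDwi(tv, noise_sd = 0.05, seed = 10L)
  expect_identical(a$dwi, b$dwi)
  expect_false(identical(a$dwi, c2$dwi))
})

test_that("DWI simulation rejects unidentifiable gradient schemes", {
  tv <- singleVoxelVolume(diag(3) * 1e-3)
  g <- gradientTable(c(0, rep(1000, 5)),
                     cbind(c(0, 0, 0), diag(3), diag(3)[, 1:2]))
  expect_error(phantomToDwi(tv, g), "6 unique")
})

test_that("degenerate cohort spec yields constant ALPS at beta0", {
  spec <- cohortSpec(n_hc = 10L, n_del = 10L,
                     beta_group = 0, beta_age = 0, beta_interaction = 0,
                     beta_sex = 0, beta_pps = 0, beta_pps_interaction = 0,
                     sd_intercept = 0, sd_slope = 0, sd_resid = 0,
                     hemi_offset_sd = 0, mrs_subset_n = 5L)
  co <- simulateCohort(spec, seed = 4)
  expect_true(all(abs(co$alps_bilateral - spec@beta0) < 1e-12))
  expect_true(all(co$alps_left == co$alps_right))
})

test_that("cohort generator is reproducible and respects the design ranges", {
  spec <- cohortSpec()
  a <- simulateCohort(spec, seed = 7)
  b <- simulateCohort(spec, seed = 7)
  expect_identical(a, b)
  expect_true(all(a$age >= 5 & a$age <= 35))
  expect_true(all(table(a$participant) <= 3))
  expect_setequal(unique(a$group), c("HC", "DEL"))
  expect_true(all(is.na(a$pps[a$group == "HC"])))
  ## scan-level sizes match the configured participant counts
  expect_equal(length(unique(a$participant[a$group == "HC"])), 83L)
  expect_equal(length(unique(a$participant[a$group == "DEL"])), 85L)
})

test_that("participant intercept variance matches sd_intercept^2 at large n", {
  spec <- cohortSpec(n_hc = 1000L, n_del = 1000L, scans_range = c(1L, 1L),
                     beta_group = 0, beta_age = 0, beta_interaction = 0,
                     beta_sex = 0, beta_pps = 0, beta_pps_interaction = 0,
                     sd_slope = 0, sd_resid = 0, hemi_offset_sd = 0)
  co <- simulateCohort(spec, seed = 11)
  expect_equal(stats::var(co$alps_bilateral), spec@sd_intercept^2,
               tolerance = 0.1)
})

test_that("MRS subset is cross-sectional and recovers the slope when noiseless", {
  spec <- cohortSpec(mrs_noise_sd = 0)
  co <- simulateCohort(spec, seed = 3)
  mrs <- simulateMrs(co, spec, seed = 5)
  expect_equal(nrow(mrs), 39L)
  expect_equal(anyDuplicated(mrs$participant), 0L)
  ## deterministic line: OLS recovers slope and intercept exactly
  fit <- stats::lm(glx_gaba ~ alps, data = mrs)
  expect_equal(unname(stats::coef(fit)), c(19.4, -11.02), tolerance = 1e-10)
  ## reproducibility
  expect_identical(mrs, simulateMrs(co, spec, seed = 5))
})

test_that("MRS subset larger than the carrier group is rejected", {
  spec <- cohortSpec(n_hc = 5L, n_del = 5L, mrs_subset_n = 5L)
  co <- simulateCohort(spec, seed = 1)
  spec10 <- spec; spec10@mrs_subset_n <- 10L
  expect_error(simulateMrs(co, spec10), "exceeds")
})
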