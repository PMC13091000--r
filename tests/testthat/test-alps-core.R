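test_that("automated placement lands inside the constructed bundles", {
  spec <- smallPhantomSpec()
  ph <- buildTensorPhantom(spec)
  tv <- ph$tensor
  rois <- placeRoisAuto(faMap(tv), principalDirection(tv, mask = ph$masks$slab),
                        smallPlacementParams(spec), include_cc = TRUE)
  expect_equal(nrow(rois@rois), 6L)
  inBox <- function(r, box) {
    all(c(r$cx, r$cy, r$cz) >= box[, 1] & c(r$cx, r$cy, r$cz) <= box[, 2])
  }
  r <- rois@rois
  expect_true(inBox(r[r$side == "left" & r$fiber_class == "projection", ],
                    spec@proj_region$left))
  expect_true(inBox(r[r$side == "right" & r$fiber_class == "projection", ],
                    spec@proj_region$right))
  expect_true(inBox(r[r$side == "left" & r$fiber_class == "association", ],
                    spec@assoc_region$left))
  expect_true(inBox(r[r$side == "right" & r$fiber_class == "association", ],
                    spec@assoc_region$right))
  expect_true(inBox(r[r$side == "left" & r$fiber_class == "cc_control", ],
                    spec@cc_region$left))
})

test_that("x-aligned fibers are never selected as projection or association", {
  spec <- smallPhantomSpec()
  ph <- buildTensorPhantom(spec)
  tv <- ph$tensor
  rois <- placeRoisAuto(faMap(tv), principalDirection(tv, mask = ph$masks$slab),
                        smallPlacementParams(spec))
  ## the CC bundle sits at y 25-28; no proj/assoc centroid may fall there
  expect_true(all(rois@rois$cy < 25))
})

test_that("placement errors name the failing class when FA excludes all voxels", {
  spec <- smallPhantomSpec()
  ph <- buildTensorPhantom(spec)
  tv <- ph$tensor
  expect_error(
    placeRoisAuto(faMap(tv), principalDirection(tv, mask = ph$masks$slab),
                  smallPlacementParams(spec, fa_min = 0.99)),
    "projection|association")
})

test_that("ROI means aggregate exactly the voxels inside the sphere", {
  ## constant map: any ROI returns the constant
  aff <- diag(c(2, 2, 2, 1))
  m <- new("ScalarMap", data = array(7.5, c(10, 10, 10)), affine = aff)
  r <- data.frame(cx = 5, cy = 5, cz = 5, radius_mm = 4)
  expect_equal(extractRoiMean(m, r)$value, 7.5)
  ## radius below half a voxel at a center: exactly that voxel
  m@data[5, 5, 5] <- -3
  expect_equal(extractRoiMean(m, data.frame(cx = 5, cy = 5, cz = 5,
                                            radius_mm = 0.9))$value, -3)
  expect_equal(extractRoiMean(m, data.frame(cx = 5, cy = 5, cz = 5,
                                            radius_mm = 0.9))$n_voxels, 1L)
  ## two-value field: compare to brute-force voxel enumeration
  set.seed(99)
  vals <- array(sample(c(1, 2), 1000, TRUE), c(10, 10, 10))
  m2 <- new("ScalarMap", data = vals, affine = aff)
  r2 <- data.frame(cx = 4.3, cy = 6.1, cz = 5.5, radius_mm = 5.2)
  got <- extractRoiMean(m2, r2)
  grid <- as.matrix(expand.grid(x = 1:10, y = 1:10, z = 1:10))
  d_mm <- sqrt(rowSums(sweep(grid * 2, 2, c(r2$cx, r2$cy, r2$cz) * 2)^2))
  inside <- d_mm <= r2$radius_mm
  expect_equal(got$n_voxels, sum(inside))
  expect_equal(got$value, mean(vals[grid[inside, , drop = FALSE]]))
})

test_that("an ROI without voxels in the volume is an error", {
  m <- new("ScalarMap", data = array(1, c(5, 5, 5)), affine = diag(4))
  expect_error(extractRoiMean(m, data.frame(cx = 50, cy = 50, cz = 50,
                                            radius_mm = 2)), "no valid voxels")
})

test_that("the ALPS ratio reproduces its defining arithmetic", {
  ## Dx_proj = Dx_assoc = 1.2e-3 against orthogonal 0.8e-3 gives 1.5
  aff <- diag(4)
  mk <- function(v) new("ScalarMap", data = array(v, c(8, 8, 8)), affine = aff)
  rois <- roiSet(side = rep(c("left", "right"), each = 2),
                 fiber_class = rep(c("projection", "association"), 2),
                 cx = c(2, 2, 6, 6), cy = c(2, 6, 2, 6), cz = rep(4, 4),
                 radius_mm = rep(1.2, 4), affine = aff)
  a <- computeAlps(mk(1.2e-3), mk(0.8e-3), mk(0.8e-3), rois)
  expect_equal(alpsLeft(a), 1.5)
  expect_equal(alpsRight(a), 1.5)
  expect_equal(alpsBilateral(a), 1.5)
  expect_identical(qcFlags(a), "ok")
})

test_that("ALPS is exactly 1 on isotropic volumes wherever ROIs sit", {
  set.seed(17)
  aff <- diag(c(2, 2, 2, 1))
  v <- array(1.1e-3, c(12, 12, 12))
  m <- new("ScalarMap", data = v, affine = aff)
  for (i in 1:5) {
    cx <- runif(4, 3, 10); cy <- runif(4, 3, 10); cz <- runif(4, 3, 10)
    rois <- roiSet(side = rep(c("left", "right"), each = 2),
                   fiber_class = rep(c("projection", "association"), 2),
                   cx = cx, cy = cy, cz = cz, radius_mm = rep(3, 4),
                   affine = aff)
    a <- computeAlps(m, m, m, rois)
    expect_equal(alpsLeft(a), 1)
    expect_equal(alpsRight(a), 1)
  }
})

test_that("ALPS is scale invariant and monotone in the x-axis diffusivities", {
  spec <- smallPhantomSpec(k = 1.4)
  res <- phantomAlpsPath(spec, noise_sd = 0)
  tv <- res$tensor
  base <- alpsBilateral(res$alps)
  comp <- tensorComponents(tv)
  scale_map <- function(m, c) new("ScalarMap", data = m@data * c,
                                  affine = m@affine)
  for (c in c(0.25, 3, 11)) {
    a <- computeAlps(scale_map(comp$Dxx, c), scale_map(comp$Dyy, c),
                     scale_map(comp$Dzz, c), res$rois)
    expect_equal(alpsBilateral(a), base, tolerance = 1e-12)
  }
  ## raising Dxx alone strictly raises the index
  prev <- base
  for (c in c(1.1, 1.3, 1.7)) {
    a <- computeAlps(scale_map(comp$Dxx, c), comp$Dyy, comp$Dzz, res$rois)
    expect_gt(alpsBilateral(a), prev)
    prev <- alpsBilateral(a)
  }
})

test_that("non-positive denominators invalidate the hemisphere and flag it", {
  aff <- diag(4)
  mk <- function(v) new("ScalarMap", data = array(v, c(8, 8, 8)), affine = aff)
  rois <- roiSet(side = rep(c("left", "right"), each = 2),
                 fiber_class = rep(c("projection", "association"), 2),
                 cx = c(2, 2, 6, 6), cy = c(2, 6, 2, 6), cz = rep(4, 4),
                 radius_mm = rep(1.2, 4), affine = aff)
  dyy <- mk(0.8e-3)
  dyy@data[1:4, , ] <- -2e-3      # left hemisphere denominator forced negative
  a <- computeAlps(mk(1.2e-3), dyy, mk(0.8e-3), rois)
  expect_true(is.na(alpsLeft(a)))
  expect_false(is.na(alpsRight(a)))
  expect_true(is.na(alpsBilateral(a)))
  expect_true(any(grepl("invalid_denominator_left", qcFlags(a))))
})

test_that("the CC control reads d_parallel in the phantom bundle", {
  spec <- smallPhantomSpec()
  ph <- buildTensorPhantom(spec)
  tv <- ph$tensor
  rois <- placeRoisAuto(faMap(tv), principalDirection(tv, mask = ph$masks$slab),
                        smallPlacementParams(spec), include_cc = TRUE)
  comp <- tensorComponents(tv)
  cc <- computeCcControl(comp$Dxx, rois)
  expect_equal(cc$cc_left, spec@d_parallel, tolerance = 1e-12)
  expect_equal(cc$cc_right, spec@d_parallel, tolerance = 1e-12)
  ## isotropic region: the control reads the isotropic diffusivity
  iso <- new("ScalarMap", data = array(9e-4, dim(tv@valid)), affine = tv@affine)
  expect_equal(computeCcControl(iso, rois)$cc_bilateral, 9e-4)
  expect_error(computeCcControl(comp$Dxx,
                                roiSet("left", "projection", 2, 2, 2, 1)),
               "cc_control")
})

test_that("per-side CC means follow an asymmetric phantom", {
  spec <- smallPhantomSpec()
  ph <- buildTensorPhantom(spec)
  tv <- ph$tensor
  ## make the right CC bundle hotter by hand
  comp_arr <- tv@components
  m <- ph$masks$cc_right
  comp_arr[, , , 1][m] <- 2e-3
  tv2 <- new("TensorVolume", components = comp_arr, affine = tv@affine,
             valid = tv@valid)
  rois <- placeRoisAuto(faMap(tv), principalDirection(tv, mask = ph$masks$slab),
                        smallPlacementParams(spec), include_cc = TRUE)
  cc <- computeCcControl(tensorComponents(tv2)$Dxx, rois)
  expect_equal(cc$cc_left, spec@d_parallel, tolerance = 1e-12)
  expect_equal(cc$cc_right, 2e-3, tolerance = 1e-12)
})

test_that("ROI sets round-trip through JSON in both coordinate spaces", {
  spec <- smallPhantomSpec()
  ph <- buildTensorPhantom(spec)
  tv <- ph$tensor
  rois <- placeRoisAuto(faMap(tv), principalDirection(tv, mask = ph$masks$slab),
                        smallPlacementParams(spec))
  td <- withr::local_tempdir()
  writeRoiSet(rois, file.path(td, "vox.json"), space = "voxel")
  writeRoiSet(rois, file.path(td, "mm.json"), space = "mm")
  back_v <- readRoiSet(file.path(td, "vox.json"))
  back_m <- readRoiSet(file.path(td, "mm.json"))
  expect_equal(back_v@rois, rois@rois, tolerance = 1e-12)
  expect_equal(back_m@rois$cx, rois@rois$cx, tolerance = 1e-9)
  expect_equal(back_m@rois$cz, rois@rois$cz, tolerance = 1e-9)
})
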