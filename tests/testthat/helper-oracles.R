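## Independent brute-force oracles used across the suite.  These deliberately
## avoid the package's own code paths (and stats:: shortcuts) so that each
## dual-route check compares two genuinely different computations.

## Two-sided Fisher exact p by exhaustive enumeration of tables with the
## observed margins: p = sum of probabilities of tables no more probable
## than the observed one (R's 1 + 1e-7 relative tolerance).
oracleFisherP <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  xs <- max(0, c1 - r2):min(r1, c1)
  pr <- choose(r1, xs) * choose(r2, c1 - xs) / choose(n, c1)
  pobs <- choose(r1, a) * choose(r2, c1 - a) / choose(n, c1)
  sum(pr[pr <= pobs * (1 + 1e-7)])
}

## Textbook Yates-corrected chi-square for a 2x2 table (statistic clamped at
## zero when the correction exceeds |ad - bc| / n).
oracleYates <- function(a, b, c, d) {
  n <- a + b + c + d
  num <- max(0, abs(a * d - b * c) - n / 2)
  stat <- n * num^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  list(statistic = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

## Quartiles by direct linear interpolation of order statistics
## (the type-7 definition, written out by hand).
oracleQuartile <- function(x, p) {
  x <- sort(x); n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

oracleIqrKeep <- function(x, k = 1.5) {
  q1 <- oracleQuartile(x, 0.25); q3 <- oracleQuartile(x, 0.75)
  x >= q1 - k * (q3 - q1) & x <= q3 + k * (q3 - q1)
}

## R^2 via the projection matrix, independent of summary.lm.
oracleR2 <- function(y, X) {
  X <- cbind(1, X)
  H <- X %*% solve(crossprod(X)) %*% t(X)
  1 - sum(((diag(nrow(H)) - H) %*% y)^2) / sum((y - mean(y))^2)
}

## Random symmetric positive-definite diffusion-scale tensor.
randomSpdTensor <- function() {
  A <- matrix(stats::rnorm(9), 3, 3)
  S <- crossprod(A) + diag(3) * 0.1
  S / max(abs(S)) * 1.5e-3
}

## Tensor (3x3) -> the package's 6-component storage order.
tensorToComponents <- function(D) {
  c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3])
}

## Single-voxel TensorVolume from a 3x3 tensor.
singleVoxelVolume <- function(D, affine = diag(4)) {
  new("TensorVolume",
      components = array(tensorToComponents(D), c(1, 1, 1, 6)),
      affine = affine, valid = array(TRUE, c(1, 1, 1)))
}

## Small, fast phantom used throughout the unit tests: 24 x 28 x 16 grid,
## 2 mm voxels, 6-voxel slab, ROI radius 3 mm.
smallPhantomSpec <- function(k = 1.5, ...) {
  args <- list(
    grid_shape = c(24L, 28L, 16L), slab_z = c(6L, 11L),
    perivascular_gain = k,
    proj_region = list(left = rbind(x = c(4L, 7L), y = c(12L, 17L), z = c(3L, 14L)),
                       right = rbind(x = c(18L, 21L), y = c(12L, 17L), z = c(3L, 14L))),
    assoc_region = list(left = rbind(x = c(8L, 11L), y = c(5L, 24L), z = c(5L, 12L)),
                        right = rbind(x = c(14L, 17L), y = c(5L, 24L), z = c(5L, 12L))),
    cc_region = list(left = rbind(x = c(9L, 11L), y = c(25L, 28L), z = c(7L, 10L)),
                     right = rbind(x = c(13L, 15L), y = c(25L, 28L), z = c(7L, 10L))),
    ventricle_region = rbind(x = c(11L, 14L), y = c(1L, 4L), z = c(6L, 11L)))
  ov <- list(...)
  for (nm in names(ov)) args[[nm]] <- ov[[nm]]
  do.call(phantomSpec, args)
}

smallPlacementParams <- function(spec, ...) {
  autoPlacementParams(slab_z = spec@slab_z, radius_mm = 3, ...)
}

## Full imaging path: phantom -> (optionally noisy) DWI -> log-linear fit ->
## canonical maps -> automated ROIs -> ALPS.
phantomAlpsPath <- function(spec, noise_sd = 0, seed = 1L,
                            params = smallPlacementParams(spec)) {
  ph <- buildTensorPhantom(spec)
  dwi <- phantomToDwi(ph$tensor, noise_sd = noise_sd, seed = seed)
  tv <- reorientToCanonical(fitTensorLogLinear(dwi))
  slab <- array(FALSE, dim(tv@valid))
  slab[, , params@slab_z[1]:params@slab_z[2]] <- TRUE
  comp <- tensorComponents(tv)
  rois <- placeRoisAuto(faMap(tv), principalDirection(tv, mask = slab), params)
  list(alps = computeAlps(comp$Dxx, comp$Dyy, comp$Dzz, rois),
       rois = rois, tensor = tv, phantom = ph)
}
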