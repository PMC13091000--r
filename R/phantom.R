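## Synthetic tensor phantoms with known ground-truth ALPS.

.box <- function(x0, x1, y0, y1, z0, z1) {
  m <- rbind(x = c(x0, x1), y = c(y0, y1), z = c(z0, z1))
  storage.mode(m) <- "integer"
  colnames(m) <- c("lo", "hi")
  m
}

.boxMask <- function(shape, box) {
  m <- array(FALSE, shape)
  m[box[1, 1]:box[1, 2], box[2, 1]:box[2, 2], box[3, 1]:box[3, 2]] <- TRUE
  m
}

#' Construct a phantom specification
#'
#' The default geometry is a 40 x 48 x 28 grid of 2 mm voxels: bilateral
#' projection columns running inferior-superior, bilateral association slabs
#' running anterior-posterior, a right-left corpus-callosum-like bundle near
#' the midline, and a CSF-like ventricle block, all on an isotropic
#' background.  Inside the axial slab (`slab_z`, the "lateral-ventricle
#' level") the x-axis diffusivity of projection and association voxels is
#' multiplied by the perivascular gain `k`, so the ground-truth ALPS index
#' of the slab is exactly `k`.
#'
#' Default eigenvalues (d_parallel 1.4e-3, d_perp 0.4e-3 mm^2/s) give the
#' bundles FA ~ 0.63, comfortably above typical placement thresholds, while
#' keeping the enhanced Dxx (`k * d_perp`) below d_parallel for k <= 3 so
#' the principal direction of each bundle is unchanged by the enhancement.
#'
#' @param grid_shape integer length-3 voxel grid.
#' @param voxel_size voxel edge length, mm.
#' @param slab_z inclusive z-index range of the periventricular slab.
#' @param perivascular_gain unitless gain k > 0 applied to Dxx in slab
#'   projection/association voxels.
#' @param d_parallel,d_perp bundle eigenvalues, mm^2/s (axial / radial).
#' @param d_iso,d_csf isotropic diffusivities of background and ventricle.
#' @param proj_region,assoc_region,cc_region lists with `left`/`right`
#'   3 x 2 index-range boxes; defaults scale with `grid_shape`.
#' @param ventricle_region single 3 x 2 box.
#' @param noise_sd default DWI noise SD (signal units, for s0 = 1).
#' @param seed integer seed used by [phantomToDwi()] when none is given.
#' @return a [PhantomSpec].
#' @export
phantomSpec <- function(grid_shape = c(40L, 48L, 28L), voxel_size = 2,
                        slab_z = c(12L, 17L), perivascular_gain = 1.5,
                        d_parallel = 1.4e-3, d_perp = 0.4e-3,
                        d_iso = 0.8e-3, d_csf = 3.0e-3,
                        proj_region = NULL, assoc_region = NULL,
                        cc_region = NULL, ventricle_region = NULL,
                        noise_sd = 1 / 30, seed = 42L) {
  grid_shape <- as.integer(grid_shape)
  if (is.null(proj_region))
    proj_region <- list(left  = .box(8, 12, 20, 28, 5, 24),
                        right = .box(29, 33, 20, 28, 5, 24))
  if (is.null(assoc_region))
    assoc_region <- list(left  = .box(13, 16, 8, 40, 10, 20),
                         right = .box(25, 28, 8, 40, 10, 20))
  if (is.null(cc_region))
    cc_region <- list(left  = .box(17, 20, 20, 24, 13, 16),
                      right = .box(21, 24, 20, 24, 13, 16))
  if (is.null(ventricle_region)) ventricle_region <- .box(18, 23, 28, 36, 11, 18)
  spec <- new("PhantomSpec", grid_shape = grid_shape,
              voxel_size = voxel_size, slab_z = as.integer(slab_z),
              proj_region = proj_region, assoc_region = assoc_region,
              cc_region = cc_region, ventricle_region = ventricle_region,
              d_parallel = d_parallel, d_perp = d_perp, d_iso = d_iso,
              d_csf = d_csf, perivascular_gain = perivascular_gain,
              noise_sd = noise_sd, seed = as.integer(seed))
  .validatePhantomSpec(spec)
  spec
}

.validatePhantomSpec <- function(spec) {
  if (spec@perivascular_gain <= 0) stop("perivascular_gain must be > 0")
  if (!(spec@d_parallel >= spec@d_perp && spec@d_perp > 0))
    stop("need d_parallel >= d_perp > 0")
  if (spec@slab_z[1] < 1L || spec@slab_z[2] > spec@grid_shape[3])
    stop("slab_z outside grid")
  boxes <- c(spec@proj_region, spec@assoc_region, spec@cc_region,
             list(spec@ventricle_region))
  for (b in boxes) {
    if (any(b[, 1] < 1L) || any(b[, 2] > spec@grid_shape))
      stop("region box outside grid")
  }
  total <- array(0L, spec@grid_shape)
  for (b in boxes) total <- total + .boxMask(spec@grid_shape, b)
  if (any(total > 1L)) stop("phantom regions overlap; boxes must be disjoint")
  invisible(TRUE)
}

.canonicalAffine <- function(shape, voxel_size) {
  aff <- diag(c(rep(voxel_size, 3), 1))
  aff[1:3, 4] <- -voxel_size * (shape + 1) / 2   # center world origin
  aff
}

#' Build the tensor field of a phantom
#'
#' Voxels in projection regions get a diagonal tensor with d_parallel on z
#' and d_perp on x/y (principal direction inferior-superior); association
#' regions have d_parallel on y; the CC bundle has d_parallel on x; the
#' ventricle and background are isotropic.  Within `slab_z`, Dxx of
#' projection and association voxels is multiplied by the perivascular
#' gain.
#'
#' @param spec a [PhantomSpec].
#' @return list with `tensor` (a [TensorVolume]), `masks` (named logical
#'   arrays: proj_left/right, assoc_left/right, cc_left/right, ventricle,
#'   slab), and `ground_truth_alps` (= the gain k).
#' @export
buildTensorPhantom <- function(spec) {
  .validatePhantomSpec(spec)
  shape <- spec@grid_shape
  comp <- array(0, c(shape, 6L))
  ## background isotropic
  comp[, , , 1] <- spec@d_iso; comp[, , , 2] <- spec@d_iso
  comp[, , , 3] <- spec@d_iso
  masks <- list()
  setDiag <- function(mask, dx, dy, dz) {
    idx <- which(mask)
    n <- prod(shape)
    comp[idx] <<- dx; comp[idx + n] <<- dy; comp[idx + 2 * n] <<- dz
  }
  for (side in c("left", "right")) {
    m <- .boxMask(shape, spec@proj_region[[side]])
    masks[[paste0("proj_", side)]] <- m
    setDiag(m, spec@d_perp, spec@d_perp, spec@d_parallel)
    m <- .boxMask(shape, spec@assoc_region[[side]])
    masks[[paste0("assoc_", side)]] <- m
    setDiag(m, spec@d_perp, spec@d_parallel, spec@d_perp)
    m <- .boxMask(shape, spec@cc_region[[side]])
    masks[[paste0("cc_", side)]] <- m
    setDiag(m, spec@d_parallel, spec@d_perp, spec@d_perp)
  }
  masks$ventricle <- .boxMask(shape, spec@ventricle_region)
  setDiag(masks$ventricle, spec@d_csf, spec@d_csf, spec@d_csf)
  slab <- array(FALSE, shape)
  slab[, , spec@slab_z[1]:spec@slab_z[2]] <- TRUE
  masks$slab <- slab
  ## perivascular enhancement of the x-axis diffusivity at ventricle level
  enh <- slab & (masks$proj_left | masks$proj_right |
                 masks$assoc_left | masks$assoc_right)
  idx <- which(enh)
  comp[idx] <- comp[idx] * spec@perivascular_gain
  tensor <- new("TensorVolume", components = comp,
                affine = .canonicalAffine(shape, spec@voxel_size),
                valid = array(TRUE, shape))
  list(tensor = tensor, masks = masks,
       ground_truth_alps = spec@perivascular_gain)
}

#' Simulate a diffusion-weighted series from a tensor volume
#'
#' Per volume i the noiseless signal is the single-tensor model
#' S_i = s0 * exp(-b_i g_i' D g_i); additive Gaussian noise of SD
#' `noise_sd` is the default, Rician noise (magnitude of the complex
#' Gaussian-corrupted signal) optional.  Deterministic given `seed`.
#'
#' @param tensor a [TensorVolume].
#' @param gtab a [GradientTable] with >= 6 unique nonzero directions and
#'   >= 1 b = 0 volume.
#' @param s0 non-diffusion-weighted signal.
#' @param noise_sd noise SD in signal units (0 = noiseless).
#' @param noise_model "gaussian" or "rician".
#' @param seed integer RNG seed.
#' @return list with `dwi` (4-D array), `gtab`, and `affine`.
#' @export
phantomToDwi <- function(tensor, gtab = defaultGradientTable(),
                         s0 = 1, noise_sd = 0,
                         noise_model = c("gaussian", "rician"),
                         seed = 42L) {
  stopifnot(is(tensor, "TensorVolume"), is(gtab, "GradientTable"))
  noise_model <- match.arg(noise_model)
  nz <- gtab@bvals > 0
  uniq <- unique(round(t(gtab@bvecs[, nz, drop = FALSE]), 6))
  if (nrow(uniq) < 6L)
    stop("tensor unidentifiable: need >= 6 unique nonzero gradient directions, got ",
         nrow(uniq))
  if (!any(!nz)) stop("need at least one b = 0 volume")
  shape <- dim(tensor@components)[1:3]
  nvox <- prod(shape); nvol <- length(gtab@bvals)
  C <- matrix(tensor@components, nvox, 6L)
  g <- gtab@bvecs
  ## rows match component order Dxx,Dyy,Dzz,Dxy,Dxz,Dyz
  M <- rbind(g[1, ]^2, g[2, ]^2, g[3, ]^2,
             2 * g[1, ] * g[2, ], 2 * g[1, ] * g[3, ], 2 * g[2, ] * g[3, ])
  Q <- C %*% sweep(M, 2, gtab@bvals, "*")      # nvox x nvol, b g'Dg
  S <- s0 * exp(-Q)
  if (noise_sd > 0) {
    set.seed(seed)
    if (noise_model == "gaussian") {
      S <- S + stats::rnorm(length(S), 0, noise_sd)
    } else {
      S <- sqrt((S + stats::rnorm(length(S), 0, noise_sd))^2 +
                stats::rnorm(length(S), 0, noise_sd)^2)
    }
  }
  list(dwi = array(S, c(shape, nvol)), gtab = gtab, affine = tensor@affine)
}
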