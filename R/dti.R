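## Reading diffusion data, canonical axis convention, log-linear tensor fit.

#' Read a diffusion-weighted series with its gradient scheme
#'
#' @param dwi_path path to a 4-D NIfTI volume.
#' @param bval_path,bvec_path FSL-style gradient text files.
#' @return list with `dwi` (4-D array), `gtab` (a [GradientTable]) and
#'   `affine` (4 x 4 voxel-to-world, 1-based voxel indices).
#' @export
readDwi <- function(dwi_path, bval_path, bvec_path) {
  img <- RNifti::readNifti(dwi_path)
  if (length(dim(img)) != 4L)
    stop("expected a 4-D diffusion series, got ", length(dim(img)), "-D image")
  gtab <- readGradients(bval_path, bvec_path, n_volumes = dim(img)[4])
  list(dwi = unclass(img)[, , , , drop = FALSE],
       gtab = gtab, affine = .affineOf(img))
}

#' Read / write a 6-component tensor volume as NIfTI
#'
#' Components are stored in the 4th dimension in the order
#' Dxx, Dyy, Dzz, Dxy, Dxz, Dyz.
#'
#' @param path NIfTI file path (.nii or .nii.gz).
#' @return `readTensor`: a [TensorVolume]; voxels with any non-finite
#'   component are flagged invalid.
#' @export
readTensor <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L || d[4] != 6L)
    stop("expected a 4-D NIfTI with 6 tensor components, got dim ",
         paste(d, collapse = "x"))
  comp <- array(as.numeric(img), d)
  valid <- array(rowSums(!is.finite(matrix(comp, prod(d[1:3]), 6L))) == 0L,
                 d[1:3])
  new("TensorVolume", components = comp, affine = .affineOf(img),
      valid = valid)
}

#' @rdname readTensor
#' @param tensor a [TensorVolume] to write.
#' @export
writeTensor <- function(tensor, path) {
  stopifnot(is(tensor, "TensorVolume"))
  .writeNiftiArray(tensor@components, tensor@affine, path)
}

#' Write a diffusion-weighted series and its gradient files
#'
#' @param dwi list as returned by [phantomToDwi()] or [readDwi()].
#' @param dwi_path,bval_path,bvec_path output paths.
#' @export
writeDwi <- function(dwi, dwi_path, bval_path, bvec_path) {
  .writeNiftiArray(dwi$dwi, dwi$affine, dwi_path)
  writeGradients(dwi$gtab, bval_path, bvec_path)
  invisible(dwi_path)
}

## RNifti's xform maps 0-based voxel indices to world; convert to 1-based.
.affineOf <- function(img) {
  x <- structure(RNifti::xform(img), code = NULL)
  aff <- matrix(as.numeric(x), 4, 4)
  aff[1:3, 4] <- aff[1:3, 4] - aff[1:3, 1:3] %*% rep(1, 3)
  aff
}

.writeNiftiArray <- function(arr, affine, path) {
  aff0 <- affine
  aff0[1:3, 4] <- aff0[1:3, 4] + aff0[1:3, 1:3] %*% rep(1, 3)  # back to 0-based
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(sqrt(colSums(aff0[1:3, 1:3]^2)),
                           rep(1, length(dim(arr)) - 3L))
  img <- RNifti::`sform<-`(img, structure(aff0, code = 2L))
  img <- RNifti::`qform<-`(img, structure(aff0, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

## ---------------------------------------------------------------------------
## Canonical reorientation
## ---------------------------------------------------------------------------

## Decompose the affine's rotation part into a signed axis permutation:
## world axis of each voxel axis and its sign.  Returns perm (voxel axis
## feeding each world axis), sign, and the worst-case obliquity in degrees.
.axisPermutation <- function(affine) {
  R <- affine[1:3, 1:3]
  Rn <- sweep(R, 2, sqrt(colSums(R^2)), "/")
  world_of <- integer(3); sgn <- numeric(3); obli <- 0
  for (j in 1:3) {
    i <- which.max(abs(Rn[, j]))
    world_of[j] <- i
    sgn[j] <- sign(Rn[i, j])
    obli <- max(obli, acos(min(1, abs(Rn[i, j]))) * 180 / pi)
  }
  if (length(unique(world_of)) != 3L)
    stop("degenerate affine: voxel axes do not map to distinct world axes")
  perm <- match(1:3, world_of)   # voxel axis feeding world axis i
  list(perm = perm, sign = sgn[perm], obliquity = obli)
}

## Reorient a 3-D (or 4-D, spatial-first) array given perm/sign, and return
## the updated affine.
.reorientArray <- function(arr, affine, ax) {
  d <- dim(arr)
  spatial <- d[1:3]
  extra <- if (length(d) > 3L) seq(4L, length(d)) else integer(0)
  arr2 <- aperm(arr, c(ax$perm, extra))
  idx <- lapply(1:3, function(i) {
    n <- dim(arr2)[i]
    if (ax$sign[i] < 0) n:1 else 1:n
  })
  args <- c(list(arr2), idx,
            lapply(extra, function(e) seq_len(dim(arr2)[e - 0])),
            list(drop = FALSE))
  ## build do.call index list of correct length
  full <- vector("list", length(dim(arr2)))
  for (i in 1:3) full[[i]] <- idx[[i]]
  if (length(extra)) for (e in seq_along(extra))
    full[[3L + e]] <- seq_len(dim(arr2)[3L + e])
  arr3 <- do.call(`[`, c(list(arr2), full, list(drop = FALSE)))
  ## new affine: old voxel index as a function of new index
  P <- matrix(0, 4, 4); P[4, 4] <- 1
  newdim <- spatial[ax$perm]
  for (i in 1:3) {
    j <- ax$perm[i]                       # old voxel axis on new axis i
    if (ax$sign[i] > 0) { P[j, i] <- 1 } else {
      P[j, i] <- -1; P[j, 4] <- newdim[i] + 1
    }
  }
  list(arr = arr3, affine = affine %*% P)
}

#' @describeIn reorientToCanonical permutes/flips the grid and rotates the
#'   tensor components with the signed permutation.
#' @param tol maximal tolerated obliquity in degrees before a warning is
#'   issued (the nearest-axis permutation is applied either way).
#' @export
setMethod("reorientToCanonical", "TensorVolume", function(x, tol = 1e-3) {
  ax <- .axisPermutation(x@affine)
  if (ax$obliquity > tol)
    warning(sprintf("affine is oblique by %.2f degrees; applying nearest-axis permutation",
                    ax$obliquity))
  if (identical(ax$perm, 1:3) && all(ax$sign > 0)) return(x)
  rc <- .reorientArray(x@components, x@affine, ax)
  rv <- .reorientArray(x@valid, x@affine, ax)
  ## rotate tensor: D'_{ab} = s_a s_b D_{perm(a) perm(b)}
  p <- ax$perm; s <- ax$sign
  pairidx <- matrix(c(1, 1, 2, 2, 3, 3, 1, 2, 1, 3, 2, 3), ncol = 2, byrow = TRUE)
  compOf <- function(a, b) {
    if (a == b) return(a)
    k <- sort(c(a, b))
    if (all(k == c(1, 2))) 4L else if (all(k == c(1, 3))) 5L else 6L
  }
  d <- dim(rc$arr); n <- prod(d[1:3])
  flat <- matrix(rc$arr, n, 6L)
  out <- flat
  for (m in 1:6) {
    a <- pairidx[m, 1]; b <- pairidx[m, 2]
    src <- compOf(p[a], p[b])
    out[, m] <- s[a] * s[b] * flat[, src]
  }
  new("TensorVolume", components = array(out, d), affine = rc$affine,
      valid = array(as.logical(rv$arr), d[1:3]))
})

#' @describeIn reorientToCanonical permutes/flips the grid only.
#' @export
setMethod("reorientToCanonical", "ScalarMap", function(x, tol = 1e-3) {
  ax <- .axisPermutation(x@affine)
  if (ax$obliquity > tol)
    warning(sprintf("affine is oblique by %.2f degrees; applying nearest-axis permutation",
                    ax$obliquity))
  if (identical(ax$perm, 1:3) && all(ax$sign > 0)) return(x)
  r <- .reorientArray(x@data, x@affine, ax)
  new("ScalarMap", data = r$arr, affine = r$affine)
})

## ---------------------------------------------------------------------------
## Log-linear tensor fit
## ---------------------------------------------------------------------------

#' Fit diffusion tensors by log-linear least squares
#'
#' Per voxel, solves ln S_i = ln S0 - b_i g_i' D g_i by unweighted ordinary
#' least squares over all volumes.  Voxels with any non-positive signal (or
#' outside `mask`) are flagged invalid and not fitted.  No eigenvalue
#' clamping is applied; downstream code consults the validity mask.
#'
#' @param dwi 4-D array (or list from [readDwi()]/[phantomToDwi()]).
#' @param gtab a [GradientTable] (ignored if `dwi` is a list carrying one).
#' @param mask optional logical 3-D array restricting the fit.
#' @param affine 4 x 4 affine (ignored if `dwi` is a list).
#' @return a [TensorVolume].
#' @export
fitTensorLogLinear <- function(dwi, gtab = NULL, mask = NULL, affine = NULL) {
  if (is.list(dwi)) {
    gtab <- dwi$gtab; affine <- dwi$affine; dwi <- dwi$dwi
  }
  stopifnot(is(gtab, "GradientTable"))
  if (is.null(affine)) affine <- diag(4)
  d <- dim(dwi)
  if (length(d) != 4L) stop("dwi must be 4-D")
  if (d[4] != length(gtab@bvals))
    stop("volume count (", d[4], ") does not match gradient table (",
         length(gtab@bvals), ")")
  nz <- gtab@bvals > 0
  uniq <- unique(round(t(gtab@bvecs[, nz, drop = FALSE]), 6))
  if (nrow(uniq) < 6L || !any(!nz))
    stop("rank-deficient gradient scheme: need >= 6 unique nonzero directions ",
         "plus a b = 0 volume (got ", nrow(uniq), " directions, ",
         sum(!nz), " b = 0)")
  g <- gtab@bvecs
  X <- cbind(1, -gtab@bvals * t(rbind(
    g[1, ]^2, g[2, ]^2, g[3, ]^2,
    2 * g[1, ] * g[2, ], 2 * g[1, ] * g[3, ], 2 * g[2, ] * g[3, ])))
  if (qr(X)$rank < 7L)
    stop("rank-deficient gradient scheme: design matrix rank ",
         qr(X)$rank, " < 7")
  nvox <- prod(d[1:3])
  S <- matrix(dwi, nvox, d[4])
  ok <- rowSums(!is.finite(S) | S <= 0) == 0L
  if (!is.null(mask)) ok <- ok & as.vector(mask)
  B <- matrix(NA_real_, nvox, 7L)
  if (any(ok)) {
    ## one QR solve for all voxels: coefficients (7 x nvox_ok)
    B[ok, ] <- t(qr.coef(qr(X), t(log(S[ok, , drop = FALSE]))))
  }
  comp <- array(B[, 2:7], c(d[1:3], 6L))
  new("TensorVolume", components = comp, affine = affine,
      valid = array(ok, d[1:3]))
}
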