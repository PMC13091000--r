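## Scalar and direction maps derived from a tensor volume.

#' @describeIn tensorComponents diagonal component maps of a tensor volume
#' @export
setMethod("tensorComponents", "TensorVolume", function(x, ...) {
  mk <- function(k) {
    a <- x@components[, , , k, drop = TRUE]
    a[!x@valid] <- NA_real_
    new("ScalarMap", data = array(a, dim(x@valid)), affine = x@affine)
  }
  list(Dxx = mk(1L), Dyy = mk(2L), Dzz = mk(3L))
})

#' @describeIn faMap fractional anisotropy from tensor invariants
#'
#' FA is computed from rotational invariants (trace and Frobenius norm), so
#' no eigen-decomposition is needed:
#' FA^2 = (3/2) (tr(D^2) - tr(D)^2 / 3) / tr(D^2).
#' @export
setMethod("faMap", "TensorVolume", function(x, ...) {
  d <- dim(x@valid)
  C <- matrix(x@components, prod(d), 6L)
  tr <- C[, 1] + C[, 2] + C[, 3]
  fro2 <- C[, 1]^2 + C[, 2]^2 + C[, 3]^2 + 2 * (C[, 4]^2 + C[, 5]^2 + C[, 6]^2)
  fa <- sqrt(pmax(0, 1.5 * (fro2 - tr^2 / 3) / pmax(fro2, .Machine$double.xmin)))
  fa <- pmin(fa, 1)
  fa[!as.vector(x@valid) | !is.finite(fa)] <- NA_real_
  new("ScalarMap", data = array(fa, d), affine = x@affine)
})

## Deterministic sign: first component nonzero -> nonnegative, else second,
## else third.  Keeps automated placement dot-product tests reproducible.
.fixSign <- function(v, tol = 1e-12) {
  k <- which(abs(v) > tol)
  if (length(k) && v[k[1]] < 0) -v else v
}

#' @describeIn principalDirection unit eigenvector of the largest
#'   eigenvalue per valid voxel (NA elsewhere)
#' @param mask optional logical array restricting computation (e.g. a slab).
#' @export
setMethod("principalDirection", "TensorVolume", function(x, mask = NULL, ...) {
  d <- dim(x@valid)
  out <- array(NA_real_, c(d, 3L))
  sel <- x@valid
  if (!is.null(mask)) sel <- sel & mask
  idx <- which(sel)
  n <- prod(d)
  C <- matrix(x@components, n, 6L)
  for (i in idx) {
    D <- matrix(c(C[i, 1], C[i, 4], C[i, 5],
                  C[i, 4], C[i, 2], C[i, 6],
                  C[i, 5], C[i, 6], C[i, 3]), 3, 3)
    if (any(!is.finite(D))) next
    e <- eigen(D, symmetric = TRUE)
    v <- .fixSign(e$vectors[, 1])
    out[i] <- v[1]; out[i + n] <- v[2]; out[i + 2 * n] <- v[3]
  }
  new("VectorMap", data = out, affine = x@affine)
})
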