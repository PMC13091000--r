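#' Construct a gradient table
#'
#' @param bvals numeric vector of b-values (s/mm^2), one per volume.
#' @param bvecs 3 x n matrix (or n x 3, auto-transposed) of directions.
#' @return a [GradientTable].
#' @export
gradientTable <- function(bvals, bvecs) {
  bvecs <- as.matrix(bvecs)
  if (nrow(bvecs) != 3L && ncol(bvecs) == 3L) bvecs <- t(bvecs)
  new("GradientTable", bvals = as.numeric(bvals), bvecs = bvecs)
}

#' Default single-shell acquisition scheme
#'
#' One b = 0 volume followed by `n_dirs` diffusion-weighted directions at
#' b-value `b`, spread quasi-uniformly over the hemisphere by a Fibonacci
#' spiral.  The default mirrors a standard clinical 30-direction
#' b = 1000 s/mm^2 protocol.
#'
#' @param n_dirs number of diffusion-weighted directions.
#' @param b shell b-value (s/mm^2).
#' @param n_b0 number of leading b = 0 volumes.
#' @return a [GradientTable].
#' @export
defaultGradientTable <- function(n_dirs = 30L, b = 1000, n_b0 = 1L) {
  i <- seq_len(n_dirs) - 0.5
  phi <- pi * (1 + sqrt(5)) * i          # golden-angle longitude
  z <- i / n_dirs                        # hemisphere: cos(theta) in (0,1)
  r <- sqrt(pmax(0, 1 - z^2))
  dirs <- rbind(r * cos(phi), r * sin(phi), z)
  dirs <- sweep(dirs, 2, sqrt(colSums(dirs^2)), "/")
  gradientTable(c(rep(0, n_b0), rep(b, n_dirs)),
                cbind(matrix(0, 3, n_b0), dirs))
}

#' Read / write FSL-style bval and bvec files
#'
#' `readGradients` expects whitespace-separated text: a single row of
#' b-values and three rows of direction components.  Counts must agree;
#' `n_volumes`, when given, is validated against them.
#'
#' @param bval_path,bvec_path file paths.
#' @param n_volumes optional expected number of volumes.
#' @return a [GradientTable].
#' @export
readGradients <- function(bval_path, bvec_path, n_volumes = NULL) {
  bvals <- scan(bval_path, quiet = TRUE)
  bv <- as.matrix(utils::read.table(bvec_path))
  if (nrow(bv) != 3L)
    stop("bvec file must have exactly 3 rows, found ", nrow(bv))
  if (ncol(bv) != length(bvals))
    stop("gradient count mismatch: ", length(bvals), " bvals vs ",
         ncol(bv), " bvecs")
  if (!is.null(n_volumes) && n_volumes != length(bvals))
    stop("gradient count mismatch: ", length(bvals), " gradients vs ",
         n_volumes, " volumes")
  gradientTable(bvals, bv)
}

#' @rdname readGradients
#' @param gtab a [GradientTable] to write.
#' @export
writeGradients <- function(gtab, bval_path, bvec_path) {
  stopifnot(is(gtab, "GradientTable"))
  writeLines(paste(format(gtab@bvals, trim = TRUE), collapse = " "), bval_path)
  writeLines(apply(gtab@bvecs, 1, function(r)
    paste(format(r, trim = TRUE, digits = 10), collapse = " ")), bvec_path)
  invisible(c(bval_path, bvec_path))
}
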