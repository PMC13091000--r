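## Automated ROI placement, ROI aggregation, the ALPS index and CC control.

#' Construct automated-placement parameters
#'
#' Defaults (theta_class 30 deg, theta_exclude_x 30 deg, fa_min 0.15,
#' radius 5 mm) classify the phantom bundles unambiguously and are all
#' configurable; see [AutoPlacementParams] for the rules.
#'
#' @param slab_z inclusive z-index range of the periventricular slab.
#' @param fa_min minimum FA for candidate voxels.
#' @param theta_class degrees, max angle between e1 and the class axis.
#' @param theta_exclude_x degrees, min angle to the x axis required.
#' @param radius_mm ROI sphere radius.
#' @param min_cluster_voxels minimal acceptable candidate-cluster size.
#' @return an [AutoPlacementParams].
#' @export
autoPlacementParams <- function(slab_z, fa_min = 0.15, theta_class = 30,
                                theta_exclude_x = 30, radius_mm = 5,
                                min_cluster_voxels = 5L) {
  new("AutoPlacementParams", slab_z = as.integer(slab_z),
      fa_min = fa_min, theta_class = theta_class,
      theta_exclude_x = theta_exclude_x, radius_mm = radius_mm,
      min_cluster_voxels = as.integer(min_cluster_voxels))
}

## Label 26-connected components of a logical 3-D array by breadth-first
## search; returns integer labels (0 = background).  No installed package
## offers 3-D labelling, so this is done by hand on the (small) candidate
## masks.
.labelComponents <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  idx <- which(mask)
  if (!length(idx)) return(lab)
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(off != 0) > 0, ]
  cur <- 0L
  for (seed in idx) {
    if (lab[seed] != 0L) next
    cur <- cur + 1L
    queue <- seed
    lab[seed] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      z <- (v - 1L) %/% (d[1] * d[2])
      r <- (v - 1L) %% (d[1] * d[2])
      vox <- c(r %% d[1] + 1L, r %/% d[1] + 1L, z + 1L)
      nb <- sweep(off, 2, vox, "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
            nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- nb[, 1] + d[1] * (nb[, 2] - 1L) + d[1] * d[2] * (nb[, 3] - 1L)
      lin <- lin[mask[lin] & lab[lin] == 0L]
      if (length(lin)) { lab[lin] <- cur; queue <- c(queue, lin) }
    }
  }
  lab
}

## Centroid of the largest labelled cluster; NULL when all clusters are
## smaller than min_size.
.largestClusterCentroid <- function(mask, min_size) {
  lab <- .labelComponents(mask)
  if (!any(lab > 0L)) return(NULL)
  sizes <- tabulate(lab)
  if (max(sizes) < min_size) return(NULL)
  best <- which.max(sizes)
  idx <- which(lab == best, arr.ind = TRUE)
  colMeans(idx)
}

#' Automated placement of the periventricular ALPS ROIs
#'
#' Within the axial slab, voxels with FA >= `fa_min` are classified by
#' their principal direction: within `theta_class` degrees of the
#' inferior-superior axis they are projection candidates, of the
#' anterior-posterior axis association candidates.  Voxels closer than
#' `theta_exclude_x` degrees of complement to the right-left axis (i.e.
#' |e1 . x| >= sin(theta_exclude_x)) are dropped from both classes, so
#' fibers crossing in the perivascular direction never contribute.  The
#' hemisphere split is the mid-sagittal plane at `midline_x` (default: the
#' volume's x center).  Per side and class, the centroid of the largest
#' 26-connected candidate cluster becomes a spherical ROI of
#' `radius_mm`.
#'
#' @param fa a [ScalarMap] of fractional anisotropy.
#' @param e1 a [VectorMap] of principal directions.
#' @param params an [AutoPlacementParams].
#' @param midline_x hemisphere split in voxel coordinates.
#' @param include_cc also place bilateral corpus-callosum control ROIs
#'   (x-aligned candidates near the midline).
#' @return a [RoiSet] with 4 ROIs (6 with `include_cc`).
#' @export
placeRoisAuto <- function(fa, e1, params, midline_x = NULL,
                          include_cc = FALSE) {
  stopifnot(is(fa, "ScalarMap"), is(e1, "VectorMap"),
            is(params, "AutoPlacementParams"))
  d <- dim(fa@data)
  if (params@slab_z[1] < 1L || params@slab_z[2] > d[3])
    stop("slab outside volume")
  if (is.null(midline_x)) midline_x <- (d[1] + 1) / 2
  slab <- array(FALSE, d)
  slab[, , params@slab_z[1]:params@slab_z[2]] <- TRUE
  faok <- !is.na(fa@data) & fa@data >= params@fa_min & slab
  ex <- abs(e1@data[, , , 1]) >= sin(params@theta_exclude_x * pi / 180)
  ex[is.na(ex)] <- TRUE
  cosc <- cos(params@theta_class * pi / 180)
  proj <- faok & !ex & !is.na(e1@data[, , , 3]) & abs(e1@data[, , , 3]) >= cosc
  asso <- faok & !ex & !is.na(e1@data[, , , 2]) & abs(e1@data[, , , 2]) >= cosc
  xidx <- array(rep(seq_len(d[1]), prod(d[2:3])), d)
  hemis <- list(left = xidx < midline_x, right = xidx > midline_x)
  classes <- list(projection = proj, association = asso)
  if (include_cc) {
    cc <- faok & !is.na(e1@data[, , , 1]) & abs(e1@data[, , , 1]) >= cosc
    classes$cc_control <- cc
  }
  rows <- list()
  for (cl in names(classes)) for (side in names(hemis)) {
    cen <- .largestClusterCentroid(classes[[cl]] & hemis[[side]],
                                   params@min_cluster_voxels)
    if (is.null(cen))
      stop("automated placement failed: no candidate cluster of >= ",
           params@min_cluster_voxels, " voxels for ", side, " ", cl)
    rows[[paste(side, cl)]] <- data.frame(
      side = side, fiber_class = cl,
      cx = cen[1], cy = cen[2], cz = cen[3],
      radius_mm = params@radius_mm, stringsAsFactors = FALSE)
  }
  new("RoiSet", rois = do.call(rbind, c(rows, list(make.row.names = FALSE))),
      affine = fa@affine)
}

#' Manually specified ROI set
#'
#' @param side,fiber_class,cx,cy,cz,radius_mm vectors of equal length
#'   (voxel-space centers, 1-based, fractional allowed).
#' @param affine 4 x 4 voxel-to-world transform of the reference volume.
#' @return a [RoiSet].
#' @export
roiSet <- function(side, fiber_class, cx, cy, cz, radius_mm,
                   affine = diag(4)) {
  new("RoiSet", rois = data.frame(side = side, fiber_class = fiber_class,
                                  cx = cx, cy = cy, cz = cz,
                                  radius_mm = radius_mm,
                                  stringsAsFactors = FALSE),
      affine = affine)
}

## logical mask of voxels whose centers fall within radius_mm of the
## (voxel-space) center, distances measured in world mm via the affine.
.sphereMask <- function(dim3, affine, center_vox, radius_mm) {
  A <- affine[1:3, 1:3]; t0 <- affine[1:3, 4]
  cworld <- A %*% center_vox + t0
  ## bounding box in voxel space to avoid full-grid distance computation
  vox_mm <- sqrt(colSums(A^2))
  lo <- pmax(1L, floor(center_vox - radius_mm / vox_mm - 1))
  hi <- pmin(dim3, ceiling(center_vox + radius_mm / vox_mm + 1))
  if (any(lo > hi)) return(array(FALSE, dim3))
  gx <- lo[1]:hi[1]; gy <- lo[2]:hi[2]; gz <- lo[3]:hi[3]
  grid <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  w <- t(A %*% t(grid)) + matrix(rep(t0, each = nrow(grid)), ncol = 3)
  inside <- rowSums(sweep(w, 2, as.vector(cworld))^2) <= radius_mm^2
  m <- array(FALSE, dim3)
  m[grid[inside, , drop = FALSE]] <- TRUE
  m
}

#' Mean of a scalar map over a spherical ROI
#'
#' Aggregates over voxels whose centers lie within the sphere; the
#' statistic is the arithmetic mean by default (median via `stat`).
#'
#' @param map a [ScalarMap].
#' @param roi single-row data.frame with cx, cy, cz (voxel) and radius_mm,
#'   or a [RoiSet] row index via `which_roi`.
#' @param affine affine of the map (defaults to `map@affine`).
#' @param stat "mean" or "median".
#' @return list with `value` and `n_voxels`.
#' @export
extractRoiMean <- function(map, roi, affine = NULL, stat = c("mean", "median")) {
  stat <- match.arg(stat)
  if (is(roi, "RoiSet")) roi <- roi@rois[1, ]
  if (is.null(affine)) affine <- map@affine
  m <- .sphereMask(dim(map@data), affine,
                   c(roi$cx, roi$cy, roi$cz), roi$radius_mm)
  vals <- map@data[m]
  vals <- vals[is.finite(vals)]
  if (!length(vals))
    stop("ROI at (", roi$cx, ",", roi$cy, ",", roi$cz,
         ") contains no valid voxels")
  list(value = if (stat == "mean") mean(vals) else stats::median(vals),
       n_voxels = length(vals))
}

#' Compute the ALPS index from component maps and an ROI set
#'
#' Per hemisphere the index is
#' \deqn{ALPS = mean(Dx_{proj}, Dx_{assoc}) / mean(Dy_{proj}, Dz_{assoc})}
#' i.e. diffusivity along the presumed perivascular (right-left) axis in
#' projection and association fiber ROIs over the fiber-orthogonal
#' diffusivities.  The bilateral value is the mean of the two hemispheres
#' and is only reported when both are valid; a non-positive denominator
#' invalidates that hemisphere and is flagged.
#'
#' @param dxx,dyy,dzz [ScalarMap]s of the diagonal tensor components.
#' @param rois a [RoiSet] with projection and association ROIs per side.
#' @param stat aggregation statistic, "mean" (default) or "median".
#' @return an [AlpsMeasurement].
#' @export
computeAlps <- function(dxx, dyy, dzz, rois, stat = "mean") {
  stopifnot(is(rois, "RoiSet"))
  r <- rois@rois
  sides <- c("left", "right")
  means <- data.frame(side = sides, Dx_proj = NA_real_, Dx_assoc = NA_real_,
                      Dy_proj = NA_real_, Dz_assoc = NA_real_,
                      n_proj = NA_integer_, n_assoc = NA_integer_,
                      stringsAsFactors = FALSE)
  alps <- c(left = NA_real_, right = NA_real_)
  flags <- character(0)
  for (s in sides) {
    pr <- r[r$side == s & r$fiber_class == "projection", ]
    as_ <- r[r$side == s & r$fiber_class == "association", ]
    if (nrow(pr) != 1L || nrow(as_) != 1L)
      stop("need exactly one projection and one association ROI per side; ",
           "missing for side ", s)
    xp <- extractRoiMean(dxx, pr, rois@affine, stat)
    xa <- extractRoiMean(dxx, as_, rois@affine, stat)
    yp <- extractRoiMean(dyy, pr, rois@affine, stat)
    za <- extractRoiMean(dzz, as_, rois@affine, stat)
    i <- means$side == s
    means[i, c("Dx_proj", "Dx_assoc", "Dy_proj", "Dz_assoc")] <-
      c(xp$value, xa$value, yp$value, za$value)
    means[i, c("n_proj", "n_assoc")] <- c(xp$n_voxels, za$n_voxels)
    den <- mean(c(yp$value, za$value))
    if (!is.finite(den) || den <= 0) {
      flags <- c(flags, paste0("invalid_denominator_", s))
    } else {
      alps[s] <- mean(c(xp$value, xa$value)) / den
    }
  }
  bil <- if (all(is.finite(alps))) mean(alps) else NA_real_
  if (!all(is.finite(alps))) flags <- c(flags, "bilateral_unavailable")
  if (!length(flags)) flags <- "ok"
  new("AlpsMeasurement", means = means,
      alps_left = unname(alps["left"]), alps_right = unname(alps["right"]),
      alps_bilateral = bil, qc_flags = flags)
}

#' Corpus-callosum Dxx negative control
#'
#' Mean right-left diffusivity in bilateral CC ROIs at the same axial level
#' as the ALPS ROIs; the resulting per-scan values feed the same
#' mixed-effects framework as the ALPS index, with the opposite expected
#' direction of group effects.
#'
#' @param dxx a [ScalarMap] of Dxx.
#' @param rois a [RoiSet] containing `cc_control` ROIs for both sides.
#' @param stat aggregation statistic.
#' @return list with `cc_left`, `cc_right`, `cc_bilateral` (mm^2/s).
#' @export
computeCcControl <- function(dxx, rois, stat = "mean") {
  stopifnot(is(rois, "RoiSet"))
  r <- rois@rois[rois@rois$fiber_class == "cc_control", ]
  if (nrow(r) < 1L) stop("no cc_control ROIs in the set")
  out <- c(cc_left = NA_real_, cc_right = NA_real_)
  for (s in c("left", "right")) {
    rs <- r[r$side == s, ]
    if (nrow(rs) == 1L)
      out[paste0("cc_", s)] <- extractRoiMean(dxx, rs, rois@affine, stat)$value
  }
  c(as.list(out), cc_bilateral = mean(out, na.rm = TRUE))
}

## ---------------------------------------------------------------------------
## ROI JSON I/O
## ---------------------------------------------------------------------------

#' Read / write ROI sets as JSON
#'
#' The JSON records centers, radii, sides and fiber classes together with a
#' coordinate-space tag; voxel space (1-based indices) is the native
#' representation, mm centers are converted through the affine.
#'
#' @param rois a [RoiSet].
#' @param path JSON file path.
#' @param space "voxel" or "mm" for the written centers.
#' @export
writeRoiSet <- function(rois, path, space = c("voxel", "mm")) {
  space <- match.arg(space)
  r <- rois@rois
  if (space == "mm") {
    A <- rois@affine[1:3, 1:3]; t0 <- rois@affine[1:3, 4]
    w <- t(A %*% t(as.matrix(r[, c("cx", "cy", "cz")]))) +
      matrix(rep(t0, each = nrow(r)), ncol = 3)
    r[, c("cx", "cy", "cz")] <- w
  }
  jsonlite::write_json(list(space = space, affine = rois@affine, rois = r),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeRoiSet
#' @return `readRoiSet`: a [RoiSet] in voxel space.
#' @export
readRoiSet <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  aff <- matrix(unlist(x$affine), 4, 4)
  r <- as.data.frame(x$rois)
  if (identical(x$space, "mm")) {
    A <- aff[1:3, 1:3]; t0 <- aff[1:3, 4]
    v <- t(solve(A) %*% (t(as.matrix(r[, c("cx", "cy", "cz")])) - t0))
    r[, c("cx", "cy", "cz")] <- v
  }
  new("RoiSet", rois = r, affine = aff)
}

#' Binary NIfTI mask for one ROI
#'
#' @param rois a [RoiSet]; `which_roi` selects the row.
#' @param dim3 spatial grid dimensions of the reference volume.
#' @param path output NIfTI path.
#' @param which_roi row index.
#' @export
writeRoiMask <- function(rois, dim3, path, which_roi = 1L) {
  r <- rois@rois[which_roi, ]
  m <- .sphereMask(dim3, rois@affine, c(r$cx, r$cy, r$cz), r$radius_mm)
  .writeNiftiArray(array(as.integer(m), dim3), rois@affine, path)
}
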