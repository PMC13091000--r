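#' @import methods
NULL

## ---------------------------------------------------------------------------
## Imaging containers
## ---------------------------------------------------------------------------

#' Diffusion gradient table
#'
#' Acquisition scheme for a diffusion-weighted series: one b-value (s/mm^2)
#' and one unit gradient direction per volume, in the FSL bval/bvec
#' convention (directions for b = 0 volumes are ignored and may be zero).
#'
#' @slot bvals numeric vector of b-values, one per volume (s/mm^2).
#' @slot bvecs 3 x n numeric matrix of gradient directions (columns).
#'
#' @seealso [gradientTable()], [defaultGradientTable()]
#' @export
setClass("GradientTable",
  representation(bvals = "numeric", bvecs = "matrix"))

setValidity("GradientTable", function(object) {
  if (ncol(object@bvecs) != length(object@bvals))
    return("number of bvecs columns must equal number of bvals")
  if (nrow(object@bvecs) != 3L)
    return("bvecs must have 3 rows")
  if (any(object@bvals < 0))
    return("bvals must be nonnegative")
  nz <- object@bvals > 0
  if (any(nz)) {
    nrm <- sqrt(colSums(object@bvecs[, nz, drop = FALSE]^2))
    if (any(abs(nrm - 1) > 1e-3))
      return("gradient directions for nonzero b-values must be unit vectors (|norm - 1| <= 1e-3)")
  }
  TRUE
})

#' Per-voxel symmetric diffusion tensor volume
#'
#' Stores the six unique tensor components per voxel in the order
#' Dxx, Dyy, Dzz, Dxy, Dxz, Dyz (mm^2/s), together with the voxel-to-world
#' affine and a validity mask.  After [reorientToCanonical()] the voxel axes
#' follow the radiological convention used throughout: +x right-left,
#' +y anterior-posterior, +z inferior-superior.
#'
#' @slot components 4-D numeric array, dim (nx, ny, nz, 6).
#' @slot affine 4 x 4 voxel-to-world (mm) transform, 1-based voxel indices.
#' @slot valid logical 3-D array flagging voxels with a usable tensor.
#'
#' @export
setClass("TensorVolume",
  representation(components = "array", affine = "matrix", valid = "array"))

setValidity("TensorVolume", function(object) {
  d <- dim(object@components)
  if (length(d) != 4L || d[4] != 6L)
    return("components must be a 4-D array with 6 components in the 4th dimension")
  if (!all(dim(object@affine) == c(4L, 4L)))
    return("affine must be a 4x4 matrix")
  if (!identical(dim(object@valid), d[1:3]))
    return("valid mask must match the spatial grid")
  TRUE
})

#' Scalar map (one value per voxel)
#'
#' @slot data 3-D numeric array.
#' @slot affine 4 x 4 voxel-to-world transform.
#' @export
setClass("ScalarMap", representation(data = "array", affine = "matrix"))

setValidity("ScalarMap", function(object) {
  if (length(dim(object@data)) != 3L) return("data must be a 3-D array")
  if (!all(dim(object@affine) == c(4L, 4L))) return("affine must be 4x4")
  TRUE
})

#' Vector map (one 3-vector per voxel)
#'
#' Used for the principal diffusion direction e1; vectors are unit norm where
#' defined and NA elsewhere, with the sign fixed so the first nonzero
#' component is nonnegative.
#'
#' @slot data 4-D numeric array, dim (nx, ny, nz, 3).
#' @slot affine 4 x 4 voxel-to-world transform.
#' @export
setClass("VectorMap", representation(data = "array", affine = "matrix"))

setValidity("VectorMap", function(object) {
  d <- dim(object@data)
  if (length(d) != 4L || d[4] != 3L) return("data must be (nx,ny,nz,3)")
  if (!all(dim(object@affine) == c(4L, 4L))) return("affine must be 4x4")
  TRUE
})

## ---------------------------------------------------------------------------
## ROI containers
## ---------------------------------------------------------------------------

#' Set of spherical regions of interest
#'
#' Bilateral spherical ROIs over projection / association white matter (and
#' optionally a corpus-callosum control) in voxel coordinates, with the
#' affine of the volume they were placed on.  One row per ROI with columns
#' \code{side} ("left"/"right"), \code{fiber_class} ("projection",
#' "association" or "cc_control"), fractional voxel center \code{cx, cy, cz}
#' (1-based) and \code{radius_mm}.
#'
#' @slot rois data.frame as described above.
#' @slot affine 4 x 4 voxel-to-world transform of the reference volume.
#' @export
setClass("RoiSet", representation(rois = "data.frame", affine = "matrix"))

setValidity("RoiSet", function(object) {
  need <- c("side", "fiber_class", "cx", "cy", "cz", "radius_mm")
  if (!all(need %in% names(object@rois)))
    return(paste("rois must have columns:", paste(need, collapse = ", ")))
  if (any(!object@rois$side %in% c("left", "right")))
    return("side must be 'left' or 'right'")
  if (any(!object@rois$fiber_class %in% c("projection", "association", "cc_control")))
    return("fiber_class must be projection, association or cc_control")
  if (any(object@rois$radius_mm <= 0))
    return("radius_mm must be positive")
  TRUE
})

#' ALPS measurement for one scan
#'
#' The four ROI-mean diffusivities per hemisphere and the derived left /
#' right / bilateral ALPS indices.  The bilateral index is the mean of the
#' two hemispheres and is only defined when both are valid.
#'
#' @slot means data.frame with one row per side: Dx_proj, Dx_assoc, Dy_proj,
#'   Dz_assoc (mm^2/s) and the ROI voxel counts.
#' @slot alps_left,alps_right,alps_bilateral numeric scalars (NA when invalid).
#' @slot qc_flags character vector of quality flags ("ok" when clean).
#' @export
setClass("AlpsMeasurement",
  representation(means = "data.frame", alps_left = "numeric",
                 alps_right = "numeric", alps_bilateral = "numeric",
                 qc_flags = "character"))

#' Parameters for automated periventricular ROI placement
#'
#' Voxels inside the axial slab at the level of the lateral ventricles are
#' classified by their principal diffusion direction: within
#' \code{theta_class} degrees of the inferior-superior axis -> projection
#' candidates; of the anterior-posterior axis -> association candidates.
#' Voxels whose e1 lies within \code{90 - theta_exclude_x} degrees of the
#' right-left axis are excluded from both classes (fibers running with the
#' medullary veins must not contribute).  Per hemisphere the centroid of the
#' largest connected candidate cluster becomes the ROI center.
#'
#' @slot slab_z integer length-2, inclusive z-index range of the slab.
#' @slot fa_min minimum fractional anisotropy for candidacy.
#' @slot theta_class degrees, maximal angle to the class axis.
#' @slot theta_exclude_x degrees, minimal angle to the x axis required.
#' @slot radius_mm ROI radius in mm.
#' @slot min_cluster_voxels minimal size of an acceptable candidate cluster.
#' @export
setClass("AutoPlacementParams",
  representation(slab_z = "integer", fa_min = "numeric",
                 theta_class = "numeric", theta_exclude_x = "numeric",
                 radius_mm = "numeric", min_cluster_voxels = "integer"))

setValidity("AutoPlacementParams", function(object) {
  if (length(object@slab_z) != 2L || object@slab_z[1] > object@slab_z[2])
    return("slab_z must be an increasing index pair")
  if (object@fa_min < 0 || object@fa_min >= 1) return("fa_min must be in [0,1)")
  if (object@theta_class <= 0 || object@theta_class >= 90)
    return("theta_class must be in (0,90) degrees")
  if (object@theta_exclude_x < 0 || object@theta_exclude_x >= 90)
    return("theta_exclude_x must be in [0,90) degrees")
  if (object@radius_mm <= 0) return("radius_mm must be positive")
  TRUE
})

## ---------------------------------------------------------------------------
## Synthetic-data specifications
## ---------------------------------------------------------------------------

#' Specification of a diffusion tensor phantom
#'
#' Describes an axis-aligned digital phantom with projection fibers along
#' the inferior-superior axis, association fibers along the
#' anterior-posterior axis, a corpus-callosum-like right-left bundle and a
#' CSF-like ventricle block, on an isotropic background.  Inside the axial
#' slab at "lateral-ventricle level", the x-axis diffusivity of the
#' projection and association bundles is multiplied by the perivascular gain
#' k, so the ground-truth ALPS index of the slab equals k by construction.
#'
#' Region boxes are 3 x 2 integer matrices of inclusive 1-based voxel index
#' ranges (rows x, y, z); bilateral regions are lists with elements
#' \code{left} and \code{right}.
#'
#' @slot grid_shape integer length-3 voxel grid.
#' @slot voxel_size isotropic voxel edge, mm.
#' @slot slab_z integer length-2 slab index range.
#' @slot proj_region,assoc_region,cc_region lists (left/right) of boxes.
#' @slot ventricle_region single box.
#' @slot d_parallel,d_perp axial/radial bundle eigenvalues, mm^2/s.
#' @slot d_iso background isotropic diffusivity, mm^2/s.
#' @slot d_csf ventricle isotropic diffusivity, mm^2/s.
#' @slot perivascular_gain unitless gain k (> 0).
#' @slot noise_sd default additive noise SD for the DWI stage, signal units.
#' @slot seed integer RNG seed.
#' @export
setClass("PhantomSpec",
  representation(grid_shape = "integer", voxel_size = "numeric",
                 slab_z = "integer", proj_region = "list",
                 assoc_region = "list", cc_region = "list",
                 ventricle_region = "matrix",
                 d_parallel = "numeric", d_perp = "numeric",
                 d_iso = "numeric", d_csf = "numeric",
                 perivascular_gain = "numeric", noise_sd = "numeric",
                 seed = "integer"))

#' Specification of a simulated longitudinal cohort
#'
#' Generative mirror of the trajectory model fitted downstream: per scan
#' \deqn{ALPS_{ij} = \beta_0 + \beta_g G_i + \beta_a agec_{ij} +
#'   \beta_{ga} G_i agec_{ij} + \beta_s S_i + u_{0i} + u_{1i} agec_{ij} +
#'   \epsilon_{ij}}
#' with participant-level random intercept/slope and Gaussian residuals.
#' Within the deletion-carrier group a second binary label (positive
#' psychotic symptoms) with its own age interaction is generated, and a
#' cross-sectional MRS subset carries a Glx/GABA ratio depending linearly
#' and negatively on ALPS.
#'
#' @slot n_hc,n_del participants per group (controls / deletion carriers).
#' @slot scans_range integer length-2, scans per participant (uniform).
#' @slot age_range years; baseline ages are uniform in this range and later
#'   visits exceeding it are dropped.
#' @slot visit_interval_mean,visit_interval_sd years between visits.
#' @slot beta0,beta_group,beta_age,beta_interaction,beta_sex fixed effects
#'   (ALPS units; per year where age is involved).
#' @slot beta_pps,beta_pps_interaction fixed effects of the PPS label within
#'   the deletion group.
#' @slot sd_intercept,sd_slope,sd_resid variance components (SDs).
#' @slot hemi_offset_sd SD of the zero-mean hemispheric offset added to the
#'   latent bilateral value to produce left/right columns.
#' @slot family_sharing_prob probability a new participant joins an existing
#'   family of the same group.
#' @slot mrs_subset_n,mrs_slope,mrs_intercept,mrs_noise_sd,mrs_target_r2
#'   E/I generative parameters; \code{mrs_noise_sd = NA} calibrates the
#'   residual SD from \code{mrs_target_r2} by the closed form
#'   R^2 = s^2 v / (s^2 v + sigma^2) with v the ALPS variance of the subset.
#' @slot seed integer RNG seed.
#' @export
setClass("CohortSpec",
  representation(n_hc = "integer", n_del = "integer",
                 scans_range = "integer", age_range = "numeric",
                 visit_interval_mean = "numeric", visit_interval_sd = "numeric",
                 beta0 = "numeric", beta_group = "numeric",
                 beta_age = "numeric", beta_interaction = "numeric",
                 beta_sex = "numeric", beta_pps = "numeric",
                 beta_pps_interaction = "numeric",
                 sd_intercept = "numeric", sd_slope = "numeric",
                 sd_resid = "numeric", hemi_offset_sd = "numeric",
                 family_sharing_prob = "numeric",
                 mrs_subset_n = "integer", mrs_slope = "numeric",
                 mrs_intercept = "numeric", mrs_noise_sd = "numeric",
                 mrs_target_r2 = "numeric", seed = "integer"))

setValidity("CohortSpec", function(object) {
  if (object@n_hc < 1L || object@n_del < 1L) return("need >= 1 participant per group")
  if (length(object@scans_range) != 2L || object@scans_range[1] < 1L ||
      object@scans_range[1] > object@scans_range[2])
    return("scans_range must be an increasing pair with min >= 1")
  if (length(object@age_range) != 2L || object@age_range[1] >= object@age_range[2])
    return("age_range must be an increasing pair")
  sds <- c(object@sd_intercept, object@sd_slope, object@sd_resid,
           object@hemi_offset_sd)
  if (any(sds < 0)) return("all standard deviations must be >= 0")
  if (object@family_sharing_prob < 0 || object@family_sharing_prob > 1)
    return("family_sharing_prob must be in [0,1]")
  if (object@mrs_subset_n > object@n_del)
    return("mrs_subset_n cannot exceed the number of deletion-group participants")
  if (!is.na(object@mrs_target_r2) &&
      (object@mrs_target_r2 <= 0 || object@mrs_target_r2 >= 1))
    return("mrs_target_r2 must be in (0,1)")
  TRUE
})

## ---------------------------------------------------------------------------
## Model-fit summaries
## ---------------------------------------------------------------------------

#' Linear mixed-effects trajectory fit summary
#'
#' Fixed effects with Wald-z inference (CI = beta +/- 1.96 SE, two-sided
#' normal p), random-effect variance components, and the fallback flag:
#' \code{model_used} is "full" for the random intercept + slope model and
#' "fallback" when a singular or non-convergent fit was refit with a random
#' intercept only.
#'
#' @slot coefficients data.frame: term, estimate, se, z, p, ci_lo, ci_hi.
#' @slot varcomp named numeric vector of random-effect variances (and
#'   residual variance).
#' @slot converged logical.
#' @slot model_used "full" or "fallback".
#' @slot n_obs,n_participants integers.
#' @slot formula character representation of the fitted model.
#' @export
setClass("LmmFit",
  representation(coefficients = "data.frame", varcomp = "numeric",
                 converged = "logical", model_used = "character",
                 n_obs = "integer", n_participants = "integer",
                 formula = "character"))

#' Ordinary least-squares fit summary
#'
#' @slot coefficients data.frame: term, estimate, se, t, p.
#' @slot r_squared coefficient of determination of the full model.
#' @slot n number of observations.
#' @slot formula character representation.
#' @export
setClass("OlsFit",
  representation(coefficients = "data.frame", r_squared = "numeric",
                 n = "integer", formula = "character"))

#' 2x2 contingency test result
#'
#' Test selection is deterministic: when the minimum expected cell count is
#' below 5 a two-sided Fisher exact test is used (p = sum of table
#' probabilities not exceeding the observed one), otherwise a chi-square
#' test with Yates continuity correction (df = 1).
#'
#' @slot counts observed 2x2 integer matrix.
#' @slot expected expected counts under independence.
#' @slot test_used "fisher_exact" or "yates_chi2".
#' @slot statistic chi-square statistic (NA for Fisher).
#' @slot p two-sided p-value.
#' @export
setClass("ContingencyResult",
  representation(counts = "matrix", expected = "matrix",
                 test_used = "character", statistic = "numeric",
                 p = "numeric"))

#' Report of the group-wise IQR outlier filter
#'
#' @slot n_input number of values seen.
#' @slot n_removed number of values outside their group's fence.
#' @slot n_nonfinite non-finite values (removed, counted separately).
#' @slot bounds data.frame per group: q1, q3, iqr, low, high, n, n_removed.
#' @export
setClass("FilterReport",
  representation(n_input = "integer", n_removed = "integer",
                 n_nonfinite = "integer", bounds = "data.frame"))
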