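## Simulated longitudinal cohorts and the cross-sectional MRS subset.

#' Construct a cohort specification
#'
#' Defaults mirror the study conditions the downstream models assume:
#' 83 controls and 85 deletion carriers, 1-3 scans each, ages 5-35 with a
#' mean intervisit interval of ~5 years, a group effect of -0.05 ALPS
#' units, and a cross-sectional MRS subset of 39 carriers whose Glx/GABA
#' ratio falls by 11.02 per ALPS unit.  Variance components (intercept SD
#' 0.13, slope SD 0.01/yr, residual SD 0.06) are calibrated so the
#' group-coefficient standard error is ~0.02, matching the reported CI
#' width, and so the random slope is identifiable from 1-3 scans per
#' participant; the methods vignette discusses this choice.
#'
#' @param n_hc,n_del participants per group.
#' @param scans_range integer pair, scans per participant (uniform draw).
#' @param age_range years (baseline ages uniform; later visits beyond the
#'   maximum are dropped).
#' @param visit_interval_mean,visit_interval_sd years between visits.
#' @param beta0,beta_group,beta_age,beta_interaction,beta_sex fixed
#'   effects; `beta_group` applies to the deletion group, age is centered
#'   at the realized sample mean.
#' @param beta_pps,beta_pps_interaction effects of the positive-psychotic-
#'   symptom label (carriers only).
#' @param sd_intercept,sd_slope,sd_resid random-effect and residual SDs.
#' @param hemi_offset_sd SD of the hemispheric offsets.
#' @param family_sharing_prob probability of joining an existing family.
#' @param mrs_subset_n,mrs_slope,mrs_intercept,mrs_noise_sd,mrs_target_r2
#'   E/I generative parameters (`mrs_noise_sd = NA` calibrates the noise to
#'   `mrs_target_r2` by the closed-form R^2).
#' @param seed integer RNG seed.
#' @return a [CohortSpec].
#' @export
cohortSpec <- function(n_hc = 83L, n_del = 85L, scans_range = c(1L, 3L),
                       age_range = c(5, 35), visit_interval_mean = 5,
                       visit_interval_sd = 1.5,
                       beta0 = 1.40, beta_group = -0.05, beta_age = 0.005,
                       beta_interaction = 0, beta_sex = 0,
                       beta_pps = 0, beta_pps_interaction = -0.01,
                       sd_intercept = 0.13, sd_slope = 0.01,
                       sd_resid = 0.06, hemi_offset_sd = 0.02,
                       family_sharing_prob = 0.1,
                       mrs_subset_n = 39L, mrs_slope = -11.02,
                       mrs_intercept = 19.4, mrs_noise_sd = NA_real_,
                       mrs_target_r2 = 0.25, seed = 42L) {
  new("CohortSpec", n_hc = as.integer(n_hc), n_del = as.integer(n_del),
      scans_range = as.integer(scans_range), age_range = age_range,
      visit_interval_mean = visit_interval_mean,
      visit_interval_sd = visit_interval_sd,
      beta0 = beta0, beta_group = beta_group, beta_age = beta_age,
      beta_interaction = beta_interaction, beta_sex = beta_sex,
      beta_pps = beta_pps, beta_pps_interaction = beta_pps_interaction,
      sd_intercept = sd_intercept, sd_slope = sd_slope, sd_resid = sd_resid,
      hemi_offset_sd = hemi_offset_sd,
      family_sharing_prob = family_sharing_prob,
      mrs_subset_n = as.integer(mrs_subset_n), mrs_slope = mrs_slope,
      mrs_intercept = mrs_intercept, mrs_noise_sd = mrs_noise_sd,
      mrs_target_r2 = mrs_target_r2, seed = as.integer(seed))
}

#' Simulate a longitudinal ALPS cohort
#'
#' Per scan j of participant i the latent bilateral index is
#' beta0 + beta_group G_i + beta_age agec_ij + beta_interaction G_i agec_ij
#' + beta_sex S_i (+ PPS terms within the deletion group) + u0_i +
#' u1_i agec_ij + eps_ij, with u0 ~ N(0, sd_intercept^2),
#' u1 ~ N(0, sd_slope^2), eps ~ N(0, sd_resid^2).  Left/right columns are
#' the latent value plus independent N(0, hemi_offset_sd^2) offsets; the
#' bilateral column is their mean.  Age is centered at the realized sample
#' mean across all scans.
#'
#' @param spec a [CohortSpec].
#' @param seed overrides `spec@seed` when given.
#' @return data.frame with one row per scan: participant, family, group
#'   ("HC"/"DEL"), pps ("PPS+"/"PPS-", NA for HC), sex, scan, age, age_c,
#'   alps_left, alps_right, alps_bilateral.
#' @export
simulateCohort <- function(spec, seed = NULL) {
  stopifnot(is(spec, "CohortSpec"))
  set.seed(if (is.null(seed)) spec@seed else seed)
  n <- spec@n_hc + spec@n_del
  group <- rep(c("HC", "DEL"), c(spec@n_hc, spec@n_del))
  sex <- sample(rep_len(c("F", "M"), n))
  pps <- ifelse(group == "DEL",
                ifelse(stats::runif(n) < 0.5, "PPS+", "PPS-"), NA)
  ## family ids: occasionally join an existing family of the same group
  family <- character(n); fam_count <- 0L
  for (i in seq_len(n)) {
    prev <- which(group[seq_len(i - 1L)] == group[i])
    if (length(prev) && stats::runif(1) < spec@family_sharing_prob) {
      family[i] <- family[sample(prev, 1L)]
    } else {
      fam_count <- fam_count + 1L
      family[i] <- sprintf("F%03d", fam_count)
    }
  }
  nscan <- sample(spec@scans_range[1]:spec@scans_range[2], n, replace = TRUE)
  u0 <- stats::rnorm(n, 0, spec@sd_intercept)
  u1 <- stats::rnorm(n, 0, spec@sd_slope)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    age <- stats::runif(1, spec@age_range[1], spec@age_range[2])
    ages <- age
    while (length(ages) < nscan[i]) {
      gap <- max(0.5, stats::rnorm(1, spec@visit_interval_mean,
                                   spec@visit_interval_sd))
      nxt <- ages[length(ages)] + gap
      if (nxt > spec@age_range[2]) break   # visits beyond the range dropped
      ages <- c(ages, nxt)
    }
    rows[[i]] <- data.frame(
      participant = sprintf("P%03d", i), family = family[i],
      group = group[i], pps = pps[i], sex = sex[i],
      scan = seq_along(ages), age = ages,
      u0 = u0[i], u1 = u1[i], stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  tab$age_c <- tab$age - mean(tab$age)
  G <- as.numeric(tab$group == "DEL")
  S <- as.numeric(tab$sex == "M")
  P <- as.numeric(!is.na(tab$pps) & tab$pps == "PPS+")
  eps <- stats::rnorm(nrow(tab), 0, spec@sd_resid)
  lat <- spec@beta0 + spec@beta_group * G + spec@beta_age * tab$age_c +
    spec@beta_interaction * G * tab$age_c + spec@beta_sex * S +
    spec@beta_pps * P + spec@beta_pps_interaction * P * tab$age_c +
    tab$u0 + tab$u1 * tab$age_c + eps
  dl <- stats::rnorm(nrow(tab), 0, spec@hemi_offset_sd)
  dr <- stats::rnorm(nrow(tab), 0, spec@hemi_offset_sd)
  tab$alps_left <- lat + dl
  tab$alps_right <- lat + dr
  tab$alps_bilateral <- (tab$alps_left + tab$alps_right) / 2
  tab$u0 <- tab$u1 <- NULL
  rownames(tab) <- NULL
  tab
}

#' Simulate the cross-sectional MRS subset
#'
#' Selects `mrs_subset_n` distinct deletion-group participants (one scan
#' each: the latest) and generates hippocampal Glx/GABA ratios as
#' mrs_intercept + mrs_slope * ALPS + noise.  With `mrs_noise_sd = NA` the
#' noise SD is calibrated so the closed-form coefficient of determination
#' R^2 = s^2 v / (s^2 v + sigma^2), with v the sample variance of the
#' subset's ALPS values, equals `mrs_target_r2`.
#'
#' @param cohort data.frame from [simulateCohort()].
#' @param spec the [CohortSpec] used to generate it.
#' @param seed overrides `spec@seed + 1` when given.
#' @param alps_col which ALPS column drives the ratio.
#' @return data.frame with one row per selected participant: participant,
#'   age, sex, alps (the predictor used), glx, gaba, glx_gaba.
#' @export
simulateMrs <- function(cohort, spec, seed = NULL,
                        alps_col = "alps_bilateral") {
  stopifnot(is(spec, "CohortSpec"))
  set.seed(if (is.null(seed)) spec@seed + 1L else seed)
  del <- cohort[cohort$group == "DEL", ]
  ids <- unique(del$participant)
  if (spec@mrs_subset_n > length(ids))
    stop("mrs_subset_n (", spec@mrs_subset_n,
         ") exceeds available deletion-group participants (", length(ids), ")")
  sel <- sample(ids, spec@mrs_subset_n)
  last <- del[del$participant %in% sel, ]
  last <- last[order(last$participant, -last$scan), ]
  last <- last[!duplicated(last$participant), ]   # one (latest) scan each
  alps <- last[[alps_col]]
  sigma <- spec@mrs_noise_sd
  if (is.na(sigma)) {
    v <- stats::var(alps)
    sigma <- abs(spec@mrs_slope) * sqrt(v) *
      sqrt(1 / spec@mrs_target_r2 - 1)
  }
  ratio <- spec@mrs_intercept + spec@mrs_slope * alps +
    stats::rnorm(nrow(last), 0, sigma)
  gaba <- pmax(0.5, stats::rnorm(nrow(last), 2.5, 0.3))
  out <- data.frame(participant = last$participant, age = last$age,
                    sex = last$sex, alps = alps,
                    glx = ratio * gaba, gaba = gaba, glx_gaba = ratio,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write / read cohort and MRS tables as CSV
#'
#' @param table data.frame.
#' @param path CSV path.
#' @export
writeCohortTable <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCohortTable
#' @export
readCohortTable <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
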