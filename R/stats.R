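## Trajectory mixed models, the E/I regression, contingency tests, BH-FDR.

.waldTable <- function(est, se) {
  z <- est / se
  data.frame(term = names(est), estimate = unname(est), se = unname(se),
             z = unname(z), p = 2 * stats::pnorm(-abs(z)),
             ci_lo = unname(est - 1.96 * se),
             ci_hi = unname(est + 1.96 * se),
             stringsAsFactors = FALSE, row.names = NULL)
}

.lmerSingular <- function(fit, tol = 1e-8) {
  vc <- as.data.frame(lme4::VarCorr(fit))
  own <- is.na(vc$var2) & vc$grp != "Residual"   # variances, not covariances
  any(vc$vcov[own] < tol) || lme4::isSingular(fit, tol = 1e-4)
}

#' Fit the developmental trajectory mixed-effects model
#'
#' Fits (by REML unless `estimator = "ML"`)
#' \code{outcome ~ group * age_c + sex + (1 + age_c | participant)}
#' with age centered at the analysis sample's mean, so the group
#' coefficient is the group difference at mean age.  When the random-slope
#' fit fails to converge or has a singular / near-zero random-effect
#' covariance (variance below 1e-8), the model is refit with a random
#' intercept only and flagged `model_used = "fallback"`.  Inference on the
#' fixed effects is by Wald z: CI = estimate +/- 1.96 SE and two-sided
#' normal p-values.
#'
#' @param table scan-level data.frame.
#' @param outcome outcome column name (e.g. "alps_bilateral").
#' @param group_var binary group column (factor or character).
#' @param age_var age column (years); centered internally.
#' @param sex_var sex column; set NULL to omit.
#' @param interaction include the group x age term.
#' @param random "intercept_slope" or "intercept".
#' @param family_intercept add a family-level random intercept (requires a
#'   `family` column).
#' @param estimator "REML" or "ML".
#' @param keep_mask optional logical column name; only rows where it is
#'   TRUE (and the outcome is finite) are fitted.
#' @return an [LmmFit].
#' @export
fitTrajectoryLmm <- function(table, outcome = "alps_bilateral",
                             group_var = "group", age_var = "age",
                             sex_var = "sex", interaction = TRUE,
                             random = c("intercept_slope", "intercept"),
                             family_intercept = FALSE,
                             estimator = c("REML", "ML"),
                             keep_mask = NULL) {
  random <- match.arg(random)
  estimator <- match.arg(estimator)
  if (!outcome %in% names(table)) stop("outcome column '", outcome, "' missing")
  if (family_intercept && !"family" %in% names(table))
    stop("family_intercept = TRUE requires a 'family' column")
  d <- table
  if (!is.null(keep_mask)) d <- d[d[[keep_mask]] %in% TRUE, ]
  d <- d[is.finite(d[[outcome]]), ]
  if (!nrow(d)) stop("no usable observations for outcome '", outcome, "'")
  if (length(unique(d$participant)) < 2L)
    stop("need at least 2 participants")
  d$.age_c <- d[[age_var]] - mean(d[[age_var]])   # recentered post-QC
  d$.grp <- factor(d[[group_var]])
  ## control group, when present, is the reference level
  ref <- intersect(c("HC", "control", "Control", "PPS-"), levels(d$.grp))
  if (length(ref)) d$.grp <- stats::relevel(d$.grp, ref[1])
  fixed <- paste0(outcome, " ~ .grp ",
                  if (interaction) "* .age_c" else "+ .age_c",
                  if (!is.null(sex_var)) paste0(" + ", sex_var) else "")
  reFull <- "(1 + .age_c | participant)"
  reInt <- "(1 | participant)"
  fam <- if (family_intercept) " + (1 | family)" else ""
  fitOne <- function(re) {
    f <- stats::as.formula(paste0(fixed, " + ", re, fam))
    withCallingHandlers(
      lme4::lmer(f, data = d, REML = estimator == "REML",
                 control = lme4::lmerControl(check.conv.singular = "ignore",
                                             check.nobs.vs.nRE = "ignore",
                                             check.nobs.vs.nlev = "ignore",
                                             calc.derivs = FALSE)),
      warning = function(w) invokeRestart("muffleWarning"))
  }
  model_used <- "full"; fit <- NULL
  if (random == "intercept_slope") {
    ## needs repeated scans to identify the slope variance
    nrep <- sum(table(d$participant) >= 2L)
    fit <- if (nrep >= 2L) tryCatch(fitOne(reFull), error = function(e) NULL)
    if (is.null(fit) || !is.null(fit@optinfo$conv$lme4$code) ||
        .lmerSingular(fit)) {
      fit <- NULL
    }
  }
  if (is.null(fit)) {
    if (random == "intercept_slope") model_used <- "fallback"
    fit <- fitOne(reInt)
  }
  co <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  tab <- .waldTable(co, se)
  ## readable term names: .grp<level> -> group<level>
  tab$term <- sub("^\\.grp", "group", tab$term)
  tab$term <- gsub("\\.grp", "group", tab$term)
  tab$term <- gsub("\\.age_c", "age_c", tab$term)
  vc <- as.data.frame(lme4::VarCorr(fit))
  vnames <- ifelse(is.na(vc$var2),
                   paste0(vc$grp, ifelse(is.na(vc$var1), "", paste0(".", vc$var1))),
                   paste0(vc$grp, ".cov"))
  varcomp <- stats::setNames(vc$vcov, vnames)
  conv <- is.null(fit@optinfo$conv$lme4$code)
  new("LmmFit", coefficients = tab, varcomp = varcomp,
      converged = conv, model_used = model_used,
      n_obs = nrow(d),
      n_participants = length(unique(d$participant)),
      formula = paste(deparse(stats::formula(fit)), collapse = ""))
}

#' @describeIn fitTrajectoryLmm convenience wrapper adding the family-level
#'   random intercept used in the familial-nonindependence sensitivity fit.
#' @param ... passed on to `fitTrajectoryLmm`.
#' @export
fitTrajectoryLmmFamily <- function(table, ...) {
  fitTrajectoryLmm(table, family_intercept = TRUE, ...)
}

#' Excitation/inhibition regression
#'
#' OLS of the Glx/GABA ratio on an ALPS index, controlling for age and sex;
#' reports the predictor coefficient with its two-sided t-test p-value and
#' the full-model R^2.
#'
#' @param table one row per participant with the predictor, outcome, age
#'   and sex columns.
#' @param predictor ALPS column name.
#' @param outcome outcome column name.
#' @param covariates character vector of covariate columns.
#' @return an [OlsFit].
#' @export
fitEiOls <- function(table, predictor = "alps", outcome = "glx_gaba",
                     covariates = c("age", "sex")) {
  need <- c(predictor, outcome, covariates)
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  d <- table[stats::complete.cases(table[need]), need, drop = FALSE]
  if (nrow(d) <= length(need) - 1L)
    stop("n (", nrow(d), ") too small for ", length(need) - 1L, " predictors")
  f <- stats::as.formula(paste(outcome, "~",
                               paste(c(predictor, covariates), collapse = " + ")))
  fit <- stats::lm(f, data = d)
  if (any(is.na(stats::coef(fit))))
    stop("singular design: a predictor is constant or collinear")
  s <- summary(fit)
  cf <- s$coefficients
  tab <- data.frame(term = rownames(cf), estimate = cf[, 1], se = cf[, 2],
                    t = cf[, 3], p = cf[, 4], stringsAsFactors = FALSE,
                    row.names = NULL)
  new("OlsFit", coefficients = tab, r_squared = unname(s$r.squared),
      n = nrow(d), formula = deparse(f))
}

#' 2x2 contingency test with deterministic test selection
#'
#' Computes expected counts under independence; when the minimum expected
#' count is below 5 a two-sided Fisher exact test is used (two-sided p =
#' sum of probabilities of tables no more probable than the observed one),
#' otherwise the chi-square test with Yates continuity correction (df = 1).
#'
#' @param a,b,c,d cell counts (row 1: a, b; row 2: c, d), or `a` may be a
#'   2x2 matrix.
#' @return a [ContingencyResult].
#' @export
contingencyTest <- function(a, b = NULL, c = NULL, d = NULL) {
  m <- if (is.matrix(a)) a else matrix(c(a, c, b, d), 2, 2)
  if (any(m < 0) || any(m != round(m))) stop("counts must be nonnegative integers")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("zero margin: every row and column must have a positive total")
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (min(expected) < 5) {
    ft <- stats::fisher.test(m, alternative = "two.sided")
    new("ContingencyResult", counts = m, expected = expected,
        test_used = "fisher_exact", statistic = NA_real_, p = ft$p.value)
  } else {
    ct <- suppressWarnings(stats::chisq.test(m, correct = TRUE))
    new("ContingencyResult", counts = m, expected = expected,
        test_used = "yates_chi2", statistic = unname(ct$statistic),
        p = ct$p.value)
  }
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up adjusted p-values (monotone, capped at 1) with significance
#' flags at q < alpha.
#'
#' @param pvals numeric vector in [0,1].
#' @param labels optional names for the output.
#' @param alpha significance threshold on q.
#' @return data.frame with label, p, q, significant.
#' @export
bhFdr <- function(pvals, labels = NULL, alpha = 0.05) {
  if (!length(pvals))
    return(data.frame(label = character(0), p = numeric(0), q = numeric(0),
                      significant = logical(0)))
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in [0,1]")
  if (is.null(labels)) labels <- paste0("test", seq_along(pvals))
  q <- stats::p.adjust(pvals, method = "BH")
  data.frame(label = labels, p = pvals, q = q,
             significant = !is.na(q) & q < alpha,
             stringsAsFactors = FALSE)
}
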