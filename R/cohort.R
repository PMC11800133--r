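#' Parameters of the synthetic cohort generator
#'
#' Defaults reproduce the marginal summary statistics and association
#' structure reported for acute spontaneous intracerebral hemorrhage (sICH)
#' cohorts with matched healthy controls (HC): hemispheric ALPS indices
#' (ipsilateral 1.34 +/- 0.24, contralateral 1.48 +/- 0.21 in patients,
#' 1.46 +/- 0.22 in controls), hemorrhage 22.1 +/- 20.1 mL and edema
#' 24.2 +/- 26.2 mL, negative ALPS-volume correlations, and a logistic
#' outcome model in which each 0.1 increase in ipsilateral ALPS multiplies
#' the odds of a favorable 90-day outcome (mRS <= 2) by 1.686, with the
#' intercept calibrated so about 70.9% of patients are favorable.
#'
#' @param n_sich,n_hc Group sizes (default 55 patients / 97 controls).
#' @param n_subtentorial Number of patients with subtentorial hemorrhage
#'   (no lateralized ALPS; default 9).
#' @param means,sds Named numeric vectors for the continuous sICH marginals
#'   (`alps_ipsi`, `alps_contra`, `hem_vol`, `edema_vol`, `age`, `nihss`,
#'   `duration`) and the HC marginals (`hc_alps`, `hc_age`).
#' @param correlations Named list of latent pairwise correlations among the
#'   sICH continuous variables, e.g. `list(alps_ipsi.hem_vol = -0.426)`.
#'   Unlisted pairs are 0.
#' @param proportions Named list of Bernoulli rates: `female_sich`,
#'   `female_hc`, `hypertension_sich`, ... (see defaults in the source).
#' @param marginals Optional named character vector choosing the marginal
#'   family for the nonnegative variables (`hem_vol`, `edema_vol`, `nihss`,
#'   `duration`): `"truncnorm"` (zero-truncated normal, moment-matched) or
#'   `"lognormal"` (moment-matched). Default `"auto"`: truncated normal
#'   where the target SD/mean ratio is achievable by one (the ratio must be
#'   below 1), lognormal otherwise -- an SD of the order of the mean
#'   indicates right skew that a truncated normal cannot carry.
#' @param or_per_0.1 Odds ratio of favorable outcome per 0.1 increase in
#'   ipsilateral ALPS (default 1.686); the slope is `log(or_per_0.1) / 0.1`.
#' @param ratio_corr Target correlation between ipsilateral ALPS and the
#'   relative edema ratio (default -0.489). The ratio is computed from the
#'   simulated volumes, never drawn, so this target is met by calibrating
#'   the latent hemorrhage-edema correlation (closed form when both volume
#'   marginals are lognormal); it is ignored when `hem_vol.edema_vol` is set
#'   explicitly in `correlations`.
#' @param favorable_target Marginal favorable-outcome fraction used to
#'   calibrate the logistic intercept by root finding (default 0.709).
#' @param beta_age,beta_nihss Optional extra outcome-model coefficients
#'   (default 0; whether these entered the original outcome mechanism is not
#'   knowable, so they are exposed as configuration).
#' @return An object of class `cohort_params`.
#' @export
cohort_params <- function(n_sich = 55, n_hc = 97, n_subtentorial = 9,
                          means = NULL, sds = NULL,
                          correlations = list(),
                          proportions = list(),
                          marginals = NULL,
                          or_per_0.1 = 1.686,
                          favorable_target = 0.709,
                          ratio_corr = -0.489,
                          beta_age = 0, beta_nihss = 0) {
  if (n_sich < 2 || n_hc < 2) stop("group sizes must be >= 2")
  if (n_subtentorial < 0 || n_subtentorial > n_sich)
    stop("n_subtentorial must be between 0 and n_sich")
  def_means <- c(alps_ipsi = 1.34, alps_contra = 1.48, hem_vol = 22.1,
                 edema_vol = 24.2, age = 58, nihss = 5.6, duration = 5.3,
                 hc_alps = 1.46, hc_age = 58)
  def_sds <- c(alps_ipsi = 0.24, alps_contra = 0.21, hem_vol = 20.1,
               edema_vol = 26.2, age = 15, nihss = 5.3, duration = 3.1,
               hc_alps = 0.22, hc_age = 7)
  means <- merge_named(def_means, means)
  sds <- merge_named(def_sds, sds)
  if (any(sds <= 0)) stop("SDs must be > 0")

  def_cor <- list(alps_ipsi.alps_contra = 0.5,
                  alps_ipsi.hem_vol = -0.426,
                  alps_ipsi.edema_vol = -0.592,
                  alps_ipsi.nihss = -0.30,
                  hem_vol.nihss = 0.55,
                  edema_vol.nihss = 0.50)
  user_set_he <- "hem_vol.edema_vol" %in% names(correlations)
  correlations <- utils::modifyList(def_cor, correlations)
  if (any(abs(unlist(correlations)) >= 1)) stop("|r| must be < 1")
  R <- build_cor_matrix(c("alps_ipsi", "alps_contra", "hem_vol", "edema_vol",
                          "age", "nihss", "duration"), correlations)

  def_prop <- list(female_sich = 14 / 55, female_hc = 25 / 97,
                   hypertension_sich = 40 / 55, hypertension_hc = 64 / 97,
                   diabetes_sich = 7 / 55, diabetes_hc = 17 / 97,
                   hyperlipemia_sich = 5 / 55, hyperlipemia_hc = 22 / 97,
                   smoking_sich = 14 / 55, smoking_hc = 25 / 97)
  proportions <- utils::modifyList(def_prop, proportions)

  nonneg <- c("hem_vol", "edema_vol", "nihss", "duration")
  def_marg <- stats::setNames(rep("auto", length(nonneg)), nonneg)
  marg <- merge_named(def_marg, marginals)
  auto <- marg == "auto"
  marg[auto] <- ifelse(sds[nonneg][auto] / means[nonneg][auto] >= 0.9,
                       "lognormal", "truncnorm")
  if (!all(marg %in% c("truncnorm", "lognormal")))
    stop("marginals must be 'auto', 'truncnorm' or 'lognormal'")

  beta_alps <- log(or_per_0.1) / 0.1
  p <- structure(list(n_sich = n_sich, n_hc = n_hc,
                      n_subtentorial = n_subtentorial,
                      means = means, sds = sds, cor_target = R,
                      proportions = proportions, marginals = marg,
                      beta_alps = beta_alps, beta_age = beta_age,
                      beta_nihss = beta_nihss,
                      favorable_target = favorable_target,
                      ratio_corr = ratio_corr),
                 class = "cohort_params")
  p$cor_matrix <- adjust_latent_correlations(p)
  if (!user_set_he && all(marg[c("hem_vol", "edema_vol")] == "lognormal"))
    p <- calibrate_ratio_correlation(p)
  check_positive_definite(p$cor_matrix)
  p$beta0 <- calibrate_outcome_intercept(p)
  p
}

# Latent hemorrhage-edema correlation such that the derived relative edema
# ratio carries the configured correlation with ipsilateral ALPS. With both
# volumes lognormal the ratio is itself lognormal and everything is closed
# form: for A ~ normal latent z_A and ratio = exp(mu_r + s_r * w),
# cor(A, ratio) = c / sqrt(exp(s_r^2) - 1) with
# c = rho_Ae * s_e - rho_Ah * s_h (latent log-scale covariance with z_A),
# and s_r^2 = s_e^2 + s_h^2 - 2 * rho_he * s_e * s_h.
calibrate_ratio_correlation <- function(p) {
  se <- lognormal_match(p$means["edema_vol"], p$sds["edema_vol"])$sdlog
  sh <- lognormal_match(p$means["hem_vol"], p$sds["hem_vol"])$sdlog
  R <- p$cor_matrix
  cc <- R["alps_ipsi", "edema_vol"] * se - R["alps_ipsi", "hem_vol"] * sh
  r_t <- p$ratio_corr
  if (r_t == 0 || sign(cc) != sign(r_t) || abs(cc) < 1e-12)
    stop("ratio correlation target ", r_t,
         " not attainable from the ALPS-volume correlations")
  sr2 <- log(1 + (cc / r_t)^2)
  rho_he <- (se^2 + sh^2 - sr2) / (2 * se * sh)
  if (rho_he >= 0.999 || rho_he <= -0.999)
    stop("ratio correlation target ", r_t,
         " requires an infeasible hemorrhage-edema correlation")
  R["hem_vol", "edema_vol"] <- R["edema_vol", "hem_vol"] <- rho_he
  p$cor_matrix <- R
  # record the induced product-moment hemorrhage-edema correlation
  r_pm <- (exp(rho_he * se * sh) - 1) /
    sqrt((exp(se^2) - 1) * (exp(sh^2) - 1))
  p$cor_target["hem_vol", "edema_vol"] <-
    p$cor_target["edema_vol", "hem_vol"] <- r_pm
  p
}

merge_named <- function(defaults, user) {
  if (is.null(user)) return(defaults)
  bad <- setdiff(names(user), names(defaults))
  if (length(bad)) stop("unknown parameter: ", paste(bad, collapse = ", "))
  defaults[names(user)] <- user
  defaults
}

# Assemble and validate the latent correlation matrix; a non-PD matrix is
# rejected naming the most extreme configured pair.
build_cor_matrix <- function(vars, correlations) {
  R <- diag(length(vars)); dimnames(R) <- list(vars, vars)
  for (nm in names(correlations)) {
    pair <- strsplit(nm, ".", fixed = TRUE)[[1]]
    if (length(pair) != 2 || !all(pair %in% vars))
      stop("correlation name must be '<var1>.<var2>': ", nm)
    R[pair[1], pair[2]] <- R[pair[2], pair[1]] <- correlations[[nm]]
  }
  R
}

# Final PD validation of the latent matrix; a failure names the most extreme
# configured pair as the likeliest culprit.
check_positive_definite <- function(R) {
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) {
    off <- abs(R); diag(off) <- 0
    w <- which(off == max(off), arr.ind = TRUE)[1, ]
    stop(sprintf("correlation matrix not positive definite (check pair %s/%s)",
                 colnames(R)[w[1]], colnames(R)[w[2]]))
  }
  invisible(R)
}

# Underlying-normal parameters such that the zero-truncated distribution has
# the requested mean and SD (two-moment matching).
truncnorm_match <- function(m, s) {
  obj <- function(p) {
    mu <- p[1]; sg <- exp(p[2])
    a <- -mu / sg
    Z <- stats::pnorm(a, lower.tail = FALSE)
    lam <- stats::dnorm(a) / Z
    tm <- mu + sg * lam
    tv <- sg^2 * (1 + a * lam - lam^2)
    (tm - m)^2 / s^2 + (sqrt(max(tv, 0)) - s)^2 / s^2
  }
  fit <- stats::optim(c(m, log(s)), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  list(mu = fit$par[1], sigma = exp(fit$par[2]),
       p0 = stats::pnorm(0, fit$par[1], exp(fit$par[2])))
}

# Quantile of the zero-truncated normal, for copula margin mapping.
qtrunc0 <- function(u, mu, sigma) {
  p0 <- stats::pnorm(0, mu, sigma)
  p <- pmin(p0 + u * (1 - p0), 1 - 1e-16)
  stats::qnorm(p, mu, sigma)
}

# Lognormal parameters with the requested mean and SD (exact moment match).
lognormal_match <- function(m, s) {
  sdlog2 <- log(1 + (s / m)^2)
  list(meanlog = log(m) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

# Quantile function of variable v's configured marginal, for the copula
# mapping and the latent correlation adjustment.
margin_quantile <- function(params, v) {
  m <- params$means[[v]]; s <- params$sds[[v]]
  if (!v %in% names(params$marginals))
    return(function(u) stats::qnorm(u, m, s))
  if (params$marginals[[v]] == "lognormal") {
    lp <- lognormal_match(m, s)
    function(u) stats::qlnorm(pmin(u, 1 - 1e-16), lp$meanlog, lp$sdlog)
  } else {
    tp <- truncnorm_match(m, s)
    function(u) qtrunc0(u, tp$mu, tp$sigma)
  }
}

# Gauss-Hermite nodes/weights for E[f(Z)], Z standard normal
# (Golub-Welsch on the Jacobi matrix, rescaled from physicists' Hermite).
gauss_hermite_normal <- function(n) {
  off <- sqrt(seq_len(n - 1) / 2)
  J <- matrix(0, n, n)
  J[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- off
  J[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  list(z = sqrt(2) * e$values, w = e$vectors[1, ]^2)
}

# Product-moment correlation induced between two quantile-mapped margins by
# latent Gaussian correlation rz (2-D Gauss-Hermite quadrature).
induced_correlation <- function(rz, q1, q2, n_nodes = 48) {
  gh <- gauss_hermite_normal(n_nodes)
  z <- gh$z; w <- gh$w
  # clamp away from 0/1 so extreme nodes stay finite through any quantile
  pn <- function(q) pmin(pmax(stats::pnorm(q), 1e-16), 1 - 1e-16)
  x1 <- q1(pn(z)); x2 <- q2(pn(z))
  m1 <- sum(w * x1); s1 <- sqrt(sum(w * x1^2) - m1^2)
  m2 <- sum(w * x2); s2 <- sqrt(sum(w * x2^2) - m2^2)
  # E[x2 | z1] over the conditional normal, on the same node set
  cross <- outer(z, z, function(a, e) rz * a + sqrt(1 - rz^2) * e)
  x2c <- as.vector(matrix(q2(pn(cross)), n_nodes, n_nodes) %*% w)
  (sum(w * x1 * x2c) - m1 * m2) / (s1 * s2)
}

# Latent Gaussian correlations such that the quantile-mapped variables carry
# the configured product-moment correlations (NORTA inversion, exact to
# quadrature accuracy; identity for pairs of plain normal margins).
adjust_latent_correlations <- function(params) {
  Rt <- params$cor_target
  vars <- colnames(Rt)
  is_normal <- !(vars %in% names(params$marginals))
  R <- Rt
  for (i in seq_along(vars)[-length(vars)]) for (j in (i + 1):length(vars)) {
    r <- Rt[i, j]
    if (r == 0 || (is_normal[i] && is_normal[j])) next
    q1 <- margin_quantile(params, vars[i])
    q2 <- margin_quantile(params, vars[j])
    f <- function(rz) induced_correlation(rz, q1, q2) - r
    lo <- max(-0.999, r * 1.0); hi <- min(0.999, sign(r) * 0.999)
    sol <- tryCatch(stats::uniroot(f, sort(c(lo, hi)), tol = 1e-6)$root,
                    error = function(e)
                      stop(sprintf("correlation %s/%s = %.3f not attainable under the chosen marginals",
                                   vars[i], vars[j], r)))
    R[i, j] <- R[j, i] <- sol
  }
  R
}

# Intercept such that the marginal favorable fraction matches the target,
# integrating the logistic response over the ALPS marginal actually used
# (ipsilateral for supratentorial cases, per-subject average for
# subtentorial), with age/NIHSS held at their configured means.
calibrate_outcome_intercept <- function(p) {
  m <- p$means; s <- p$sds; R <- p$cor_matrix
  r_ic <- R["alps_ipsi", "alps_contra"]
  m_avg <- (m["alps_ipsi"] + m["alps_contra"]) / 2
  s_avg <- sqrt((s["alps_ipsi"]^2 + s["alps_contra"]^2 +
                 2 * r_ic * s["alps_ipsi"] * s["alps_contra"]) / 4)
  w <- (p$n_sich - p$n_subtentorial) / p$n_sich
  shift <- p$beta_age * m["age"] + p$beta_nihss * m["nihss"]
  expected_fav <- function(b0) {
    f <- function(mu, sd) stats::integrate(function(a)
      stats::plogis(b0 + p$beta_alps * a + shift) * stats::dnorm(a, mu, sd),
      mu - 8 * sd, mu + 8 * sd)$value
    w * f(m["alps_ipsi"], s["alps_ipsi"]) + (1 - w) * f(m_avg, s_avg)
  }
  stats::uniroot(function(b0) expected_fav(b0) - p$favorable_target,
                 c(-60, 60), tol = 1e-10)$root
}

#' Simulate a cohort table
#'
#' Draws one synthetic cohort: patient continuous variables come from a
#' Gaussian copula with the configured marginals (plain normal for ALPS and
#' age; zero-truncated normal, moment-matched to the configured mean/SD, for
#' volumes, NIHSS and disease duration) and the configured latent correlation
#' matrix; the relative edema ratio is computed from the simulated volumes,
#' never drawn; binary risk factors are independent Bernoulli draws at the
#' configured group rates; 90-day outcome (mRS <= 2 favorable) follows the
#' logistic model on the subject's ipsilateral (or, for subtentorial cases,
#' average) ALPS. Controls carry only demographic fields and an average ALPS.
#'
#' The fraction of latent mass truncated at zero per truncated variable is
#' attached as attribute `truncated_mass`.
#'
#' @param params A `cohort_params`.
#' @param seed Integer seed; identical seed and parameters give an identical
#'   table.
#' @return A `data.frame` of class `alps_cohort`, one row per subject.
#' @export
simulate_cohort <- function(params, seed = 1L) {
  stopifnot(inherits(params, "cohort_params"))
  set.seed(seed)
  m <- params$means; s <- params$sds
  n <- params$n_sich
  vars <- colnames(params$cor_matrix)
  Z <- MASS::mvrnorm(n, mu = rep(0, length(vars)), Sigma = params$cor_matrix)
  colnames(Z) <- vars

  # copula margin: each latent normal score is pushed through its configured
  # marginal's quantile function
  draw <- function(v) margin_quantile(params, v)(stats::pnorm(Z[, v]))
  alps_ipsi <- pmax(draw("alps_ipsi"), 1e-6)
  alps_contra <- pmax(draw("alps_contra"), 1e-6)
  age <- draw("age")
  hem <- draw("hem_vol")
  ede <- draw("edema_vol")
  nihss <- draw("nihss")
  dur <- draw("duration")
  trunc_mass <- vapply(c("hem_vol", "edema_vol", "nihss", "duration"),
                       function(v) {
                         if (params$marginals[[v]] == "lognormal") 0
                         else truncnorm_match(m[v], s[v])$p0
                       }, numeric(1))

  n_sub <- params$n_subtentorial
  side <- rep("none", n)
  supra <- seq_len(n - n_sub)
  side[supra] <- sample(c("left", "right"), length(supra), replace = TRUE)
  if (n_sub > 0) side[(n - n_sub + 1):n] <- "subtentorial"

  alps_avg <- (alps_ipsi + alps_contra) / 2
  alps_used <- ifelse(side == "subtentorial", alps_avg, alps_ipsi)
  eta <- params$beta0 + params$beta_alps * alps_used +
    params$beta_age * age + params$beta_nihss * nihss
  fav <- stats::rbinom(n, 1, stats::plogis(eta))
  mrs <- ifelse(fav == 1, sample(0:2, n, replace = TRUE),
                sample(3:6, n, replace = TRUE))

  pr <- params$proportions
  sich <- data.frame(
    subject_id = sprintf("sich_%03d", seq_len(n)),
    group = "sICH",
    age = age,
    sex = ifelse(stats::rbinom(n, 1, pr$female_sich) == 1, "F", "M"),
    hypertension = stats::rbinom(n, 1, pr$hypertension_sich),
    diabetes = stats::rbinom(n, 1, pr$diabetes_sich),
    hyperlipemia = stats::rbinom(n, 1, pr$hyperlipemia_sich),
    smoking = stats::rbinom(n, 1, pr$smoking_sich),
    hemorrhage_side = side,
    alps_ipsilateral = ifelse(side == "subtentorial", NA_real_, alps_ipsi),
    alps_contralateral = ifelse(side == "subtentorial", NA_real_, alps_contra),
    alps_average = alps_avg,
    hemorrhage_volume_ml = hem,
    edema_volume_ml = ede,
    relative_edema_ratio = ede / hem,
    nihss_baseline = nihss,
    disease_duration_days = dur,
    mrs_90d = mrs,
    stringsAsFactors = FALSE
  )

  nh <- params$n_hc
  hc <- data.frame(
    subject_id = sprintf("hc_%03d", seq_len(nh)),
    group = "HC",
    age = stats::rnorm(nh, m["hc_age"], s["hc_age"]),
    sex = ifelse(stats::rbinom(nh, 1, pr$female_hc) == 1, "F", "M"),
    hypertension = stats::rbinom(nh, 1, pr$hypertension_hc),
    diabetes = stats::rbinom(nh, 1, pr$diabetes_hc),
    hyperlipemia = stats::rbinom(nh, 1, pr$hyperlipemia_hc),
    smoking = stats::rbinom(nh, 1, pr$smoking_hc),
    hemorrhage_side = "none",
    alps_ipsilateral = NA_real_,
    alps_contralateral = NA_real_,
    alps_average = pmax(stats::rnorm(nh, m["hc_alps"], s["hc_alps"]), 1e-6),
    hemorrhage_volume_ml = NA_real_,
    edema_volume_ml = NA_real_,
    relative_edema_ratio = NA_real_,
    nihss_baseline = NA_real_,
    disease_duration_days = NA_real_,
    mrs_90d = NA_integer_,
    stringsAsFactors = FALSE
  )

  out <- rbind(sich, hc)
  attr(out, "truncated_mass") <- trunc_mass
  class(out) <- c("alps_cohort", "data.frame")
  validate_cohort(out)
  out
}

cohort_columns <- function() {
  c("subject_id", "group", "age", "sex", "hypertension", "diabetes",
    "hyperlipemia", "smoking", "hemorrhage_side", "alps_ipsilateral",
    "alps_contralateral", "alps_average", "hemorrhage_volume_ml",
    "edema_volume_ml", "relative_edema_ratio", "nihss_baseline",
    "disease_duration_days", "mrs_90d")
}

#' Validate a cohort table
#'
#' Checks the structural invariants of the per-subject table: all mandatory
#' columns present; volumes nonnegative; ALPS positive; mRS in 0..6; the
#' average ALPS equal to the mean of the two sides wherever both are
#' defined; controls free of lesion fields.
#'
#' @param table A data frame.
#' @return The table, invisibly, on success; otherwise an error naming the
#'   problem.
#' @export
validate_cohort <- function(table) {
  miss <- setdiff(cohort_columns(), names(table))
  if (length(miss))
    stop("missing mandatory column: ", paste(miss, collapse = ", "))
  if (nrow(table) == 0) stop("cohort table is empty")
  num <- table[, c("hemorrhage_volume_ml", "edema_volume_ml")]
  if (any(unlist(num) < 0, na.rm = TRUE)) stop("volumes must be >= 0")
  alps <- table[, c("alps_ipsilateral", "alps_contralateral", "alps_average")]
  if (any(unlist(alps) <= 0, na.rm = TRUE)) stop("ALPS indices must be > 0")
  mrs <- table$mrs_90d
  if (any(!is.na(mrs) & !(mrs %in% 0:6)))
    stop("mrs_90d must be an integer in 0..6")
  both <- !is.na(table$alps_ipsilateral) & !is.na(table$alps_contralateral)
  if (any(abs(table$alps_average[both] -
              (table$alps_ipsilateral[both] +
               table$alps_contralateral[both]) / 2) > 1e-8))
    stop("alps_average must equal the mean of the two sides")
  hcrows <- table$group == "HC"
  lesion_cols <- c("alps_ipsilateral", "alps_contralateral",
                   "hemorrhage_volume_ml", "edema_volume_ml",
                   "relative_edema_ratio", "nihss_baseline",
                   "disease_duration_days", "mrs_90d")
  if (any(!is.na(unlist(table[hcrows, lesion_cols]))))
    stop("HC records must not carry lesion fields")
  invisible(table)
}

#' Write / read a cohort table as CSV
#'
#' UTF-8 CSV with a header row and one record per subject; the round trip is
#' lossless for all fields. Reading validates the table and errors naming
#' any missing mandatory column.
#'
#' @param table An `alps_cohort` data frame.
#' @param path CSV file path.
#' @export
write_cohort <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE,
                                  na.strings = ""),
                  error = function(e) stop("cannot parse cohort CSV: ",
                                           conditionMessage(e)))
  validate_cohort(tab)
  class(tab) <- c("alps_cohort", "data.frame")
  tab
}
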