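#' Group comparison report (patients vs controls)
#'
#' Builds the demographic/clinical comparison table for a cohort: continuous
#' variables as mean +/- SD compared by pooled Student's t, binary risk
#' factors as counts (proportions) compared by a 2x2 test. The ALPS rows
#' compare each patient index (ipsilateral, contralateral, average) against
#' the control average index.
#'
#' @param cohort An `alps_cohort` table.
#' @param method_2x2 Method passed to [categorical_2x2()] (default
#'   `"auto"`).
#' @return Data frame with one row per variable: group summaries, statistic
#'   and two-sided p.
#' @export
analyze_group_comparison <- function(cohort, method_2x2 = "auto") {
  hc <- cohort[cohort$group == "HC", ]
  pt <- cohort[cohort$group == "sICH", ]
  rows <- list()
  cont_row <- function(label, x_hc, x_pt) {
    tt <- ttest_two_sample(x_pt[is.finite(x_pt)], x_hc[is.finite(x_hc)])
    data.frame(variable = label,
               hc = sprintf("%.2f ± %.2f", mean(x_hc, na.rm = TRUE),
                            stats::sd(x_hc, na.rm = TRUE)),
               sich = sprintf("%.2f ± %.2f", mean(x_pt, na.rm = TRUE),
                              stats::sd(x_pt, na.rm = TRUE)),
               statistic = tt$statistic, p = tt$p,
               method = tt$method, stringsAsFactors = FALSE)
  }
  bin_row <- function(label, x_hc, x_pt) {
    a <- sum(x_hc == 1, na.rm = TRUE); b <- sum(x_hc == 0, na.rm = TRUE)
    c_ <- sum(x_pt == 1, na.rm = TRUE); d <- sum(x_pt == 0, na.rm = TRUE)
    ct <- categorical_2x2(a, b, c_, d, method = method_2x2)
    data.frame(variable = label,
               hc = sprintf("%d (%.1f%%)", a, 100 * a / (a + b)),
               sich = sprintf("%d (%.1f%%)", c_, 100 * c_ / (c_ + d)),
               statistic = ct$statistic, p = ct$p, method = ct$method,
               stringsAsFactors = FALSE)
  }
  rows$age <- cont_row("age", hc$age, pt$age)
  rows$female <- bin_row("female", as.integer(hc$sex == "F"),
                         as.integer(pt$sex == "F"))
  for (v in c("hypertension", "diabetes", "hyperlipemia", "smoking"))
    rows[[v]] <- bin_row(v, hc[[v]], pt[[v]])
  rows$ipsi <- cont_row("alps_ipsilateral", hc$alps_average,
                        pt$alps_ipsilateral)
  rows$contra <- cont_row("alps_contralateral", hc$alps_average,
                          pt$alps_contralateral)
  rows$avg <- cont_row("alps_average", hc$alps_average, pt$alps_average)
  do.call(rbind, rows)
}

#' Outcome-determinants report within patients
#'
#' Compares patients with favorable (mRS 0-2) versus poor (mRS 3-6) 90-day
#' outcomes on demographics, risk factors, volumes and ALPS indices.
#'
#' @param cohort An `alps_cohort` table.
#' @return Data frame of per-variable group summaries and p-values.
#' @export
analyze_outcome_determinants <- function(cohort) {
  pt <- cohort[cohort$group == "sICH" & !is.na(cohort$mrs_90d), ]
  fav <- pt[pt$mrs_90d <= 2, ]; poor <- pt[pt$mrs_90d > 2, ]
  if (nrow(fav) < 2 || nrow(poor) < 2)
    stop("need at least 2 subjects per outcome group")
  rows <- list()
  cont_row <- function(label, xf, xp) {
    tt <- ttest_two_sample(xf[is.finite(xf)], xp[is.finite(xp)])
    data.frame(variable = label,
               favorable = sprintf("%.2f ± %.2f", mean(xf, na.rm = TRUE),
                                   stats::sd(xf, na.rm = TRUE)),
               poor = sprintf("%.2f ± %.2f", mean(xp, na.rm = TRUE),
                              stats::sd(xp, na.rm = TRUE)),
               statistic = tt$statistic, p = tt$p, stringsAsFactors = FALSE)
  }
  bin_row <- function(label, xf, xp) {
    a <- sum(xf == 1, na.rm = TRUE); b <- sum(xf == 0, na.rm = TRUE)
    c_ <- sum(xp == 1, na.rm = TRUE); d <- sum(xp == 0, na.rm = TRUE)
    ct <- categorical_2x2(a, b, c_, d)
    data.frame(variable = label,
               favorable = sprintf("%d (%.1f%%)", a, 100 * a / max(a + b, 1)),
               poor = sprintf("%d (%.1f%%)", c_, 100 * c_ / max(c_ + d, 1)),
               statistic = ct$statistic, p = ct$p, stringsAsFactors = FALSE)
  }
  rows$age <- cont_row("age", fav$age, poor$age)
  rows$female <- bin_row("female", as.integer(fav$sex == "F"),
                         as.integer(poor$sex == "F"))
  for (v in c("hypertension", "diabetes", "hyperlipemia", "smoking"))
    rows[[v]] <- bin_row(v, fav[[v]], poor[[v]])
  rows$nihss <- cont_row("nihss_baseline", fav$nihss_baseline,
                         poor$nihss_baseline)
  rows$hem <- cont_row("hemorrhage_volume_ml", fav$hemorrhage_volume_ml,
                       poor$hemorrhage_volume_ml)
  rows$ede <- cont_row("edema_volume_ml", fav$edema_volume_ml,
                       poor$edema_volume_ml)
  rows$ratio <- cont_row("relative_edema_ratio", fav$relative_edema_ratio,
                         poor$relative_edema_ratio)
  rows$ipsi <- cont_row("alps_ipsilateral", fav$alps_ipsilateral,
                        poor$alps_ipsilateral)
  rows$contra <- cont_row("alps_contralateral", fav$alps_contralateral,
                          poor$alps_contralateral)
  rows$avg <- cont_row("alps_average", fav$alps_average, poor$alps_average)
  do.call(rbind, rows)
}

#' ALPS-severity correlation report
#'
#' Correlations of each ALPS index (ipsilateral, contralateral, average)
#' with hemorrhage volume, edema volume and the relative edema ratio within
#' the patient group.
#'
#' @param cohort An `alps_cohort` table.
#' @param method Correlation method (default Pearson).
#' @return Data frame with columns `alps`, `against`, `r`, `n`, `p`.
#' @export
analyze_alps_correlations <- function(cohort, method = "pearson") {
  pt <- cohort[cohort$group == "sICH", ]
  alps_cols <- c(ipsilateral = "alps_ipsilateral",
                 contralateral = "alps_contralateral",
                 average = "alps_average")
  sev_cols <- c(hemorrhage_volume_ml = "hemorrhage_volume_ml",
                edema_volume_ml = "edema_volume_ml",
                relative_edema_ratio = "relative_edema_ratio")
  out <- list()
  for (an in names(alps_cols)) for (sn in names(sev_cols)) {
    cr <- correlation(pt[[alps_cols[[an]]]], pt[[sev_cols[[sn]]]], method)
    out[[paste(an, sn)]] <- data.frame(alps = an, against = sn, r = cr$r,
                                       n = cr$n, p = cr$p,
                                       stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Multivariable outcome model report
#'
#' Fits the binary logistic model for favorable 90-day outcome (mRS <= 2)
#' among supratentorial patients, adjusting for age, sex, baseline NIHSS and
#' hemorrhage volume, with the ipsilateral ALPS odds ratio reported per 0.1
#' increase.
#'
#' @param cohort An `alps_cohort` table.
#' @return Data frame with one row per predictor: OR (ALPS per 0.1), 95% CI
#'   and p.
#' @export
analyze_outcome_model <- function(cohort) {
  pt <- cohort[cohort$group == "sICH" &
               cohort$hemorrhage_side %in% c("left", "right") &
               !is.na(cohort$mrs_90d), ]
  X <- cbind(age = pt$age,
             sex = as.integer(pt$sex == "F"),
             nihss = pt$nihss_baseline,
             hemorrhage_volume_ml = pt$hemorrhage_volume_ml,
             alps_ipsilateral = pt$alps_ipsilateral)
  y <- as.integer(pt$mrs_90d <= 2)
  scale <- c(1, 1, 1, 1, 0.1)  # ALPS odds ratio reported per 0.1
  fit <- logistic_fit(X, y, or_scale = scale)
  data.frame(predictor = names(fit$coefficients),
             odds_ratio = fit$or_scaled,
             ci_low = fit$or_scaled_ci[, 1],
             ci_high = fit$or_scaled_ci[, 2],
             p = fit$p, stringsAsFactors = FALSE)
}
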