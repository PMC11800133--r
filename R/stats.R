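#' Group summary for two-sample tests from printed moments
#'
#' @param n Sample size (>= 2).
#' @param mean,sd Sample mean and standard deviation (sd > 0).
#' @return An object of class `summary_group`.
#' @export
summary_group <- function(n, mean, sd) {
  if (n < 2) stop("n must be >= 2")
  if (sd <= 0) stop("SD must be > 0")
  structure(list(n = n, mean = mean, sd = sd), class = "summary_group")
}

#' Kolmogorov-Smirnov normality test with estimated parameters
#'
#' One-sample KS distance of the sample against a normal with the sample's
#' own mean and SD. Because the parameters are estimated, the classical KS
#' null distribution is anticonservative; the p-value is therefore taken
#' from a seeded Monte-Carlo null (Lilliefors-style): `n_mc` standard-normal
#' samples of the same size, each re-standardised by its own moments. The
#' null table is cached per (n, n_mc, mc_seed), so repeated calls at one
#' sample size are cheap.
#'
#' @param x Numeric sample, n >= 5, non-constant.
#' @param n_mc Monte-Carlo replicates for the null (default 1000).
#' @param mc_seed Seed for the null simulation (recorded in the output).
#' @return A list of class `alps_test` with `statistic`, `p`, `method`,
#'   `n`, `mc_seed`.
#' @export
ks_normality <- function(x, n_mc = 1000, mc_seed = 42L) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 5) stop("need at least 5 observations")
  if (stats::sd(x) == 0) stop("constant sample: normality test undefined")
  D <- lilliefors_stat(x)
  null <- lilliefors_null(n, n_mc, mc_seed)
  p <- (1 + sum(null >= D)) / (n_mc + 1)
  structure(list(statistic = D, df = NA_real_, p = p,
                 method = "KS normality (estimated parameters, Monte-Carlo null)",
                 n = n, mc_seed = mc_seed),
            class = "alps_test")
}

lilliefors_stat <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / stats::sd(x))
  p <- stats::pnorm(z)
  max(max(seq_len(n) / n - p), max(p - (seq_len(n) - 1) / n))
}

.lilliefors_cache <- new.env(parent = emptyenv())

lilliefors_null <- function(n, n_mc, mc_seed) {
  key <- paste(n, n_mc, mc_seed, sep = "_")
  if (!is.null(.lilliefors_cache[[key]])) return(.lilliefors_cache[[key]])
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(mc_seed)
  null <- vapply(seq_len(n_mc),
                 function(i) lilliefors_stat(stats::rnorm(n)), numeric(1))
  .lilliefors_cache[[key]] <- null
  null
}

#' Two-sample t-test on raw samples or printed summaries
#'
#' Pooled-variance Student's t by default (`pooled = FALSE` gives Welch).
#' Accepts either two raw numeric vectors or two [summary_group()] objects;
#' both routes run through the same moment formulas, so results are
#' identical whenever the summaries equal the raw moments -- which is what
#' makes tests on published mean +/- SD tables possible.
#'
#' @param a,b Raw numeric vectors or `summary_group` objects.
#' @param pooled Use the pooled-variance Student's t (default TRUE).
#' @return An `alps_test` with `statistic`, `df`, `p` (two-sided), `method`.
#' @export
ttest_two_sample <- function(a, b, pooled = TRUE) {
  ga <- as_summary_group(a); gb <- as_summary_group(b)
  if (pooled) {
    sp2 <- ((ga$n - 1) * ga$sd^2 + (gb$n - 1) * gb$sd^2) / (ga$n + gb$n - 2)
    if (sp2 <= 0) stop("zero pooled variance")
    se <- sqrt(sp2 * (1 / ga$n + 1 / gb$n))
    df <- ga$n + gb$n - 2
    method <- "Student's t (pooled)"
  } else {
    va <- ga$sd^2 / ga$n; vb <- gb$sd^2 / gb$n
    if (va + vb <= 0) stop("zero variance")
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (ga$n - 1) + vb^2 / (gb$n - 1))
    method <- "Welch's t"
  }
  t <- (ga$mean - gb$mean) / se
  structure(list(statistic = t, df = df,
                 p = 2 * stats::pt(-abs(t), df), method = method),
            class = "alps_test")
}

as_summary_group <- function(x) {
  if (inherits(x, "summary_group")) return(x)
  x <- x[is.finite(x)]
  if (length(x) < 2) stop("n must be >= 2")
  # sd = 0 is allowed from raw data; the pooled-variance check rejects it
  structure(list(n = length(x), mean = mean(x), sd = stats::sd(x)),
            class = "summary_group")
}

#' @export
print.alps_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4f%s, p = %.4g\n", x$method, x$statistic,
              if (is.null(x$df) || is.na(x$df)) ""
              else sprintf(", df = %.5g", x$df), x$p))
  invisible(x)
}

#' Pearson or Spearman correlation with t-based p-value
#'
#' Pearson r with the exact t transform t = r sqrt((n-2)/(1-r^2)) on n - 2
#' degrees of freedom; Spearman applies the same machinery to average ranks
#' (ties receive mid-ranks). Pairs with missing values are dropped.
#'
#' @param x,y Numeric vectors.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A list of class `alps_correlation` with `r`, `n`, `p`, `method`.
#' @export
correlation <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  if (method == "spearman") { x <- rank(x); y <- rank(y) }
  r <- stats::cor(x, y)
  p <- if (abs(r) >= 1) 0 else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(t), n - 2)
  }
  structure(list(r = r, n = n, p = p, method = method),
            class = "alps_correlation")
}

#' @export
print.alps_correlation <- function(x, ...) {
  cat(sprintf("%s correlation: r = %.4f (n = %d), p = %.4g\n",
              x$method, x$r, x$n, x$p))
  invisible(x)
}

#' 2x2 contingency-table test
#'
#' The table is `rbind(c(a, b), c(c, d))` (rows = groups, columns = yes/no).
#' `"pearson"` is the uncorrected chi-square, `"yates"` the
#' continuity-corrected version, `"fisher"` the exact hypergeometric test;
#' `"auto"` (default) uses Fisher when any expected cell count is below 5
#' and Pearson otherwise -- the common reporting convention when the
#' original test variant is unstated.
#'
#' @param a,b,c,d Nonnegative integer cell counts.
#' @param method `"auto"`, `"pearson"`, `"yates"`, or `"fisher"`.
#' @return An `alps_test`.
#' @export
categorical_2x2 <- function(a, b, c, d,
                            method = c("auto", "pearson", "yates", "fisher")) {
  method <- match.arg(method)
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cells must be nonnegative integers")
  if (sum(cells) == 0) stop("all cells are zero")
  tab <- matrix(cells, 2, 2, byrow = TRUE)
  if (method == "auto") {
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    method <- if (any(expected < 5)) "fisher" else "pearson"
  }
  res <- switch(method,
    pearson = {
      h <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      list(stat = unname(h$statistic), df = unname(h$parameter), p = h$p.value)
    },
    yates = {
      h <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
      list(stat = unname(h$statistic), df = unname(h$parameter), p = h$p.value)
    },
    fisher = {
      h <- stats::fisher.test(tab)
      list(stat = unname(h$estimate), df = NA_real_, p = h$p.value)
    })
  structure(list(statistic = res$stat, df = res$df, p = res$p,
                 method = paste0("2x2 ", method)),
            class = "alps_test")
}

#' Logistic regression with per-unit odds-ratio rescaling
#'
#' Maximum-likelihood binomial fit (iteratively reweighted least squares via
#' `stats::glm`), Wald standard errors from the observed information, odds
#' ratios with 95% confidence intervals, and an optional rescaled odds ratio
#' per `or_scale` units of each predictor: OR_s = exp(s * beta), the
#' convention behind "per 0.1 increase" reporting. Complete separation is
#' detected (diverging coefficients / exploding standard errors) and raised
#' as an error naming the predictor.
#'
#' @param X Numeric design matrix (predictors only; an intercept is added).
#' @param y Binary outcome vector (0/1).
#' @param or_scale Optional named or unnamed numeric: units for rescaled
#'   odds ratios, e.g. 0.1 for "per 0.1 increase" (default 1).
#' @return An object of class `logistic_fit` with `coefficients`, `se`,
#'   `or`, `or_ci` (2-column matrix), `or_scaled`, `or_scaled_ci`, `p`,
#'   `converged`, `iterations`.
#' @export
logistic_fit <- function(X, y, or_scale = 1) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (any(!y %in% c(0, 1))) stop("outcome must be binary 0/1")
  if (nrow(X) <= ncol(X) + 1) stop("need n > predictors + 1")
  const <- apply(X, 2, function(col) stats::sd(col) == 0)
  if (any(const))
    stop("constant predictor: ", paste(colnames(X)[const], collapse = ", "))
  if (qr(cbind(1, X))$rank < ncol(X) + 1) stop("singular design matrix")
  dat <- data.frame(y = y, X)
  fit <- suppressWarnings(
    stats::glm(y ~ ., data = dat, family = stats::binomial()))
  beta <- stats::coef(fit)[-1]
  se <- sqrt(diag(stats::vcov(fit)))[-1]
  # separation: effect of one predictor SD explodes on the logit scale
  sds <- apply(X, 2, stats::sd)
  blown <- abs(beta * sds) > 30 | se * sds > 200
  if (!fit$converged || any(blown)) {
    worst <- colnames(X)[which.max(abs(beta * sds))]
    stop("separation detected for predictor: ", worst)
  }
  z <- beta / se
  ci <- cbind(lower = exp(beta - 1.96 * se), upper = exp(beta + 1.96 * se))
  s <- rep_len(or_scale, length(beta))
  structure(list(
    coefficients = beta, intercept = unname(stats::coef(fit)[1]), se = se,
    or = exp(beta), or_ci = ci,
    or_scaled = exp(s * beta),
    or_scaled_ci = cbind(lower = exp(s * (beta - 1.96 * se)),
                         upper = exp(s * (beta + 1.96 * se))),
    or_scale = s,
    p = 2 * stats::pnorm(-abs(z)),
    converged = fit$converged, iterations = fit$iter),
    class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("Logistic regression (ML via IRLS)\n")
  tab <- data.frame(beta = x$coefficients, se = x$se, OR = x$or,
                    ci_low = x$or_ci[, 1], ci_high = x$or_ci[, 2], p = x$p)
  print(round(tab, 4))
  invisible(x)
}

#' Ordinary least-squares fit with t-based p-values
#'
#' @param X Numeric design matrix (predictors only; intercept added).
#' @param y Numeric response.
#' @return A list of class `linear_fit` with `coefficients` (including
#'   intercept), `se`, `p`, `r_squared`, `residuals`.
#' @export
linear_fit <- function(X, y) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (qr(cbind(1, X))$rank < ncol(X) + 1) stop("rank-deficient design matrix")
  dat <- data.frame(y = y, X)
  fit <- stats::lm(y ~ ., data = dat)
  sm <- summary(fit)
  structure(list(coefficients = stats::coef(fit),
                 se = sm$coefficients[, 2],
                 p = sm$coefficients[, 4],
                 r_squared = sm$r.squared,
                 residuals = stats::residuals(fit)),
            class = "linear_fit")
}

#' Univariate covariate screen for multivariable models
#'
#' Tests each candidate against the outcome with the appropriate univariate
#' test (2x2 for binary-binary, two-sample t for continuous-binary,
#' correlation for continuous-continuous) and keeps those with p below the
#' threshold, plus a configurable always-include list -- the conventional
#' "p < 0.1 plus established covariates" model-building rule.
#'
#' @param data Data frame holding candidates and outcome.
#' @param candidates Character vector of candidate column names.
#' @param outcome Outcome column name.
#' @param threshold Univariate p-value threshold (default 0.1).
#' @param always_include Columns always retained (default age, sex, baseline
#'   NIHSS).
#' @return List with `selected` (character vector, union of screened-in and
#'   always-include) and `p_values` (named numeric).
#' @export
covariate_screen <- function(data, candidates, outcome, threshold = 0.1,
                             always_include = c("age", "sex",
                                                "nihss_baseline")) {
  is_binaryish <- function(v) {
    u <- unique(v[!is.na(v)])
    length(u) <= 2
  }
  yv <- data[[outcome]]
  pvals <- vapply(candidates, function(cn) {
    xv <- data[[cn]]
    if (is.character(xv) || is.factor(xv)) xv <- as.integer(factor(xv)) - 1L
    ok <- !is.na(xv) & !is.na(yv)
    x <- xv[ok]; y2 <- yv[ok]
    if (is.character(y2) || is.factor(y2)) y2 <- as.integer(factor(y2)) - 1L
    tryCatch({
      if (is_binaryish(x) && is_binaryish(y2)) {
        tab <- table(factor(x, levels = sort(unique(x))),
                     factor(y2, levels = sort(unique(y2))))
        if (!all(dim(tab) == c(2, 2))) return(NA_real_)
        categorical_2x2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])$p
      } else if (is_binaryish(y2)) {
        lv <- sort(unique(y2))
        ttest_two_sample(x[y2 == lv[1]], x[y2 == lv[2]])$p
      } else if (is_binaryish(x)) {
        lv <- sort(unique(x))
        ttest_two_sample(y2[x == lv[1]], y2[x == lv[2]])$p
      } else {
        correlation(x, y2)$p
      }
    }, error = function(e) NA_real_)
  }, numeric(1))
  keep <- candidates[!is.na(pvals) & pvals < threshold]
  list(selected = union(keep, intersect(always_include, names(data))),
       p_values = pvals)
}
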