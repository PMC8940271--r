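# Group-comparison pipeline and regression models for grana morphometry.

#' Normality-gated group comparison
#'
#' Tests the normality of the residuals (values minus group means) with
#' a Shapiro-Wilk test; if its p-value is at least `alpha` a one-way
#' ANOVA is run, otherwise a Kruskal-Wallis rank-sum test. If the
#' omnibus test is significant at `alpha`, all pairwise Student's
#' t-tests (pooled variance) are reported, unadjusted by default.
#'
#' @param values Numeric response vector.
#' @param group_labels Group labels, same length as `values`; at least
#'   two groups with n >= 3 each.
#' @param alpha Significance level for both the normality gate and the
#'   omnibus test.
#' @param p_adjust Multiplicity adjustment for the post hoc t-tests
#'   (a [stats::p.adjust()] method; `"none"` by default).
#' @return A list of class `group_comparison`: `branch`
#'   (`"anova"`/`"kruskal"`), `shapiro_p`, `omnibus_p`, `significant`,
#'   and `posthoc` (data.frame of pairwise comparisons, or `NULL`).
#' @export
compare_groups <- function(values, group_labels, alpha = 0.05,
                           p_adjust = "none") {
  g <- factor(group_labels)
  if (nlevels(g) < 2L) {
    stop("insufficient-data error: need >= 2 groups", call. = FALSE)
  }
  n_by <- table(g)
  if (any(n_by < 3L)) {
    stop(sprintf(
      "insufficient-data error: group '%s' has n = %d (< 3)",
      names(n_by)[which.min(n_by)], min(n_by)), call. = FALSE)
  }
  resid <- values - stats::ave(values, g)
  shapiro_p <- stats::shapiro.test(resid)$p.value
  if (shapiro_p >= alpha) {
    branch <- "anova"
    omnibus_p <- stats::anova(stats::aov(values ~ g))[["Pr(>F)"]][1L]
  } else {
    branch <- "kruskal"
    omnibus_p <- stats::kruskal.test(values, g)$p.value
  }
  significant <- is.finite(omnibus_p) && omnibus_p < alpha
  posthoc <- NULL
  if (significant) {
    pairs <- utils::combn(levels(g), 2L)
    rows <- lapply(seq_len(ncol(pairs)), function(i) {
      a <- pairs[1L, i]; b <- pairs[2L, i]
      tt <- stats::t.test(values[g == a], values[g == b],
                          var.equal = TRUE)
      data.frame(group1 = a, group2 = b,
                 estimate = unname(diff(rev(tt$estimate))),
                 statistic = unname(tt$statistic),
                 p_value = tt$p.value, stringsAsFactors = FALSE)
    })
    posthoc <- do.call(rbind, rows)
    posthoc$p_value <- stats::p.adjust(posthoc$p_value,
                                       method = p_adjust)
  }
  structure(list(branch = branch, shapiro_p = shapiro_p,
                 omnibus_p = omnibus_p, significant = significant,
                 alpha = alpha, posthoc = posthoc),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "<group_comparison> branch=%s (Shapiro p=%.3g), omnibus p=%.3g%s\n",
    x$branch, x$shapiro_p, x$omnibus_p,
    if (x$significant) " *" else ""))
  if (!is.null(x$posthoc)) print(x$posthoc)
  invisible(x)
}

# Coefficient table shared by the regression wrappers.
.model_fit_result <- function(fit, family, n_obs) {
  sm <- suppressWarnings(summary(fit))$coefficients
  structure(list(
    coefficients = data.frame(
      term = rownames(sm), estimate = sm[, 1L], std_error = sm[, 2L],
      statistic = sm[, 3L], p_value = sm[, 4L],
      row.names = NULL, stringsAsFactors = FALSE),
    family = family, n_obs = n_obs), class = "model_fit_result")
}

#' @export
print.model_fit_result <- function(x, ...) {
  cat(sprintf("<model_fit_result> family=%s, n=%d\n", x$family, x$n_obs))
  print(x$coefficients)
  invisible(x)
}

#' Poisson regression for grana stack counts
#'
#' Fits a Poisson generalized linear model with log link for the number
#' of layers per granum, `n_layers ~ genotype` or, when a covariate
#' column is named, `n_layers ~ genotype * covariate` (the
#' analysis-of-covariance form with interaction). Wald z statistics are
#' reported per coefficient. Counts are modeled as-is even though real
#' grana have at least one layer — a deliberate, mild misspecification
#' that keeps the standard model family.
#'
#' @param records Data.frame with columns `genotype`, `n_layers` and
#'   optionally a covariate.
#' @param covariate Optional name of a covariate column (ANCOVA with
#'   genotype x covariate interaction).
#' @return A `model_fit_result` with `family = "poisson_log"`.
#' @export
fit_stack_count_model <- function(records, covariate = NULL) {
  stopifnot(is.data.frame(records),
            all(c("genotype", "n_layers") %in% names(records)))
  if (any(records$n_layers < 1)) {
    stop("domain error: stack counts must be >= 1", call. = FALSE)
  }
  if (length(unique(records$genotype)) < 1L) {
    stop("insufficient-data error: no genotype levels", call. = FALSE)
  }
  fml <- if (is.null(covariate)) {
    n_layers ~ genotype
  } else {
    stats::as.formula(paste("n_layers ~ genotype *", covariate))
  }
  if (length(unique(records$genotype)) == 1L) {
    fml <- stats::update(fml, . ~ . - genotype)
    if (is.null(covariate)) fml <- n_layers ~ 1
  }
  fit <- stats::glm(fml, family = stats::poisson(link = "log"),
                    data = records,
                    control = stats::glm.control(epsilon = 1e-8,
                                                 maxit = 100))
  if (!fit$converged) {
    stop("convergence error: Poisson IRLS did not converge in 100 ",
         "iterations", call. = FALSE)
  }
  .model_fit_result(fit, "poisson_log", nrow(records))
}

#' Linear model for grana width
#'
#' Ordinary least squares `width_nm ~ genotype` (plus an optional
#' covariate interaction), reporting the genotype contrast with its t
#' statistic.
#'
#' @param records Data.frame with columns `genotype`, `width_nm`.
#' @param covariate Optional covariate column name.
#' @return A `model_fit_result` with `family = "gaussian_identity"`.
#' @export
fit_width_model <- function(records, covariate = NULL) {
  stopifnot(is.data.frame(records),
            all(c("genotype", "width_nm") %in% names(records)))
  if (stats::var(records$width_nm) == 0) {
    stop("degenerate error: zero variance in widths", call. = FALSE)
  }
  fml <- if (is.null(covariate)) {
    width_nm ~ genotype
  } else {
    stats::as.formula(paste("width_nm ~ genotype *", covariate))
  }
  fit <- stats::lm(fml, data = records)
  .model_fit_result(fit, "gaussian_identity", nrow(records))
}
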