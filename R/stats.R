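# Statistics stage: Box-Cox normalisation, per-parameter two-way
# (lesion compartment x patient group) ANOVA with partial eta-squared
# effect sizes, an optional multivariate omnibus, and the baseline
# group-comparison tests.

#' Box-Cox power transform by profile maximum likelihood
#'
#' y = (x^lambda - 1)/lambda for lambda != 0, ln(x) for lambda = 0.
#' lambda is chosen by maximising the profile log-likelihood on a grid
#' over [-3, 3] (step 0.01) followed by golden-section refinement in the
#' best bracket. Non-positive data are shifted by -min(x) plus a small
#' offset; the shift is recorded.
#'
#' @param values numeric vector, n >= 5.
#' @param grid lambda grid searched before refinement.
#' @return list with `lambda_hat`, `transformed`, `loglik_profile`
#'   (data.frame lambda, loglik), `shift`.
#' @export
box_cox_transform <- function(values, grid = seq(-3, 3, by = 0.01)) {
  x <- values[is.finite(values)]
  if (length(x) < 5L) stop("Box-Cox requires at least 5 finite values")
  if (diff(range(x)) == 0) stop("constant input: Box-Cox likelihood is degenerate")
  shift <- 0
  if (min(x) <= 0) {
    shift <- -min(x) + 1e-6 * diff(range(x))
    x <- x + shift
  }
  n <- length(x)
  slog <- sum(log(x))
  loglik <- function(lambda) {
    y <- if (abs(lambda) < 1e-12) log(x) else (x^lambda - 1) / lambda
    -n / 2 * log(mean((y - mean(y))^2)) + (lambda - 1) * slog
  }
  prof <- vapply(grid, loglik, numeric(1))
  i <- which.max(prof)
  lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
  lambda_hat <- optimize(loglik, c(lo, hi), maximum = TRUE,
                         tol = 1e-8)$maximum
  if (abs(lambda_hat) < 1e-6) lambda_hat <- 0
  y <- if (lambda_hat == 0) log(x) else (x^lambda_hat - 1) / lambda_hat
  list(lambda_hat = lambda_hat, transformed = y,
       loglik_profile = data.frame(lambda = grid, loglik = prof),
       shift = shift)
}

#' Classify a partial eta-squared effect size
#'
#' Thresholds 0.04 / 0.25 / 0.64 for small / moderate / large.
#'
#' @param partial_eta_sq value in [0, 1] (vectorised).
#' @return factor with levels negligible, small, moderate, large.
#' @export
classify_effect <- function(partial_eta_sq) {
  stopifnot(all(partial_eta_sq >= 0 & partial_eta_sq <= 1, na.rm = TRUE))
  cut(partial_eta_sq, breaks = c(-Inf, 0.04, 0.25, 0.64, Inf),
      labels = c("negligible", "small", "moderate", "large"),
      right = FALSE)
}

#' Two-way ANOVA with partial eta-squared per factor
#'
#' Fits response ~ compartment * group on the cohort table for one
#' parameter and reports, per factor (lesion compartment, patient group,
#' interaction), the sum of squares, F-test p-value, partial eta-squared
#' SS_effect / (SS_effect + SS_error) and its size class. The response is
#' Box-Cox transformed first when `transform = "boxcox"`, or when
#' `transform = "auto"` and a Shapiro-Wilk test rejects normality at
#' alpha = 0.05 (the decision and lambda are recorded in attributes).
#'
#' @param cohort cohort table with columns `voi`, `group` and the
#'   parameter.
#' @param parameter response column name.
#' @param transform `"auto"`, `"boxcox"` or `"none"`.
#' @return data.frame with one row per factor: parameter, factor, df,
#'   ss, f_value, p_value, partial_eta_sq, size_class; attributes
#'   `lambda`, `transform_applied`, `ss_error`, `ss_total`.
#' @export
two_way_anova_eta <- function(cohort, parameter,
                              transform = c("auto", "boxcox", "none")) {
  transform <- match.arg(transform)
  df <- data.frame(y = cohort[[parameter]],
                   region = factor(cohort$voi),
                   group = factor(cohort$group))
  df <- df[is.finite(df$y), ]
  cells <- table(df$region, df$group)
  if (any(cells == 0)) {
    bad <- which(cells == 0, arr.ind = TRUE)[1, ]
    stop(sprintf("empty cell: region '%s' x group '%s'",
                 rownames(cells)[bad[1]], colnames(cells)[bad[2]]))
  }
  lambda <- NA_real_; applied <- FALSE
  want <- transform == "boxcox" ||
    (transform == "auto" && length(unique(df$y)) > 2 &&
       shapiro.test(df$y)$p.value < 0.05)
  if (want) {
    bc <- box_cox_transform(df$y)
    df$y <- bc$transformed
    lambda <- bc$lambda_hat
    applied <- TRUE
  }
  fit <- lm(y ~ region * group, data = df)
  a <- anova(fit)
  ss <- a[["Sum Sq"]]; names(ss) <- rownames(a)
  ss_error <- ss[["Residuals"]]
  terms <- c(region = "lesion_compartment", group = "group",
             `region:group` = "interaction")
  out <- data.frame(
    parameter = parameter,
    factor = unname(terms),
    df = a[names(terms), "Df"],
    ss = unname(ss[names(terms)]),
    f_value = a[names(terms), "F value"],
    p_value = a[names(terms), "Pr(>F)"],
    stringsAsFactors = FALSE)
  out$partial_eta_sq <- out$ss / (out$ss + ss_error)
  out$size_class <- as.character(classify_effect(out$partial_eta_sq))
  rownames(out) <- NULL
  attr(out, "lambda") <- lambda
  attr(out, "transform_applied") <- applied
  attr(out, "ss_error") <- ss_error
  attr(out, "ss_total") <- sum(ss)
  out
}

#' Multivariate omnibus test (Pillai's trace) across parameters
#'
#' @param cohort cohort table.
#' @param parameters response columns.
#' @return summary table of `manova(cbind(...) ~ region * group)` with
#'   Pillai's trace.
#' @export
cohort_manova <- function(cohort,
                          parameters = c("adc_median", "tmax_median",
                                         "cbf_median", "cbv_median",
                                         "mtt_median")) {
  y <- as.matrix(cohort[, parameters])
  keep <- rowSums(!is.finite(y)) == 0L
  region <- factor(cohort$voi)[keep]
  group <- factor(cohort$group)[keep]
  fit <- manova(y[keep, ] ~ region * group)
  summary(fit, test = "Pillai")$stats
}

#' Baseline two-group comparison tests
#'
#' Dispatches Student's t-test (interval scale, normal), the exact
#' Mann-Whitney U-test (interval scale, non-normal) or Fisher's exact
#' test (nominal) and reports the two-sided p-value without multiplicity
#' correction. With `type = "auto"`, nominal data (factor/character)
#' go to Fisher and interval data to t or Mann-Whitney according to a
#' Shapiro-Wilk test at alpha = 0.05.
#'
#' @param values response vector (numeric, or factor/character for
#'   nominal).
#' @param group two-level grouping vector.
#' @param type `"auto"`, `"interval_normal"`, `"interval_nonnormal"`, or
#'   `"nominal"`.
#' @return list with `test`, `p_value`, `statistic`.
#' @export
baseline_tests <- function(values, group,
                           type = c("auto", "interval_normal",
                                    "interval_nonnormal", "nominal")) {
  type <- match.arg(type)
  group <- factor(group)
  stopifnot(nlevels(group) == 2L)
  if (type == "auto") {
    type <- if (!is.numeric(values)) "nominal"
    else if (shapiro.test(values)$p.value >= 0.05) "interval_normal"
    else "interval_nonnormal"
  }
  switch(type,
    interval_normal = {
      h <- t.test(values ~ group, var.equal = TRUE)
      list(test = "t", p_value = h$p.value,
           statistic = unname(h$statistic))
    },
    interval_nonnormal = {
      h <- wilcox.test(values ~ group, exact = TRUE, correct = FALSE)
      list(test = "mann_whitney_u", p_value = h$p.value,
           statistic = unname(h$statistic))
    },
    nominal = {
      h <- fisher.test(table(values, group))
      list(test = "fisher_exact", p_value = h$p.value, statistic = NA_real_)
    },
    stop("unknown variable type"))
}

#' Per-parameter effect-size report for a cohort
#'
#' Runs [two_way_anova_eta()] for every parameter and collects the
#' results, mirroring the compartment / group effect-size layout of the
#' study design this pipeline supports.
#'
#' @param cohort cohort table.
#' @param parameters response columns.
#' @param transform passed to [two_way_anova_eta()].
#' @return list with `effects` (stacked data.frame), `lambda` (named
#'   vector), `pillai` (omnibus table or NULL on failure).
#' @export
stats_report <- function(cohort,
                         parameters = c("adc_median", "tmax_median",
                                        "cbf_median", "cbv_median",
                                        "mtt_median"),
                         transform = "auto") {
  res <- lapply(parameters, function(p)
    two_way_anova_eta(cohort, p, transform = transform))
  lambda <- vapply(res, function(r) attr(r, "lambda"), numeric(1))
  names(lambda) <- parameters
  pillai <- tryCatch(cohort_manova(cohort, parameters),
                     error = function(e) NULL)
  list(effects = do.call(rbind, res), lambda = lambda, pillai = pillai)
}

#' Write a stats report to JSON
#' @param report result of [stats_report()].
#' @param path output path.
#' @export
write_stats_report <- function(report, path) {
  out <- list(
    effects = report$effects,
    box_cox_lambda = as.list(report$lambda),
    pillai = if (!is.null(report$pillai))
      as.data.frame(report$pillai) else NULL)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Format the effect-size report as a compartment x group table
#' @param report result of [stats_report()].
#' @return data.frame, one row per parameter, effect summaries as text.
#' @export
format_effect_table <- function(report) {
  e <- report$effects
  fmt <- function(p, f) {
    r <- e[e$parameter == p & e$factor == f, ]
    sprintf("eta2 = %.2f (p = %.3f, %s)", r$partial_eta_sq, r$p_value,
            r$size_class)
  }
  pars <- unique(e$parameter)
  data.frame(parameter = pars,
             lesion_compartment = vapply(pars, fmt, character(1),
                                         f = "lesion_compartment"),
             group = vapply(pars, fmt, character(1), f = "group"),
             row.names = NULL, stringsAsFactors = FALSE)
}
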