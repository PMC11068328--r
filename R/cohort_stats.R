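#' Summary statistics entering the cohort multivariate panel
#'
#' The default variable set for [pca_summary_stats()]: location
#' (mean/median/mode), spread (log variance, log IQR), shape (skewness,
#' excess kurtosis), the three displacement indices, and the summed peak
#' height `n`.
#'
#' @return Character vector of metric column names.
#' @export
panel_variables <- function() {
  c("mean", "median", "mode", "log_variance", "log_iqr", "skewness",
    "kurtosis_excess", "instability_index", "expansion_index",
    "contraction_index", "n")
}

#' PCA of the per-sample repeat-profile summary statistics
#'
#' Principal component analysis of the metric panel on the correlation
#' matrix: the panel mixes units (repeat units, log-variance, dimensionless
#' shape statistics), so each variable is standardized to zero mean and unit
#' variance before eigendecomposition. Components are ordered by decreasing
#' eigenvalue and signed so that each loading vector's largest-magnitude
#' entry is positive. Samples with any missing metric are dropped with a
#' message.
#'
#' @param metrics Per-sample metric tibble (e.g. from
#'   [instability_metrics()]), with label columns such as `sample_id`,
#'   `tissue`, `genotype` carried through to the scores.
#' @param vars Metric columns to include; defaults to the intersection of
#'   [panel_variables()] with the columns present.
#' @return An object of class `repeat_pca` with elements `scores`,
#'   `loadings` (tibbles) and `var_explained` (fractions summing to 1).
#'   Use [tidy()], [glance()] and [autoplot()] on it.
#' @export
pca_summary_stats <- function(metrics, vars = NULL) {
  vars <- vars %||% intersect(panel_variables(), names(metrics))
  check_columns(metrics, vars, "metric panel")
  label_cols <- intersect(c("sample_id", "mouse_id", "tissue", "genotype"),
    names(metrics))
  complete <- stats::complete.cases(metrics[, vars, drop = FALSE])
  if (any(!complete)) {
    inform(sprintf("Dropping %d sample(s) with missing metrics from PCA.",
      sum(!complete)))
    metrics <- metrics[complete, , drop = FALSE]
  }
  if (nrow(metrics) < 3L) {
    abort("PCA needs >= 3 complete samples.", class = "repquant_argument_error")
  }
  if (length(vars) < 2L) {
    abort("PCA needs >= 2 variables.", class = "repquant_argument_error")
  }
  x <- as.matrix(metrics[, vars, drop = FALSE])
  sds <- apply(x, 2L, sd)
  if (any(sds == 0)) {
    abort(sprintf("Constant column(s) cannot be standardized: %s.",
      paste0("`", vars[sds == 0], "`", collapse = ", ")),
      class = "repquant_constant_column_error")
  }
  fit <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  # Sign convention: the largest-magnitude loading of each PC is positive.
  flip <- apply(fit$rotation, 2L, function(v) sign(v[which.max(abs(v))]))
  fit$rotation <- sweep(fit$rotation, 2L, flip, `*`)
  fit$x <- sweep(fit$x, 2L, flip, `*`)
  eig <- fit$sdev^2
  pcs <- paste0("PC", seq_along(eig))
  colnames(fit$rotation) <- colnames(fit$x) <- pcs
  structure(
    list(
      scores = dplyr::bind_cols(metrics[, label_cols, drop = FALSE],
        tibble::as_tibble(fit$x)),
      loadings = dplyr::bind_cols(tibble::tibble(variable = vars),
        tibble::as_tibble(fit$rotation)),
      var_explained = setNames(eig / sum(eig), pcs),
      center = fit$center, scale = fit$scale, vars = vars,
      n = nrow(metrics)
    ),
    class = "repeat_pca"
  )
}

#' @export
print.repeat_pca <- function(x, ...) {
  ve <- x$var_explained
  cat(sprintf(
    "<repeat_pca> %d samples x %d variables; PC1 %.1f%%, PC1-2 %.1f%% of variance\n",
    x$n, length(x$vars), 100 * ve[1L], 100 * sum(ve[seq_len(min(2L, length(ve)))])))
  invisible(x)
}

#' @describeIn pca_summary_stats Tidy the scores, loadings or eigenvalues.
#' @param x A `repeat_pca` object.
#' @param matrix One of `"scores"`, `"loadings"`, `"eigenvalues"`.
#' @param ... Unused.
#' @export
tidy.repeat_pca <- function(x, matrix = c("scores", "loadings",
                                          "eigenvalues"), ...) {
  matrix <- match.arg(matrix)
  switch(matrix,
    scores = x$scores,
    loadings = x$loadings,
    eigenvalues = tibble::tibble(
      component = names(x$var_explained),
      var_explained = as.double(x$var_explained),
      cumulative = cumsum(as.double(x$var_explained))
    )
  )
}

#' @describeIn pca_summary_stats One-row model summary.
#' @export
glance.repeat_pca <- function(x, ...) {
  ve <- as.double(x$var_explained)
  tibble::tibble(
    n_samples = x$n, n_variables = length(x$vars),
    var_explained_pc1 = ve[1L],
    var_explained_pc12 = sum(ve[seq_len(min(2L, length(ve)))])
  )
}

#' ANCOVA of a striatal metric with the ear-tissue covariate
#'
#' Ordinary least squares of `response ~ genotype + covariate` with
#' treatment-coded genotype: the per-mouse ear (baseline) value of the same
#' metric enters as a covariate so that the genotype effect is estimated
#' over and above any non-specific baseline shift. Least-squares means are
#' the model predictions per genotype at the covariate's grand mean, with
#' t-based confidence intervals on the residual degrees of freedom; the
#' genotype effect is tested with a partial F-test. With
#' `log_transform = TRUE` the response and covariate are log10-transformed
#' before fitting (appropriate for variance-type responses) and the reported
#' least-squares means are back-transformed geometric means.
#'
#' @param data Data frame with one row per sample.
#' @param response Name of the response column.
#' @param genotype Name of the genotype factor column (>= 2 levels with
#'   >= 2 samples each).
#' @param covariate Name of the covariate column, or `NULL` to fit a plain
#'   one-way model (no covariate adjustment).
#' @param log_transform Log10-transform response and covariate first.
#' @param conf_level Confidence level for the least-squares means.
#' @return An object of class `repeat_ancova`; see [tidy()], [glance()],
#'   [ls_means()] and [autoplot()].
#' @export
ancova_least_squares <- function(data, response, genotype,
                                 covariate = NULL, log_transform = FALSE,
                                 conf_level = 0.95) {
  check_columns(data, c(response, genotype, covariate),
    "ANCOVA input")
  df <- tibble::tibble(
    .y = as.double(data[[response]]),
    .g = factor(data[[genotype]])
  )
  if (!is.null(covariate)) df$.x <- as.double(data[[covariate]])
  df <- df[stats::complete.cases(df), , drop = FALSE]
  tab <- table(df$.g)
  if (length(tab) < 2L || any(tab < 2L)) {
    abort("Need >= 2 genotype levels with >= 2 samples each.",
      class = "repquant_argument_error")
  }
  if (log_transform) {
    if (any(df$.y <= 0) || (!is.null(covariate) && any(df$.x <= 0))) {
      abort("log_transform requires strictly positive response and covariate.",
        class = "repquant_argument_error")
    }
    df$.y <- log10(df$.y)
    if (!is.null(covariate)) df$.x <- log10(df$.x)
  }
  has_cov <- !is.null(covariate)
  fit <- if (has_cov) lm(.y ~ .g + .x, data = df) else lm(.y ~ .g, data = df)
  if (anyNA(coef(fit))) {
    abort("Singular design: the covariate is collinear with the genotype indicators.",
      class = "repquant_singular_error")
  }
  reduced <- if (has_cov) lm(.y ~ .x, data = df) else lm(.y ~ 1, data = df)
  ftest <- anova(reduced, fit)
  x_bar <- if (has_cov) mean(df$.x) else NULL

  # Least-squares means: prediction per genotype at the covariate grand mean.
  lev <- levels(df$.g)
  newdata <- tibble::tibble(.g = factor(lev, levels = lev))
  if (has_cov) newdata$.x <- x_bar
  pr <- predict(fit, newdata = newdata, se.fit = TRUE)
  tcrit <- qt(1 - (1 - conf_level) / 2, df = fit$df.residual)
  lsm <- tibble::tibble(
    genotype = lev,
    estimate = as.double(pr$fit),
    std_error = as.double(pr$se.fit),
    conf_low = .data$estimate - tcrit * .data$std_error,
    conf_high = .data$estimate + tcrit * .data$std_error
  )
  if (log_transform) {
    lsm <- lsm |>
      dplyr::mutate(estimate = 10^.data$estimate,
        conf_low = 10^.data$conf_low, conf_high = 10^.data$conf_high,
        std_error = NA_real_)
  }
  structure(
    list(
      response = response, genotype = genotype, covariate = covariate,
      log_transform = log_transform, conf_level = conf_level,
      fit = fit, ls_means = lsm,
      f_statistic = ftest$F[2L],
      df = ftest$Df[2L], df_residual = fit$df.residual,
      p_value = ftest$`Pr(>F)`[2L],
      covariate_mean = x_bar
    ),
    class = "repeat_ancova"
  )
}

#' Least-squares means of a fitted ANCOVA
#'
#' @param x A `repeat_ancova` object.
#' @return Tibble with one row per genotype level: `estimate`, `std_error`,
#'   `conf_low`, `conf_high` (back-transformed geometric means when the
#'   model was fitted on the log scale).
#' @export
ls_means <- function(x) {
  stopifnot(inherits(x, "repeat_ancova"))
  x$ls_means
}

#' @export
print.repeat_ancova <- function(x, ...) {
  cat(sprintf(
    "<repeat_ancova> %s ~ %s%s%s | F(%d, %d) = %.3f, p = %.3g\n",
    x$response, x$genotype,
    if (!is.null(x$covariate)) paste0(" + ", x$covariate) else "",
    if (x$log_transform) " (log10 scale)" else "",
    x$df, x$df_residual, x$f_statistic, x$p_value))
  invisible(x)
}

#' @describeIn ancova_least_squares Coefficient table of the underlying fit.
#' @param x A `repeat_ancova` object.
#' @param ... Unused.
#' @export
tidy.repeat_ancova <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(
    term = rownames(s),
    estimate = unname(s[, "Estimate"]),
    std_error = unname(s[, "Std. Error"]),
    statistic = unname(s[, "t value"]),
    p_value = unname(s[, "Pr(>|t|)"])
  )
}

#' @describeIn ancova_least_squares One-row summary with the genotype
#'   effect test.
#' @export
glance.repeat_ancova <- function(x, ...) {
  tibble::tibble(
    response = x$response,
    log_transform = x$log_transform,
    f_statistic = x$f_statistic,
    df = x$df, df_residual = x$df_residual,
    p_value = x$p_value,
    r_squared = summary(x$fit)$r.squared,
    sigma = summary(x$fit)$sigma
  )
}
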