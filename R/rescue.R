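#' Reversal-class thresholds for the alpha multiplier
#'
#' The four cut points on the alpha axis separating the five reversal
#' classes: super-reversal (alpha < -1.3), full reversal (-1.3 to -0.7),
#' partial reversal (-0.7 to -0.3), negligible (-0.3 to 0.3) and
#' exacerbation (alpha > 0.3).
#'
#' @param cuts Strictly increasing numeric vector of four cut points.
#' @return The validated cut-point vector.
#' @export
class_thresholds <- function(cuts = c(-1.3, -0.7, -0.3, 0.3)) {
  if (length(cuts) != 4L || any(diff(cuts) <= 0)) {
    abort("`cuts` must be 4 strictly increasing thresholds.",
      class = "repquant_argument_error")
  }
  as.double(cuts)
}

#' The five reversal-class labels, ordered from strongest reversal to
#' exacerbation
#'
#' @return Character vector of class labels.
#' @export
rescue_classes <- function() {
  c("super_reversal", "full_reversal", "partial_reversal", "negligible",
    "exacerbation")
}

#' Filter a contrast table to the dysregulated signature
#'
#' Keeps genes significant after multiple-test correction
#' (`padj < padj_max`) with a fold change of at least `min_fold` in either
#' direction (`|log2fc| >= log2(min_fold)`); row order is preserved.
#'
#' @param table Contrast tibble with columns `gene_id`, `log2fc`, `se`,
#'   `padj`.
#' @param padj_max Adjusted-p cutoff (default 0.05).
#' @param min_fold Minimum fold change (default 1.2, i.e. 20% either way).
#' @return The retained rows.
#' @export
filter_signature <- function(table, padj_max = 0.05, min_fold = 1.2) {
  check_columns(table, c("gene_id", "log2fc", "padj"), "contrast table")
  dplyr::filter(table, .data$padj < padj_max,
    abs(.data$log2fc) >= log2(min_fold))
}

#' Alpha multiplier of the knockout effect on the disease signature
#'
#' Expresses the rescue-genotype effect on each gene as a multiple of that
#' gene's disease-signature log2 fold change: `alpha = beta_ko / beta_hd`.
#' Negative alpha means the disease effect is reversed by the knockout,
#' positive alpha that it is exacerbated. The standard error follows by
#' first-order (delta-method) propagation assuming independent contrast
#' errors. Genes with `|beta_hd| < min_abs_beta` are marked not evaluable
#' (the ratio is unstable) rather than classified.
#'
#' @param beta_hd Disease-vs-control log2 fold changes.
#' @param beta_ko Rescue-genotype effect log2 fold changes (knockout in the
#'   disease background).
#' @param se_hd,se_ko Standard errors of the two contrasts.
#' @param min_abs_beta Evaluability floor on `|beta_hd|` (log2 units).
#' @return A tibble with `alpha`, `alpha_se`, `evaluable`.
#' @examples
#' alpha_estimate(1, -0.5, 0.1, 0.1)
#' @export
alpha_estimate <- function(beta_hd, beta_ko, se_hd, se_ko,
                           min_abs_beta = 0.05) {
  if (any(se_hd <= 0, na.rm = TRUE) || any(se_ko <= 0, na.rm = TRUE)) {
    abort("Standard errors must be > 0.", class = "repquant_argument_error")
  }
  evaluable <- abs(beta_hd) >= min_abs_beta & !is.na(beta_hd) & !is.na(beta_ko)
  alpha <- ifelse(evaluable, beta_ko / beta_hd, NA_real_)
  # Var(a) ~ (se_ko / b_hd)^2 + (a * se_hd / b_hd)^2; this form reduces to
  # se_ko / |b_hd| at b_ko = 0 and to the usual relative-error sum otherwise.
  alpha_se <- ifelse(evaluable,
    sqrt((se_ko / beta_hd)^2 + (alpha * se_hd / beta_hd)^2), NA_real_)
  tibble::tibble(alpha = alpha, alpha_se = alpha_se, evaluable = evaluable)
}

#' Classify an alpha estimate into a reversal class
#'
#' Partitions the real line with the printed cut points; each boundary value
#' is assigned to the class nearer zero (conservative against claiming
#' rescue): `(-Inf, c1)` super, `[c1, c2)` full, `[c2, c3)` partial,
#' `[c3, c4]` negligible, `(c4, Inf)` exacerbation.
#'
#' @param alpha Numeric vector of alpha estimates.
#' @param thresholds Cut points from [class_thresholds()].
#' @return A factor with levels `super_reversal`, `full_reversal`,
#'   `partial_reversal`, `negligible`, `exacerbation`.
#' @export
classify_alpha <- function(alpha, thresholds = class_thresholds()) {
  thresholds <- class_thresholds(thresholds)
  cls <- rescue_classes()
  out <- rep(NA_character_, length(alpha))
  out[alpha < thresholds[1L]] <- cls[1L]
  out[alpha >= thresholds[1L] & alpha < thresholds[2L]] <- cls[2L]
  out[alpha >= thresholds[2L] & alpha < thresholds[3L]] <- cls[3L]
  out[alpha >= thresholds[3L] & alpha <= thresholds[4L]] <- cls[4L]
  out[alpha > thresholds[4L]] <- cls[5L]
  factor(out, levels = cls)
}

#' Monte-Carlo reversal-class probabilities
#'
#' Propagates the alpha uncertainty into class membership probabilities by
#' drawing from `Normal(alpha, alpha_se^2)` and classifying each draw; the
#' overall reversal probability is `P(alpha < c3)`, i.e. the summed
#' probability of the three reversal classes. This is a Gaussian
#' approximation with independent contrast errors; draws are seeded per
#' gene so results are reproducible and insensitive to gene order.
#'
#' @param alpha,alpha_se Alpha estimates and standard errors (vectors).
#' @param thresholds Cut points from [class_thresholds()].
#' @param n_draws Monte-Carlo draws per gene (>= 1000).
#' @param seed Integer seed.
#' @return A tibble with one row per gene: `p_super_reversal` ...
#'   `p_exacerbation` and `reversal_probability`.
#' @export
reversal_probabilities <- function(alpha, alpha_se,
                                   thresholds = class_thresholds(),
                                   n_draws = 10000L, seed = 1L) {
  thresholds <- class_thresholds(thresholds)
  if (n_draws < 1000L) {
    abort("`n_draws` must be >= 1000.", class = "repquant_argument_error")
  }
  if (any(alpha_se[!is.na(alpha_se)] <= 0)) {
    abort("`alpha_se` must be > 0.", class = "repquant_argument_error")
  }
  cls <- rescue_classes()
  rows <- purrr::map2(seq_along(alpha), alpha_se[seq_along(alpha)],
    function(i, se) {
      if (is.na(alpha[i]) || is.na(se)) {
        return(setNames(rep(NA_real_, 5L), cls))
      }
      set.seed(derive_seed(seed, i))
      draws <- rnorm(n_draws, mean = alpha[i], sd = se)
      counts <- table(classify_alpha(draws, thresholds))
      setNames(as.double(counts[cls]) / n_draws, cls)
    })
  out <- tibble::as_tibble(do.call(rbind, rows))
  names(out) <- paste0("p_", cls)
  out$reversal_probability <- out$p_super_reversal + out$p_full_reversal +
    out$p_partial_reversal
  out
}

#' Classify per-gene transcriptional rescue from two contrast tables
#'
#' End-to-end rescue analysis: filters the disease-vs-control contrast to
#' the dysregulated signature, joins the rescue-genotype contrast by gene,
#' computes the alpha multiplier with its delta-method error, assigns the
#' point-estimate reversal class and Monte-Carlo class probabilities, and
#' summarizes class counts and rescue percentages.
#'
#' @param hd_table Disease-vs-control contrast (columns `gene_id`, `log2fc`,
#'   `se`, `padj`).
#' @param ko_table Rescue-genotype-effect contrast with the same columns
#'   (effect of the knockout in the disease background).
#' @param padj_max,min_fold Signature filter settings
#'   (see [filter_signature()]).
#' @param min_abs_beta Alpha evaluability floor (see [alpha_estimate()]).
#' @param thresholds Reversal-class cut points.
#' @param n_draws,seed Monte-Carlo settings (see
#'   [reversal_probabilities()]).
#' @return An object of class `rescue_analysis` with elements `records`
#'   (per-gene tibble) and `summary` (one-row tibble); see [tidy()],
#'   [glance()], [summarize_rescue()], [autoplot()].
#' @export
rescue_analysis <- function(hd_table, ko_table, padj_max = 0.05,
                            min_fold = 1.2, min_abs_beta = 0.05,
                            thresholds = class_thresholds(),
                            n_draws = 10000L, seed = 1L) {
  check_columns(hd_table, c("gene_id", "log2fc", "se", "padj"),
    "disease contrast")
  check_columns(ko_table, c("gene_id", "log2fc", "se"), "rescue contrast")
  sig <- filter_signature(hd_table, padj_max, min_fold)
  records <- sig |>
    dplyr::select("gene_id", beta_hd = "log2fc", se_hd = "se",
      padj_hd = "padj") |>
    dplyr::inner_join(
      dplyr::select(ko_table, "gene_id", beta_ko = "log2fc", se_ko = "se"),
      by = "gene_id")
  est <- alpha_estimate(records$beta_hd, records$beta_ko, records$se_hd,
    records$se_ko, min_abs_beta)
  records <- dplyr::bind_cols(records, est)
  records$class_label <- classify_alpha(records$alpha, thresholds)
  probs <- reversal_probabilities(records$alpha, records$alpha_se,
    thresholds, n_draws, seed)
  records <- dplyr::bind_cols(records, probs)
  structure(
    list(
      records = records,
      summary = summarize_rescue(records),
      n_signature = nrow(sig),
      params = list(padj_max = padj_max, min_fold = min_fold,
        min_abs_beta = min_abs_beta, thresholds = thresholds,
        n_draws = n_draws, seed = seed,
        probability_method = "gaussian_monte_carlo_independent_errors")
    ),
    class = "rescue_analysis"
  )
}

#' Summarize reversal classes over a set of rescue records
#'
#' Counts genes per reversal class among evaluable genes and reports the
#' percentage rescued (any reversal class: super + full + partial) and
#' exacerbated. The full + partial tally is also reported separately so the
#' narrower reading of "rescued" is recoverable.
#'
#' @param records Per-gene tibble with `class_label` and `evaluable`
#'   columns (as produced by [rescue_analysis()]).
#' @return A one-row tibble of counts and percentages; percentages are `NA`
#'   with `undefined = TRUE` when no gene is evaluable.
#' @export
summarize_rescue <- function(records) {
  check_columns(records, c("class_label", "evaluable"), "rescue records")
  ev <- records[records$evaluable, , drop = FALSE]
  counts <- table(factor(ev$class_label, levels = rescue_classes()))
  n_ev <- nrow(ev)
  pct <- function(k) if (n_ev > 0L) 100 * k / n_ev else NA_real_
  counts <- setNames(as.integer(counts), names(counts))
  n_rescued <- sum(counts[c("super_reversal", "full_reversal",
    "partial_reversal")])
  tibble::tibble(
    n_evaluable = n_ev,
    n_not_evaluable = sum(!records$evaluable),
    n_super_reversal = as.integer(counts["super_reversal"]),
    n_full_reversal = as.integer(counts["full_reversal"]),
    n_partial_reversal = as.integer(counts["partial_reversal"]),
    n_negligible = as.integer(counts["negligible"]),
    n_exacerbation = as.integer(counts["exacerbation"]),
    percent_rescued = pct(n_rescued),
    percent_full_partial = pct(sum(counts[c("full_reversal",
      "partial_reversal")])),
    percent_exacerbated = pct(unname(counts["exacerbation"])),
    undefined = n_ev == 0L
  )
}

#' Overlap of a reference gene signature with the study's rescue calls
#'
#' @param signature_genes Gene ids of a reference signature (e.g. the
#'   striatal signature of robustly dysregulated genes); duplicates are
#'   removed with a warning.
#' @param records Per-gene rescue tibble (see [rescue_analysis()]).
#' @param dysregulated_ids Gene ids called dysregulated in this study.
#' @return A one-row tibble: `n_signature`, `n_detected` (signature genes
#'   among the dysregulated set), `n_reversed` (detected genes in any
#'   reversal class), `n_exacerbated`.
#' @export
signature_overlap <- function(signature_genes, records, dysregulated_ids) {
  if (anyDuplicated(signature_genes)) {
    warn(sprintf("%d duplicate signature gene id(s) removed.",
      sum(duplicated(signature_genes))))
    signature_genes <- unique(signature_genes)
  }
  detected <- intersect(signature_genes, dysregulated_ids)
  hit <- records[records$gene_id %in% detected & records$evaluable, ,
    drop = FALSE]
  reversal <- c("super_reversal", "full_reversal", "partial_reversal")
  tibble::tibble(
    n_signature = length(signature_genes),
    n_detected = length(detected),
    n_reversed = sum(hit$class_label %in% reversal),
    n_exacerbated = sum(hit$class_label == "exacerbation")
  )
}

#' @export
print.rescue_analysis <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<rescue_analysis> %d signature genes, %d evaluable; %.1f%% rescued, %.1f%% exacerbated\n",
    x$n_signature, s$n_evaluable, s$percent_rescued, s$percent_exacerbated))
  invisible(x)
}

#' @describeIn rescue_analysis Per-gene records tibble.
#' @param x A `rescue_analysis` object.
#' @param ... Unused.
#' @export
tidy.rescue_analysis <- function(x, ...) {
  x$records
}

#' @describeIn rescue_analysis One-row class-count and percentage summary.
#' @export
glance.rescue_analysis <- function(x, ...) {
  x$summary
}
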