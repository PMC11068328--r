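#' Normalize a repeat profile to relative peak probabilities
#'
#' Converts raw peak heights into a discrete probability distribution over
#' repeat lengths: peaks below `rel_threshold` times the tallest peak of the
#' profile are discarded (the standard guard against stutter ladder and
#' baseline noise in fragment-analysis profiles), and retained heights are
#' normalized to sum to one. Works on a single profile or a multi-sample
#' peak tibble (normalization is per `sample_id`).
#'
#' @param peaks Peak tibble with `repeat_count` and `height` columns (and
#'   optionally `sample_id` plus metadata).
#' @param rel_threshold Relative height threshold in `[0, 1)`; the default
#'   0.10 discards peaks under 10% of the profile maximum.
#' @return The retained rows with an added `prob` column summing to 1 within
#'   each sample, and `rel_threshold` recorded as a column.
#' @export
normalize_profile <- function(peaks, rel_threshold = 0.1) {
  check_columns(peaks, c("repeat_count", "height"), "profile")
  check_fraction(rel_threshold, "rel_threshold")
  if (!"sample_id" %in% names(peaks)) {
    peaks <- dplyr::mutate(peaks, sample_id = NA_character_, .before = 1L)
  }
  degenerate <- peaks |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(max_h = max(.data$height), .groups = "drop") |>
    dplyr::filter(.data$max_h <= 0)
  if (nrow(degenerate) > 0L) {
    abort(sprintf("Degenerate profile (all peak heights zero) for sample%s %s.",
      if (nrow(degenerate) > 1L) "s" else "",
      paste0("`", degenerate$sample_id, "`", collapse = ", ")),
      class = "repquant_degenerate_error")
  }
  peaks |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::filter(.data$height >= rel_threshold * max(.data$height),
      .data$height > 0) |>
    dplyr::mutate(prob = .data$height / sum(.data$height),
      rel_threshold = rel_threshold) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$sample_id, .data$repeat_count)
}

single_profile <- function(norm, caller) {
  if ("sample_id" %in% names(norm) &&
      dplyr::n_distinct(norm$sample_id) > 1L) {
    abort(sprintf(
      "`%s()` expects a single profile; got %d samples. Use `instability_metrics()` for cohorts.",
      caller, dplyr::n_distinct(norm$sample_id)),
      class = "repquant_argument_error")
  }
  if (nrow(norm) == 0L) {
    abort(sprintf("`%s()` got an empty profile.", caller),
      class = "repquant_argument_error")
  }
  norm
}

profile_probs <- function(norm) {
  if ("prob" %in% names(norm)) {
    norm$prob
  } else {
    norm$height / sum(norm$height)
  }
}

#' Modal repeat length of a profile
#'
#' The repeat length carrying the tallest (highest-probability) peak; ties
#' are broken toward the smallest repeat.
#'
#' @param norm A single normalized profile (see [normalize_profile()]); a
#'   raw single-profile peak tibble is also accepted.
#' @return The modal repeat length as an integer.
#' @export
modal_repeat <- function(norm) {
  norm <- single_profile(norm, "modal_repeat")
  p <- profile_probs(norm)
  reps <- norm$repeat_count
  candidates <- reps[p >= max(p) - 1e-12]
  as.integer(min(candidates))
}

#' Instability, expansion and contraction indices
#'
#' The instability index is the peak-height-weighted mean displacement of a
#' repeat profile from a reference modal allele: with displacement
#' `d_i = repeat_i - ref_mode` and retained-peak probabilities `p_i`,
#' the instability index is `sum(p_i * d_i)`, the expansion index sums only
#' positive displacements and the contraction index the magnitudes of
#' negative displacements, so that
#' `instability = expansion - contraction` exactly. Probabilities are
#' normalized over all retained peaks (not renormalized within each side).
#'
#' @param norm A single normalized profile.
#' @param ref_mode Reference modal repeat (typically the ear-biopsy mode).
#' @return A one-row tibble with `instability_index`, `expansion_index`,
#'   `contraction_index`.
#' @examples
#' prof <- tibble::tibble(repeat_count = 185:187, height = c(1000, 400, 100))
#' instability_indices(normalize_profile(prof, 0.1), ref_mode = 185)
#' @export
instability_indices <- function(norm, ref_mode) {
  norm <- single_profile(norm, "instability_indices")
  stopifnot(is.numeric(ref_mode), length(ref_mode) == 1L, ref_mode >= 1)
  p <- profile_probs(norm)
  d <- norm$repeat_count - ref_mode
  tibble::tibble(
    instability_index = sum(p * d),
    expansion_index = sum(p[d > 0] * d[d > 0]),
    contraction_index = sum(p[d < 0] * abs(d[d < 0]))
  )
}

#' Probability-weighted summary statistics of a repeat profile
#'
#' Weighted mean and central moments of the retained repeat-length
#' distribution (`variance = sum(p * (x - mu)^2)`,
#' `skewness = m3 / m2^1.5`, excess kurtosis `m4 / m2^2 - 3`), weighted
#' quartiles by linear interpolation on the cumulative probability over
#' sorted repeats, and the summed retained height `n`. Log columns are
#' `log10(value + 1e-6)`. A single-peak (zero-variance) profile gets
#' skewness and kurtosis 0 with `degenerate = TRUE` rather than `NaN`.
#'
#' @param norm A single normalized profile.
#' @return A one-row tibble with `mean`, `median`, `variance`,
#'   `log_variance`, `iqr`, `log_iqr`, `skewness`, `kurtosis_excess`, `n`,
#'   `degenerate`.
#' @export
weighted_summary_stats <- function(norm) {
  norm <- single_profile(norm, "weighted_summary_stats")
  p <- profile_probs(norm)
  x <- as.double(norm$repeat_count)
  n_total <- sum(norm$height)
  mu <- sum(p * x)
  m2 <- sum(p * (x - mu)^2)
  m3 <- sum(p * (x - mu)^3)
  m4 <- sum(p * (x - mu)^4)
  degenerate <- m2 <= 0
  q <- weighted_quantile(x, p, c(0.25, 0.5, 0.75))
  iqr <- q[3L] - q[1L]
  eps <- 1e-6
  tibble::tibble(
    mean = mu,
    median = q[2L],
    variance = m2,
    log_variance = log10(m2 + eps),
    iqr = iqr,
    log_iqr = log10(iqr + eps),
    skewness = if (degenerate) 0 else m3 / m2^1.5,
    kurtosis_excess = if (degenerate) 0 else m4 / m2^2 - 3,
    n = n_total,
    degenerate = degenerate
  )
}

# Quantiles by linear interpolation on the cumulative probability of the
# sorted support; clamped to the support ends.
weighted_quantile <- function(x, p, probs) {
  keep <- p > 0
  x <- x[keep]
  p <- p[keep]
  ord <- order(x)
  x <- x[ord]
  cum <- cumsum(p[ord])
  cum <- cum / cum[length(cum)]
  if (length(x) == 1L) {
    return(rep(x, length(probs)))
  }
  approx(cum, x, xout = probs, rule = 2, ties = "ordered")$y
}

#' Per-sample instability metric panel against a reference profile
#'
#' The cohort workhorse: normalizes every tissue profile and its ear
#' (reference) profile, anchors displacements at the reference modal allele
#' and assembles the full per-sample statistic panel (mode, change in mode,
#' instability/expansion/contraction indices and weighted distribution
#' moments), one row per sample.
#'
#' The reported indices are normalized to the reference profile: each
#' displacement component (instability, expansion, contraction) is the
#' sample's component minus the reference profile's own component about its
#' mode. A profile compared with itself therefore scores exactly zero, and
#' the small intrinsic breadth of the reference trace (including any PCR
#' stutter ladder common to both traces) cancels out. As a consequence the
#' baselined expansion/contraction columns can go slightly negative when
#' the tissue trace is narrower than its reference.
#'
#' @param peaks Multi-sample peak tibble (columns `sample_id`,
#'   `repeat_count`, `height`, plus optional metadata).
#' @param reference Reference profile(s): either a single profile applied to
#'   every sample, or a multi-sample tibble matched to `peaks` by
#'   `mouse_id` (one reference sample per mouse, e.g. the P12 ear biopsy).
#' @param rel_threshold Relative peak-height threshold (see
#'   [normalize_profile()]).
#' @param ref_mode_source `"reference"` (default) anchors the indices at the
#'   reference profile's mode; `"self"` anchors each sample at its own mode.
#'   The change in mode (`delta_mode`) is always computed against the
#'   reference mode.
#' @return A tibble with one row per sample: metadata, `mode`, `ref_mode`,
#'   `delta_mode`, the three indices, the weighted summary statistics, and
#'   provenance columns (`rel_threshold`, `ref_sample_id`,
#'   `ref_mode_source`).
#' @export
instability_metrics <- function(peaks, reference, rel_threshold = 0.1,
                                ref_mode_source = c("reference", "self")) {
  ref_mode_source <- match.arg(ref_mode_source)
  check_columns(peaks, c("sample_id", "repeat_count", "height"), "peaks")
  check_columns(reference, c("repeat_count", "height"), "reference")
  if (!"sample_id" %in% names(reference)) {
    reference <- dplyr::mutate(reference, sample_id = "reference")
  }
  norm <- normalize_profile(peaks, rel_threshold)
  ref_norm <- normalize_profile(reference, rel_threshold)

  ref_modes <- ref_norm |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      ref_mode = modal_repeat(dplyr::pick(dplyr::everything())),
      # The reference trace's own displacement about its mode: the baseline
      # subtracted from every sample's components.
      baseline = list(instability_indices(dplyr::pick(dplyr::everything()),
        modal_repeat(dplyr::pick(dplyr::everything())))),
      .groups = "drop") |>
    dplyr::rename(ref_sample_id = "sample_id")
  multi_ref <- nrow(ref_modes) > 1L
  if (multi_ref) {
    check_columns(reference, "mouse_id", "multi-sample reference")
    check_columns(peaks, "mouse_id", "peaks (for reference matching)")
    ref_map <- reference |>
      dplyr::distinct(.data$mouse_id, ref_sample_id = .data$sample_id)
    if (anyDuplicated(ref_map$mouse_id)) {
      abort("Reference has more than one profile per mouse.",
        class = "repquant_argument_error")
    }
    missing <- setdiff(unique(peaks$mouse_id), ref_map$mouse_id)
    if (length(missing) > 0L) {
      abort(sprintf("No reference profile for mouse/mice: %s.",
        paste0("`", missing, "`", collapse = ", ")),
        class = "repquant_reference_error")
    }
  }

  meta_cols <- intersect(c("mouse_id", "tissue", "genotype", "age_months"),
    names(norm))
  norm |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("sample_id", meta_cols)))) |>
    tidyr::nest(.key = "profile") |>
    dplyr::ungroup() |>
    (\(d) if (multi_ref) {
      dplyr::left_join(d, ref_map, by = "mouse_id")
    } else {
      dplyr::mutate(d, ref_sample_id = ref_modes$ref_sample_id[1L])
    })() |>
    dplyr::left_join(ref_modes, by = "ref_sample_id") |>
    dplyr::mutate(stats = purrr::pmap(
      list(.data$profile, .data$ref_mode, .data$baseline),
      function(prof, rmode, base) {
        mode <- modal_repeat(prof)
        anchor <- if (ref_mode_source == "reference") rmode else mode
        idx <- instability_indices(prof, anchor) - base
        dplyr::bind_cols(
          tibble::tibble(mode = mode, delta_mode = mode - rmode),
          idx,
          weighted_summary_stats(prof)
        )
      })) |>
    dplyr::select(-"profile", -"baseline") |>
    tidyr::unnest("stats") |>
    dplyr::mutate(rel_threshold = rel_threshold,
      ref_mode_source = ref_mode_source) |>
    dplyr::relocate("ref_mode", .after = "mode")
}
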