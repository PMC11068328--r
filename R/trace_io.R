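#' Column dialect for fragment-analysis peak tables
#'
#' Peak tables exported from GeneMapper-style software rarely share headers.
#' A dialect maps the canonical column names used throughout repquant to the
#' headers actually present in a file. The canonical columns are `sample_id`,
#' `mouse_id`, `tissue`, `genotype`, `age_months`, `repeat` (CAG units) or
#' `size_bp` (base pairs), `height`, and optionally `replicate`.
#'
#' @param ... Named overrides, canonical name = file header, e.g.
#'   `sample_id = "Sample File Name"`, `height = "Height"`.
#' @return A named list of class `peak_dialect`.
#' @examples
#' peak_dialect(sample_id = "Sample", height = "Peak Height")
#' @export
peak_dialect <- function(...) {
  dialect <- list(
    sample_id = "sample_id", mouse_id = "mouse_id", tissue = "tissue",
    genotype = "genotype", age_months = "age_months",
    repeat_count = "repeat", size_bp = "size_bp", height = "height",
    replicate = "replicate"
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(dialect))
  if (length(unknown) > 0L) {
    abort(sprintf("Unknown dialect field(s): %s.",
      paste0("`", unknown, "`", collapse = ", ")),
      class = "repquant_argument_error")
  }
  dialect[names(overrides)] <- overrides
  structure(dialect, class = "peak_dialect")
}

#' Read a fragment-analysis peak table
#'
#' Reads a TSV/CSV peak table into a tidy tibble with one row per
#' (sample, peak). Peaks are sorted by repeat length (or fragment size)
#' within each sample; zero-height rows are retained so that downstream
#' thresholding sees the full exported profile. Metadata columns absent from
#' the file are filled with `NA`.
#'
#' @param path Path to a delimited text file with a header row.
#' @param dialect A [peak_dialect()] mapping canonical names to file headers.
#' @param delim Field delimiter; guessed from the file extension when `NULL`
#'   (`.csv` is comma, anything else tab).
#' @param quiet Suppress the record-count message.
#' @return A tibble with columns `sample_id`, `mouse_id`, `tissue`,
#'   `genotype`, `age_months`, `replicate` (if present), and `repeat_count`
#'   or `size_bp` plus `height`.
#' @export
read_peak_table <- function(path, dialect = peak_dialect(), delim = NULL,
                            quiet = FALSE) {
  if (!file.exists(path)) {
    abort(sprintf("Peak table `%s` does not exist.", path),
      class = "repquant_io_error")
  }
  delim <- delim %||%
    (if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t")
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
    progress = FALSE)
  tidy_peak_table(raw, dialect = dialect, what = sprintf("`%s`", path),
    quiet = quiet)
}

# Shared canonicalisation for files and in-memory data frames.
tidy_peak_table <- function(raw, dialect = peak_dialect(),
                            what = "peak table", quiet = FALSE) {
  stopifnot(inherits(dialect, "peak_dialect"))
  present <- purrr::keep(dialect, ~ .x %in% names(raw))
  mandatory <- c("sample_id", "height")
  missing <- setdiff(mandatory, names(present))
  if (length(missing) > 0L) {
    abort(sprintf("%s is missing mandatory column%s: %s.", what,
      if (length(missing) > 1L) "s" else "",
      paste0("`", unlist(dialect[missing]), "`", collapse = ", ")),
      class = "repquant_format_error")
  }
  if (!any(c("repeat_count", "size_bp") %in% names(present))) {
    abort(sprintf(
      "%s must contain a `%s` (repeat units) or `%s` (base pairs) column.",
      what, dialect$repeat_count, dialect$size_bp),
      class = "repquant_format_error")
  }
  out <- tibble::as_tibble(raw)[, unlist(present), drop = FALSE]
  names(out) <- names(present)
  for (meta in c("mouse_id", "tissue", "genotype")) {
    if (!meta %in% names(out)) out[[meta]] <- NA_character_
  }
  if (!"age_months" %in% names(out)) out$age_months <- NA_real_
  if ("repeat_count" %in% names(out)) {
    out$repeat_count <- as.integer(out$repeat_count)
  }
  out$height <- as.double(out$height)
  if (any(out$height < 0, na.rm = TRUE)) {
    abort(sprintf("%s contains negative peak heights.", what),
      class = "repquant_format_error")
  }
  size_col <- if ("repeat_count" %in% names(out)) "repeat_count" else "size_bp"
  dup <- out |>
    dplyr::count(.data$sample_id,
      dplyr::across(dplyr::any_of("replicate")),
      .data[[size_col]]) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup) > 0L) {
    abort(sprintf("%s has duplicate (sample, %s) rows: %s.", what, size_col,
      paste(sprintf("%s@%s", dup$sample_id, dup[[size_col]]),
        collapse = ", ")),
      class = "repquant_format_error")
  }
  front <- intersect(
    c("sample_id", "mouse_id", "tissue", "genotype", "age_months",
      "replicate", "repeat_count", "size_bp", "height"), names(out))
  out <- out[, front, drop = FALSE] |>
    dplyr::arrange(.data$sample_id, .data[[size_col]])
  if (!quiet) {
    inform(sprintf("%s: %d peak rows across %d sample(s); 0 rows dropped.",
      what, nrow(out), dplyr::n_distinct(out$sample_id)))
  }
  out
}

#' Write a peak table in the canonical dialect
#'
#' @param peaks A peak tibble as returned by [read_peak_table()].
#' @param path Output path; written as TSV with the canonical header
#'   (`repeat` for the repeat-unit column).
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(peaks, path) {
  check_columns(peaks, c("sample_id", "height"), "peak table")
  out <- peaks
  if ("repeat_count" %in% names(out)) {
    names(out)[names(out) == "repeat_count"] <- "repeat"
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Merge triplicate fragment-analysis runs
#'
#' Sizing PCRs are typically run in triplicate on the capillary instrument.
#' Replicates are merged by normalizing each replicate's heights to unit sum
#' (so an overall amplification difference between runs carries no weight)
#' and averaging the normalized heights per repeat; merged heights are
#' rescaled by the mean replicate total so the summed height keeps its
#' meaning as an effective signal amount.
#'
#' @param peaks Peak tibble containing a `replicate` column.
#' @param keep_replicates If `TRUE`, return the input unchanged (replicates
#'   analysed separately).
#' @return Peak tibble without the `replicate` column.
#' @export
merge_replicates <- function(peaks, keep_replicates = FALSE) {
  if (keep_replicates || !"replicate" %in% names(peaks)) {
    return(peaks)
  }
  check_columns(peaks, c("sample_id", "repeat_count", "height"),
    "replicate peak table")
  meta <- peaks |>
    dplyr::distinct(.data$sample_id, .data$mouse_id, .data$tissue,
      .data$genotype, .data$age_months)
  norm <- peaks |>
    dplyr::group_by(.data$sample_id, .data$replicate) |>
    dplyr::mutate(.total = sum(.data$height),
      .p = ifelse(.data$.total > 0, .data$height / .data$.total, 0)) |>
    dplyr::ungroup()
  scale <- norm |>
    dplyr::distinct(.data$sample_id, .data$replicate, .data$.total) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(.scale = mean(.data$.total), .groups = "drop")
  n_rep <- norm |>
    dplyr::distinct(.data$sample_id, .data$replicate) |>
    dplyr::count(.data$sample_id, name = ".n_rep")
  norm |>
    dplyr::group_by(.data$sample_id, .data$repeat_count) |>
    dplyr::summarise(.psum = sum(.data$.p), .groups = "drop") |>
    dplyr::left_join(n_rep, by = "sample_id") |>
    dplyr::left_join(scale, by = "sample_id") |>
    dplyr::mutate(height = .data$.psum / .data$.n_rep * .data$.scale) |>
    dplyr::select("sample_id", "repeat_count", "height") |>
    dplyr::left_join(meta, by = "sample_id") |>
    dplyr::select("sample_id", "mouse_id", "tissue", "genotype",
      "age_months", "repeat_count", "height") |>
    dplyr::arrange(.data$sample_id, .data$repeat_count)
}

#' Size calibration for capillary-electrophoresis traces
#'
#' Couples the internal size-standard ladder (migration position vs known
#' base pairs, interpolated piecewise-linearly) with the repeat lattice
#' (flanking PCR-product length plus 3 bp per CAG unit).
#'
#' @param positions Migration positions (scan units) of size-standard peaks.
#' @param bp Known fragment sizes (bp) of those peaks; must increase
#'   strictly with position.
#' @param repeat_offset_bp Length (bp) of the non-repeat, flanking part of
#'   the sizing amplicon. There is no universal default: calibrate it from a
#'   sample of known repeat length with [calibrate_offset()].
#' @param bp_per_repeat Base pairs per repeat unit (3 for a trinucleotide).
#' @return An object of class `size_calibration`.
#' @export
size_calibration <- function(positions, bp, repeat_offset_bp = NA_real_,
                             bp_per_repeat = 3) {
  if (length(positions) != length(bp) || length(bp) < 2L) {
    abort("Calibration needs >= 2 (position, bp) standard points.",
      class = "repquant_argument_error")
  }
  ord <- order(positions)
  positions <- as.double(positions[ord])
  bp <- as.double(bp[ord])
  if (any(diff(bp) <= 0) || any(diff(positions) <= 0)) {
    abort("Standard bp must increase strictly with migration position.",
      class = "repquant_argument_error")
  }
  if (!is.numeric(bp_per_repeat) || bp_per_repeat <= 0) {
    abort("`bp_per_repeat` must be > 0.", class = "repquant_argument_error")
  }
  structure(
    list(positions = positions, bp = bp,
      repeat_offset_bp = as.double(repeat_offset_bp),
      bp_per_repeat = as.double(bp_per_repeat)),
    class = "size_calibration"
  )
}

#' @export
print.size_calibration <- function(x, ...) {
  cat(sprintf(
    "<size_calibration> %d standard points, %.0f-%.0f bp; offset %s bp, %.1f bp/repeat\n",
    length(x$positions), min(x$bp), max(x$bp),
    ifelse(is.na(x$repeat_offset_bp), "uncalibrated",
      format(x$repeat_offset_bp)), x$bp_per_repeat))
  invisible(x)
}

#' Calibrate the flanking-sequence offset from a known allele
#'
#' Anchors fragment sizing to a sample whose repeat length is known (e.g.
#' the ear-biopsy modal allele): the offset is the observed fragment size
#' minus `bp_per_repeat` times the known repeat, so that mapping the
#' observed size back to repeat units recovers the known repeat exactly.
#'
#' @param known_repeat Known repeat count (>= 1).
#' @param observed_size_bp Observed fragment size (bp) of that allele.
#' @param bp_per_repeat Base pairs per repeat unit.
#' @return The flanking offset in bp.
#' @examples
#' calibrate_offset(186, 658) # 100
#' @export
calibrate_offset <- function(known_repeat, observed_size_bp,
                             bp_per_repeat = 3) {
  stopifnot(known_repeat >= 1)
  offset <- observed_size_bp - bp_per_repeat * known_repeat
  if (offset <= 0) {
    abort(sprintf(
      "Calibrated offset is non-positive (%.1f bp): size %.1f bp cannot hold %d repeats of %.1f bp.",
      offset, observed_size_bp, known_repeat, bp_per_repeat),
      class = "repquant_calibration_error")
  }
  offset
}

#' Convert fragment sizes to repeat counts (and back)
#'
#' `bp_to_repeat()` maps fragment sizes to the nearest repeat-lattice point,
#' `(size_bp - repeat_offset_bp) / bp_per_repeat`, rounding half-repeat ties
#' away from zero. `repeat_to_bp()` is the inverse lattice map.
#'
#' @param size_bp Fragment sizes in bp.
#' @param repeat_count Repeat counts.
#' @param calibration Optional [size_calibration()] supplying the offset and
#'   step; alternatively pass `repeat_offset_bp`/`bp_per_repeat` directly.
#' @param repeat_offset_bp Flanking (non-repeat) product length in bp.
#' @param bp_per_repeat Base pairs per repeat unit.
#' @return Integer repeat counts, or fragment sizes in bp.
#' @examples
#' bp_to_repeat(655.2, repeat_offset_bp = 100) # 185
#' @export
bp_to_repeat <- function(size_bp, calibration = NULL,
                         repeat_offset_bp = NULL, bp_per_repeat = NULL) {
  prm <- resolve_lattice(calibration, repeat_offset_bp, bp_per_repeat)
  reps <- round_half_away((size_bp - prm$offset) / prm$step)
  if (any(reps < 1L, na.rm = TRUE)) {
    abort(sprintf(
      "Sizes %s map to repeat counts < 1; check the calibration offset.",
      paste(format(size_bp[which(reps < 1L)]), collapse = ", ")),
      class = "repquant_calibration_error")
  }
  reps
}

#' @rdname bp_to_repeat
#' @export
repeat_to_bp <- function(repeat_count, calibration = NULL,
                         repeat_offset_bp = NULL, bp_per_repeat = NULL) {
  prm <- resolve_lattice(calibration, repeat_offset_bp, bp_per_repeat)
  prm$offset + prm$step * repeat_count
}

resolve_lattice <- function(calibration, repeat_offset_bp, bp_per_repeat) {
  if (!is.null(calibration)) {
    stopifnot(inherits(calibration, "size_calibration"))
    offset <- repeat_offset_bp %||% calibration$repeat_offset_bp
    step <- bp_per_repeat %||% calibration$bp_per_repeat
  } else {
    offset <- repeat_offset_bp
    step <- bp_per_repeat %||% 3
  }
  if (is.null(offset) || is.na(offset)) {
    abort("The flanking offset is uncalibrated; set `repeat_offset_bp` (see `calibrate_offset()`).",
      class = "repquant_calibration_error")
  }
  list(offset = as.double(offset), step = as.double(step))
}

#' Call peaks in a raw electropherogram trace
#'
#' Identifies local fluorescence maxima above a noise floor, keeps those
#' whose height is at least `min_prominence_frac` of the tallest peak, and
#' converts migration positions to bp by piecewise-linear interpolation
#' through the size-standard points. Positions outside the standard range
#' are sized by linear extrapolation and flagged.
#'
#' @param trace A data frame with columns `position` and `fluorescence`
#'   (>= 3 rows).
#' @param calibration A [size_calibration()].
#' @param noise_floor Minimum fluorescence for a peak to be considered.
#' @param min_prominence_frac Minimum peak height as a fraction of the
#'   tallest retained candidate.
#' @return A tibble with columns `size_bp`, `height`, `extrapolated`.
#' @export
call_peaks <- function(trace, calibration, noise_floor = 0,
                       min_prominence_frac = 0) {
  check_columns(trace, c("position", "fluorescence"), "trace")
  stopifnot(inherits(calibration, "size_calibration"))
  check_fraction(min_prominence_frac, "min_prominence_frac", allow_one = TRUE)
  if (nrow(trace) < 3L) {
    abort("Trace must have >= 3 points.", class = "repquant_argument_error")
  }
  trace <- dplyr::arrange(trace, .data$position)
  f <- as.double(trace$fluorescence)
  n <- length(f)
  i <- 2:(n - 1L)
  is_max <- f[i] > f[i - 1L] & f[i] >= f[i + 1L]
  idx <- i[is_max]
  idx <- idx[f[idx] > noise_floor]
  empty <- tibble::tibble(size_bp = double(), height = double(),
    extrapolated = logical())
  if (length(idx) == 0L) {
    return(empty)
  }
  idx <- idx[f[idx] >= min_prominence_frac * max(f[idx])]
  pos <- trace$position[idx]
  in_range <- pos >= min(calibration$positions) &
    pos <= max(calibration$positions)
  size_bp <- interp_extrap(calibration$positions, calibration$bp, pos)
  if (any(!in_range)) {
    warn(sprintf(
      "%d peak(s) lie outside the size-standard range; sized by extrapolation.",
      sum(!in_range)), class = "repquant_extrapolation_warning")
  }
  tibble::tibble(size_bp = size_bp, height = f[idx],
    extrapolated = !in_range) |>
    dplyr::arrange(.data$size_bp)
}

# Piecewise-linear interpolation with linear extrapolation beyond the ends.
interp_extrap <- function(x, y, xout) {
  out <- approx(x, y, xout = xout, rule = 1)$y
  lo <- xout < x[1L]
  hi <- xout > x[length(x)]
  if (any(lo)) {
    s <- (y[2L] - y[1L]) / (x[2L] - x[1L])
    out[lo] <- y[1L] + s * (xout[lo] - x[1L])
  }
  if (any(hi)) {
    k <- length(x)
    s <- (y[k] - y[k - 1L]) / (x[k] - x[k - 1L])
    out[hi] <- y[k] + s * (xout[hi] - x[k])
  }
  out
}

#' Read a plain two-column TSV trace
#'
#' @param path TSV file with columns `position` and `fluorescence`.
#' @return A tibble with those two columns.
#' @export
read_trace_tsv <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(raw, c("position", "fluorescence"), sprintf("`%s`", path))
  tibble::tibble(position = as.double(raw$position),
    fluorescence = as.double(raw$fluorescence))
}
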