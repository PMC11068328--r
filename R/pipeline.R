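#' Default pipeline configuration
#'
#' The resolved defaults for every pipeline stage, as a nested list. Each
#' `run_*()` stage embeds the resolved configuration it used in a
#' `provenance.json` file in its output directory, sufficient to re-run the
#' stage bit-identically.
#'
#' @return A nested named list.
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    simulate = list(n_mice = 8L, dosages = c(1, 0.5, 0),
      n_genes = 2000L, n_images = 3L),
    instability = list(rel_threshold = 0.1, ref_tissue = "ear",
      ref_mode_source = "reference",
      responses = c("instability_index", "expansion_index", "variance")),
    rescue = list(padj_max = 0.05, min_fold = 1.2, min_abs_beta = 0.05,
      thresholds = class_thresholds(), n_draws = 10000L),
    imaging = list(object_threshold = 190L, object_min_pixels = 80L,
      inclusion_threshold = 150L, inclusion_min_pixels = 2L,
      connectivity = 8L, polarity = "bright_positive")
  )
}

write_provenance <- function(out_dir, stage, config) {
  payload <- list(
    package = "repquant",
    version = as.character(packageVersion("repquant")),
    stage = stage,
    config = config
  )
  jsonlite::write_json(payload, file.path(out_dir, "provenance.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

ensure_dir <- function(out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  out_dir
}

#' Generate the full synthetic input set for a pipeline run
#'
#' Writes a synthetic cohort peak table (with its planted-truth table), the
#' two differential-expression contrast tables (with truth labels), and a
#' set of synthetic inclusion-staining images with a manifest — everything
#' the downstream stages consume, all deterministic given `seed`.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param n_mice,dosages,panel,base Cohort settings (see
#'   [generate_cohort()]).
#' @param n_genes DE table size (see [generate_de_tables()]).
#' @param n_images Number of synthetic staining images.
#' @return Invisibly, a named list of the files written.
#' @export
run_simulate <- function(out_dir, seed = 1L, n_mice = 8L,
                         dosages = c(1, 0.5, 0),
                         panel = default_tissue_panel(),
                         base = sim_config(), n_genes = 2000L,
                         n_images = 3L) {
  ensure_dir(out_dir)
  base$seed <- as.integer(seed)
  cohort <- generate_cohort(n_mice = n_mice, dosages = dosages,
    panel = panel, base = base)
  peaks_path <- file.path(out_dir, "cohort_peaks.tsv")
  write_peak_table(cohort$peaks, peaks_path)
  truth_path <- file.path(out_dir, "cohort_truth.json")
  jsonlite::write_json(cohort$truth, truth_path, digits = NA)

  de <- generate_de_tables(n_genes = n_genes, seed = derive_seed(seed, 11L))
  hd_path <- file.path(out_dir, "hd_contrast.tsv")
  ko_path <- file.path(out_dir, "ko_contrast.tsv")
  readr::write_tsv(de$hd, hd_path, progress = FALSE)
  readr::write_tsv(de$ko, ko_path, progress = FALSE)
  de_truth_path <- file.path(out_dir, "de_truth.json")
  jsonlite::write_json(de$truth, de_truth_path, digits = NA)

  image_paths <- character(n_images)
  image_truth <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    scene <- random_scene(seed = derive_seed(seed, 20L + i))
    rendered <- generate_inclusion_image(nuclei = scene$nuclei,
      inclusions = scene$inclusions, seed = derive_seed(seed, 40L + i))
    image_paths[i] <- file.path(out_dir, sprintf("image_%02d.png", i))
    write_gray_image(rendered$image, image_paths[i])
    image_truth[[i]] <- dplyr::mutate(rendered$truth_counts,
      path = image_paths[i], .before = 1L)
  }
  manifest_path <- file.path(out_dir, "image_manifest.tsv")
  readr::write_tsv(
    tibble::tibble(path = image_paths,
      sample_id = sprintf("img%02d", seq_len(n_images))),
    manifest_path, progress = FALSE)
  jsonlite::write_json(purrr::list_rbind(image_truth),
    file.path(out_dir, "image_truth.json"), digits = NA)

  write_provenance(out_dir, "simulate", list(seed = seed, n_mice = n_mice,
    dosages = dosages, panel = panel, base = unclass(base),
    n_genes = n_genes, n_images = n_images))
  invisible(list(peaks = peaks_path, cohort_truth = truth_path,
    hd = hd_path, ko = ko_path, de_truth = de_truth_path,
    manifest = manifest_path, images = image_paths))
}

#' Run the instability stage: metrics, PCA and ANCOVA reports
#'
#' Computes the per-sample instability metric panel against each mouse's
#' reference-tissue profile, then the cohort PCA of the summary-statistic
#' panel and per-tissue ANCOVAs with the reference (ear) value of each
#' response as the covariate. Mice without a reference profile are listed
#' and skipped; the stage fails only if no sample can be referenced. PCA is
#' skipped (with a logged reason) below 3 samples.
#'
#' @param peaks A peak tibble or path to a peak table TSV.
#' @param out_dir Output directory.
#' @param rel_threshold Relative peak-height threshold.
#' @param ref_tissue Tissue label of the reference profiles (default
#'   `"ear"`).
#' @param ref_mode_source See [instability_metrics()].
#' @param responses Metric columns to test by ANCOVA; `variance` is fitted
#'   on the log10 scale with geometric-mean least-squares means.
#' @return Invisibly, a list with the `metrics` tibble, `pca`, `ancova`
#'   results and the files written.
#' @export
run_instability <- function(peaks, out_dir, rel_threshold = 0.1,
                            ref_tissue = "ear",
                            ref_mode_source = "reference",
                            responses = c("instability_index",
                              "expansion_index", "variance")) {
  ensure_dir(out_dir)
  if (is.character(peaks) && length(peaks) == 1L) {
    peaks <- read_peak_table(peaks, quiet = TRUE)
  }
  check_columns(peaks, c("sample_id", "mouse_id", "tissue", "repeat_count",
    "height"), "peaks")
  refs <- dplyr::filter(peaks, .data$tissue == ref_tissue)
  tissues <- dplyr::filter(peaks, .data$tissue != ref_tissue)
  ref_mice <- unique(refs$mouse_id)
  orphans <- setdiff(unique(tissues$mouse_id), ref_mice)
  if (length(orphans) > 0L) {
    inform(sprintf("Skipping %d mouse/mice without a `%s` reference: %s.",
      length(orphans), ref_tissue, paste(orphans, collapse = ", ")))
    tissues <- dplyr::filter(tissues, !.data$mouse_id %in% orphans)
  }
  if (nrow(tissues) == 0L) {
    abort("No sample has a reference profile; nothing to analyse.",
      class = "repquant_reference_error")
  }
  metrics <- instability_metrics(tissues, refs,
    rel_threshold = rel_threshold, ref_mode_source = ref_mode_source)
  # Reference-tissue metrics, self-anchored, used as ANCOVA covariates and
  # included in the PCA (the cohort analysis uses ear and tissue panels).
  ref_metrics <- instability_metrics(refs, refs,
    rel_threshold = rel_threshold, ref_mode_source = "self")
  all_metrics <- dplyr::bind_rows(metrics, ref_metrics)
  metrics_path <- file.path(out_dir, "metrics.tsv")
  readr::write_tsv(all_metrics, metrics_path, progress = FALSE)

  files <- list(metrics = metrics_path)
  pca <- NULL
  if (nrow(all_metrics) >= 3L) {
    pca <- pca_summary_stats(all_metrics)
    for (m in c("scores", "loadings", "eigenvalues")) {
      files[[paste0("pca_", m)]] <- file.path(out_dir,
        sprintf("pca_%s.tsv", m))
      readr::write_tsv(tidy(pca, matrix = m), files[[paste0("pca_", m)]],
        progress = FALSE)
    }
  } else {
    inform(sprintf("PCA skipped: %d sample(s) < 3.", nrow(all_metrics)))
  }

  covariates <- ref_metrics |>
    dplyr::select("mouse_id", dplyr::all_of(responses)) |>
    dplyr::rename_with(~ paste0("ear_", .x), dplyr::all_of(responses))
  ancova_data <- dplyr::left_join(metrics, covariates, by = "mouse_id")
  fits <- list()
  for (tis in unique(ancova_data$tissue)) {
    sub <- dplyr::filter(ancova_data, .data$tissue == tis)
    for (resp in responses) {
      fit <- tryCatch(
        ancova_least_squares(sub, response = resp, genotype = "genotype",
          covariate = paste0("ear_", resp),
          log_transform = identical(resp, "variance")),
        error = function(e) {
          inform(sprintf("ANCOVA skipped for %s/%s: %s", tis, resp,
            conditionMessage(e)))
          NULL
        })
      if (!is.null(fit)) fits[[paste(tis, resp, sep = ".")]] <- fit
    }
  }
  if (length(fits) > 0L) {
    tests <- purrr::imap_dfr(fits, function(f, key) {
      dplyr::mutate(glance(f), tissue = sub("\\..*$", "", key),
        .before = 1L)
    })
    lsm <- purrr::imap_dfr(fits, function(f, key) {
      dplyr::mutate(ls_means(f), tissue = sub("\\..*$", "", key),
        response = f$response, .before = 1L)
    })
    files$ancova_tests <- file.path(out_dir, "ancova_tests.tsv")
    files$ancova_lsmeans <- file.path(out_dir, "ancova_lsmeans.tsv")
    readr::write_tsv(tests, files$ancova_tests, progress = FALSE)
    readr::write_tsv(lsm, files$ancova_lsmeans, progress = FALSE)
  }
  write_provenance(out_dir, "instability", list(
    rel_threshold = rel_threshold, ref_tissue = ref_tissue,
    ref_mode_source = ref_mode_source, responses = responses))
  invisible(list(metrics = all_metrics, pca = pca, ancova = fits,
    files = files))
}

#' Run the transcriptional-rescue stage
#'
#' @param hd_table,ko_table Contrast tibbles or paths to contrast TSVs
#'   (columns `gene_id`, `log2fc`, `se`, `padj`). The two tables must share
#'   at least half their gene ids, otherwise a probable id-scheme mismatch
#'   is raised as an error.
#' @param out_dir Output directory.
#' @param signature Optional reference signature: a character vector of
#'   gene ids or a path to a one-id-per-line file; adds a signature-overlap
#'   block to the summary.
#' @param seed,padj_max,min_fold,min_abs_beta,thresholds,n_draws See
#'   [rescue_analysis()].
#' @return Invisibly, the `rescue_analysis` object plus files written.
#' @export
run_rescue <- function(hd_table, ko_table, out_dir, signature = NULL,
                       seed = 1L, padj_max = 0.05, min_fold = 1.2,
                       min_abs_beta = 0.05,
                       thresholds = class_thresholds(),
                       n_draws = 10000L) {
  ensure_dir(out_dir)
  read_contrast <- function(x) {
    if (is.character(x) && length(x) == 1L) {
      readr::read_tsv(x, show_col_types = FALSE, progress = FALSE)
    } else {
      x
    }
  }
  hd_table <- read_contrast(hd_table)
  ko_table <- read_contrast(ko_table)
  overlap <- length(intersect(hd_table$gene_id, ko_table$gene_id)) /
    max(1L, length(unique(hd_table$gene_id)))
  if (overlap < 0.5) {
    abort(sprintf(
      "Only %.0f%% of disease-contrast gene ids appear in the rescue contrast; probable id-scheme mismatch.",
      100 * overlap), class = "repquant_id_mismatch_error")
  }
  res <- rescue_analysis(hd_table, ko_table, padj_max = padj_max,
    min_fold = min_fold, min_abs_beta = min_abs_beta,
    thresholds = thresholds, n_draws = n_draws, seed = seed)
  records_path <- file.path(out_dir, "rescue_records.tsv")
  readr::write_tsv(res$records, records_path, progress = FALSE)
  summary <- c(
    list(summary = res$summary, params = res$params,
      n_signature = res$n_signature)
  )
  if (!is.null(signature)) {
    if (is.character(signature) && length(signature) == 1L &&
        file.exists(signature)) {
      signature <- readr::read_lines(signature, progress = FALSE)
      signature <- signature[nzchar(signature)]
    }
    summary$signature_overlap <- signature_overlap(signature, res$records,
      dysregulated_ids = res$records$gene_id)
  }
  summary_path <- file.path(out_dir, "rescue_summary.json")
  jsonlite::write_json(summary, summary_path, auto_unbox = TRUE,
    digits = NA, pretty = TRUE)
  write_provenance(out_dir, "rescue", list(seed = seed,
    padj_max = padj_max, min_fold = min_fold,
    min_abs_beta = min_abs_beta, thresholds = thresholds,
    n_draws = n_draws, signature_supplied = !is.null(signature)))
  invisible(list(analysis = res,
    files = list(records = records_path, summary = summary_path)))
}

#' Run the imaging stage over a manifest of staining images
#'
#' @param manifest A manifest tibble or path to a manifest TSV with a
#'   `path` column.
#' @param out_dir Output directory.
#' @param object_params,inclusion_params,polarity See [quantify_images()].
#' @return Invisibly, the per-image results tibble plus files written.
#' @export
run_imaging <- function(manifest, out_dir,
                        object_params = segmentation_params(190, 80),
                        inclusion_params = segmentation_params(150, 2),
                        polarity = "bright_positive") {
  ensure_dir(out_dir)
  if (is.character(manifest) && length(manifest) == 1L) {
    manifest <- readr::read_tsv(manifest, show_col_types = FALSE,
      progress = FALSE)
  }
  results <- quantify_images(manifest, object_params, inclusion_params,
    polarity)
  n_failed <- sum(!is.na(results$error))
  if (n_failed > 0L) {
    inform(sprintf("%d image(s) failed and were recorded with errors.",
      n_failed))
  }
  results_path <- file.path(out_dir, "imaging_results.tsv")
  readr::write_tsv(results, results_path, progress = FALSE)
  write_provenance(out_dir, "imaging", list(
    object_params = unclass(object_params),
    inclusion_params = unclass(inclusion_params), polarity = polarity))
  invisible(list(results = results, files = list(results = results_path)))
}
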