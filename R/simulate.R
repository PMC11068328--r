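#' Simulation configuration for synthetic repeat-instability cohorts
#'
#' Bundles every generator parameter with its default. The somatic process
#' is a minimal per-cell birth/death model: expansion events occur at
#' `expansion_rate_per_month * tissue_factor * msh3_dosage` per cell-month
#' (Msh3 dosage scales expansion linearly and only expansion), contraction
#' events at `contraction_rate_per_month * tissue_factor` (dosage
#' independent), event counts are Poisson and jump sizes geometric on
#' `{1, 2, ...}` with success probability `step_geom_prob` (1 = unit
#' jumps). The observation process adds PCR minus-ladder stutter and a
#' relative detection floor as seen in capillary traces.
#'
#' @param ... Named overrides of the defaults.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(...) {
  cfg <- list(
    inherited_repeat = 185L,
    n_cells = 5000L,
    months = 6,
    expansion_rate_per_month = 1.0,
    contraction_rate_per_month = 0.05,
    msh3_dosage = 1.0,
    tissue_factor = 1.0,
    step_geom_prob = 1.0,
    stutter_fraction = 0.15,
    plus_stutter = 0,
    detection_floor_frac = 0.01,
    height_scale = 1,
    seed = 1L
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown) > 0L) {
    abort(sprintf("Unknown sim_config field(s): %s.",
      paste0("`", unknown, "`", collapse = ", ")),
      class = "repquant_argument_error")
  }
  cfg[names(overrides)] <- overrides
  stopifnot(cfg$expansion_rate_per_month >= 0,
    cfg$contraction_rate_per_month >= 0, cfg$tissue_factor >= 0,
    cfg$msh3_dosage >= 0, cfg$months >= 0, cfg$inherited_repeat >= 1,
    cfg$step_geom_prob > 0, cfg$step_geom_prob <= 1,
    cfg$stutter_fraction >= 0, cfg$stutter_fraction < 1)
  structure(cfg, class = "sim_config")
}

# Sum of `events` iid geometric jumps on {1, 2, ...}: events plus a
# negative-binomial number of extra units (0 when jumps are unit-sized).
geom_jump_total <- function(events, prob) {
  if (prob >= 1) {
    return(events)
  }
  events + stats::rnbinom(length(events), size = pmax(events, 1e-9),
    prob = prob) * (events > 0)
}

#' Simulate per-cell somatic repeat lengths
#'
#' Every cell starts at the inherited repeat; over `months` months it
#' accumulates Poisson-distributed expansion and contraction events with
#' geometric jump sizes (see [sim_config()]). Lengths are floored at 1.
#' Deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return Integer vector of length `config$n_cells`.
#' @export
simulate_repeat_population <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 1L))
  n <- config$n_cells
  exp_rate <- config$months * config$expansion_rate_per_month *
    config$tissue_factor * config$msh3_dosage
  con_rate <- config$months * config$contraction_rate_per_month *
    config$tissue_factor
  gains <- geom_jump_total(rpois(n, exp_rate), config$step_geom_prob)
  losses <- geom_jump_total(rpois(n, con_rate), config$step_geom_prob)
  pmax(1L, as.integer(config$inherited_repeat + gains - losses))
}

#' Synthesize a fragment-analysis peak table from a cell population
#'
#' Models the bulk-PCR/capillary-electrophoresis observation process: each
#' molecule of true length L spreads a geometric minus-ladder
#' (PCR stutter) with per-step fraction `s`, contributing normalized mass
#' `(1 - s) * s^k` to length `L - k` (an optional plus-ladder is available
#' behind `plus_stutter`, default 0). Expected heights are
#' `height_scale` times the summed mass, optionally Poisson-jittered, and
#' peaks below `detection_floor_frac` of the tallest peak are dropped.
#'
#' @param population Integer vector of per-cell repeat lengths.
#' @param stutter_fraction Minus-ladder decay per step, in `[0, 1)`.
#' @param detection_floor_frac Relative detection floor, in `[0, 1)`.
#' @param height_scale Expected height contributed per molecule.
#' @param plus_stutter Plus-ladder decay per step (default 0).
#' @param jitter Poisson-jitter the heights (`TRUE` for realistic traces).
#' @param seed Integer seed for the jitter.
#' @return A tibble with columns `repeat_count`, `height`.
#' @export
synthesize_peak_table <- function(population, stutter_fraction = 0.15,
                                  detection_floor_frac = 0.01,
                                  height_scale = 1, plus_stutter = 0,
                                  jitter = TRUE, seed = 1L) {
  stopifnot(length(population) > 0L)
  check_fraction(stutter_fraction, "stutter_fraction")
  check_fraction(detection_floor_frac, "detection_floor_frac")
  check_fraction(plus_stutter, "plus_stutter")
  counts <- table(population)
  lens <- as.integer(names(counts))
  counts <- as.double(counts)
  s <- stutter_fraction
  q <- plus_stutter
  # Per-molecule normalization over the whole ladder.
  norm <- 1 / (1 - s) + (if (q > 0) q / (1 - q) else 0)
  k_max <- if (s > 0) ceiling(log(1e-12) / log(s)) else 0L
  k_plus <- if (q > 0) ceiling(log(1e-12) / log(q)) else 0L
  support <- seq(max(1L, min(lens) - k_max), max(lens) + k_plus)
  expected <- rep(0, length(support))
  for (i in seq_along(lens)) {
    contrib_at <- function(offset, w) {
      idx <- match(lens[i] + offset, support)
      ok <- !is.na(idx)
      expected[idx[ok]] <<- expected[idx[ok]] + counts[i] * w[ok] / norm
    }
    contrib_at(-(0:k_max), s^(0:k_max))
    if (q > 0) contrib_at(seq_len(k_plus), q^seq_len(k_plus))
  }
  expected <- expected * height_scale
  heights <- if (jitter) {
    set.seed(derive_seed(seed, 2L))
    as.double(rpois(length(expected), expected))
  } else {
    expected
  }
  keep <- heights >= detection_floor_frac * max(heights) & heights > 0
  tibble::tibble(repeat_count = support[keep], height = heights[keep])
}

#' Default tissue panel for synthetic cohorts
#'
#' Three archetypes: a striatum-like highly unstable tissue, a heart-like
#' stable tissue (near-zero rates) and a pituitary-like tissue whose
#' contraction outweighs expansion so the mode drifts down regardless of
#' Msh3 dosage.
#'
#' @return Tibble with columns `tissue`, `tissue_factor`,
#'   `contraction_rate`.
#' @export
default_tissue_panel <- function() {
  tibble::tibble(
    tissue = c("striatum", "heart", "pituitary"),
    tissue_factor = c(1.0, 0.02, 0.4),
    contraction_rate = c(0.02, 0.02, 1.5)
  )
}

dosage_genotype <- function(dosage) {
  dplyr::case_when(
    dosage == 0 ~ "zQ175:Msh3ko",
    dosage == 0.5 ~ "zQ175:Msh3het",
    dosage == 1 ~ "zQ175",
    .default = sprintf("zQ175:dosage%.2g", dosage)
  )
}

#' Generate a synthetic cohort of peak tables with planted truth
#'
#' Simulates `n_mice` mice per Msh3 dosage level. Each mouse gets a
#' near-stable ear reference profile (both rates scaled by 0.02, sampled at
#' age 0.4 months, mimicking a P12 ear biopsy) plus one profile per panel
#' tissue at `base$months`. Per-sample random streams are derived from the
#' global seed with a counter, so adding a tissue does not perturb other
#' tissues' draws.
#'
#' @param n_mice Mice per dosage level.
#' @param dosages Msh3 dosage levels (1 = wild-type Msh3, 0.5 =
#'   heterozygous knockout, 0 = homozygous knockout).
#' @param panel Tissue panel (see [default_tissue_panel()]).
#' @param base A [sim_config()] holding the shared parameters.
#' @return A list with `peaks` (tidy peak tibble across all samples) and
#'   `truth` (one row per sample: planted rates and the noiseless
#'   population mean change).
#' @export
generate_cohort <- function(n_mice = 8L, dosages = c(1, 0.5, 0),
                            panel = default_tissue_panel(),
                            base = sim_config()) {
  stopifnot(inherits(base, "sim_config"), nrow(panel) > 0L)
  check_columns(panel, c("tissue", "tissue_factor", "contraction_rate"),
    "tissue panel")
  ear_scale <- 0.02
  grid <- tidyr::expand_grid(
    dosage = dosages,
    mouse = seq_len(n_mice),
    tibble::tibble(
      tissue = c("ear", panel$tissue),
      tissue_factor = c(1, panel$tissue_factor),
      contraction_rate = c(base$contraction_rate_per_month,
        panel$contraction_rate),
      is_ear = c(TRUE, rep(FALSE, nrow(panel)))
    )
  ) |>
    dplyr::mutate(stream = dplyr::row_number())
  res <- purrr::pmap(grid, function(dosage, mouse, tissue, tissue_factor,
                                    contraction_rate, is_ear, stream) {
    genotype <- dosage_genotype(dosage)
    mouse_id <- sprintf("%s_m%02d", genotype, mouse)
    cfg <- sim_config(
      inherited_repeat = base$inherited_repeat,
      n_cells = base$n_cells,
      months = base$months,
      expansion_rate_per_month = base$expansion_rate_per_month *
        (if (is_ear) ear_scale else 1),
      contraction_rate_per_month = contraction_rate *
        (if (is_ear) ear_scale else 1),
      msh3_dosage = dosage,
      tissue_factor = tissue_factor,
      step_geom_prob = base$step_geom_prob,
      seed = derive_seed(base$seed, stream)
    )
    pop <- simulate_repeat_population(cfg)
    peaks <- synthesize_peak_table(pop,
      stutter_fraction = base$stutter_fraction,
      detection_floor_frac = base$detection_floor_frac,
      height_scale = base$height_scale,
      plus_stutter = base$plus_stutter,
      seed = derive_seed(base$seed, stream + 100000L)) |>
      dplyr::mutate(
        sample_id = sprintf("%s_%s", mouse_id, tissue),
        mouse_id = mouse_id, tissue = tissue, genotype = genotype,
        age_months = if (is_ear) 0.4 else base$months,
        .before = 1L)
    truth <- tibble::tibble(
      sample_id = peaks$sample_id[1L], mouse_id = mouse_id,
      tissue = tissue, genotype = genotype, msh3_dosage = dosage,
      tissue_factor = tissue_factor,
      expansion_rate = cfg$expansion_rate_per_month,
      contraction_rate = cfg$contraction_rate_per_month,
      months = cfg$months,
      pop_mean_change = mean(pop) - base$inherited_repeat,
      pop_mode = as.integer(names(which.max(table(pop))))
    )
    list(peaks = peaks, truth = truth)
  })
  list(
    peaks = purrr::map_dfr(res, "peaks"),
    truth = purrr::map_dfr(res, "truth")
  )
}

#' Generate differential-expression contrast tables with planted alpha
#'
#' Plants a known reversal class per gene: signature genes draw a disease
#' effect `|beta_hd|` uniform on `beta_range` (random sign) and a true
#' alpha uniform within their class interval; null genes have no disease
#' effect. Observed log2 fold changes are the truth plus Gaussian noise
#' with standard deviation `noise_se`; adjusted p-values are small for
#' signature genes and uniform for nulls.
#'
#' @param n_genes Number of genes.
#' @param class_mix Named proportions over `super_reversal`,
#'   `full_reversal`, `partial_reversal`, `negligible`, `exacerbation`,
#'   `null`; must sum to 1.
#' @param beta_range Range of `|beta_hd|` for signature genes (log2 units).
#' @param noise_se Observation noise per contrast (log2 units).
#' @param thresholds Class cut points (see [class_thresholds()]).
#' @param seed Integer seed.
#' @return A list with `hd` and `ko` contrast tibbles (`gene_id`, `log2fc`,
#'   `se`, `padj`) and `truth` (`gene_id`, `class`, `true_beta_hd`,
#'   `true_alpha`).
#' @export
generate_de_tables <- function(n_genes = 2000L,
                               class_mix = c(super_reversal = 0.008,
                                 full_reversal = 0.012,
                                 partial_reversal = 0.02,
                                 negligible = 0.45,
                                 exacerbation = 0.01, null = 0.5),
                               beta_range = c(0.3, 2), noise_se = 0.05,
                               thresholds = class_thresholds(), seed = 1L) {
  expected <- c(rescue_classes(), "null")
  if (!setequal(names(class_mix), expected) ||
      abs(sum(class_mix) - 1) > 1e-9) {
    abort("`class_mix` must be named proportions over the 5 classes + `null`, summing to 1.",
      class = "repquant_argument_error")
  }
  thresholds <- class_thresholds(thresholds)
  set.seed(derive_seed(seed, 3L))
  class <- sample(expected, n_genes, replace = TRUE,
    prob = class_mix[expected])
  intervals <- rbind(
    super_reversal = c(thresholds[1L] - 0.7, thresholds[1L]),
    full_reversal = c(thresholds[1L], thresholds[2L]),
    partial_reversal = c(thresholds[2L], thresholds[3L]),
    negligible = c(thresholds[3L], thresholds[4L]),
    exacerbation = c(thresholds[4L], thresholds[4L] + 1.7)
  )
  is_sig <- class != "null"
  true_beta <- ifelse(is_sig,
    sample(c(-1, 1), n_genes, replace = TRUE) *
      runif(n_genes, beta_range[1L], beta_range[2L]), 0)
  true_alpha <- rep(NA_real_, n_genes)
  true_alpha[is_sig] <- runif(sum(is_sig),
    intervals[class[is_sig], 1L], intervals[class[is_sig], 2L])
  true_ko <- ifelse(is_sig, true_alpha * true_beta, 0)
  gene_id <- sprintf("gene%05d", seq_len(n_genes))
  noise_floor <- max(noise_se, 1e-9)
  hd <- tibble::tibble(
    gene_id = gene_id,
    log2fc = true_beta + rnorm(n_genes, sd = noise_floor),
    se = noise_floor,
    padj = ifelse(is_sig, 10^-runif(n_genes, 2, 10), runif(n_genes))
  )
  ko <- tibble::tibble(
    gene_id = gene_id,
    log2fc = true_ko + rnorm(n_genes, sd = noise_floor),
    se = noise_floor,
    padj = ifelse(abs(true_ko) > 0.1, 10^-runif(n_genes, 2, 10),
      runif(n_genes))
  )
  list(hd = hd, ko = ko,
    truth = tibble::tibble(gene_id = gene_id, class = class,
      true_beta_hd = true_beta, true_alpha = true_alpha))
}

#' Render a planted inclusion-staining scene
#'
#' Draws diffuse nucleus-sized disks and small bright inclusion disks over
#' a noisy background, clipped to 0-255 with bright-positive polarity.
#' Disks must not overlap (pairwise centre distance greater than the sum of
#' radii plus one pixel) so the planted counts are exact ground truth.
#'
#' @param width,height Image dimensions in pixels.
#' @param nuclei Tibble with columns `row`, `col`, `radius`, `intensity`.
#' @param inclusions Same columns; radius >= 1 so each inclusion covers at
#'   least the 2-pixel gate.
#' @param background_mean,background_sd Gaussian background parameters.
#' @param seed Integer seed for the background noise.
#' @return A list: `image` (integer matrix), `truth` (tibble of planted
#'   disks with rendered pixel areas and a `kind` column) and
#'   `truth_counts` (expected object/inclusion counts under the standard
#'   190/80 and 150/2 parameter pairs).
#' @export
generate_inclusion_image <- function(width = 256L, height = 256L,
                                     nuclei = NULL, inclusions = NULL,
                                     background_mean = 30,
                                     background_sd = 8, seed = 1L) {
  nuclei <- nuclei %||%
    tibble::tibble(row = numeric(), col = numeric(), radius = numeric(),
      intensity = numeric())
  inclusions <- inclusions %||%
    tibble::tibble(row = numeric(), col = numeric(), radius = numeric(),
      intensity = numeric())
  check_columns(nuclei, c("row", "col", "radius", "intensity"), "nuclei")
  check_columns(inclusions, c("row", "col", "radius", "intensity"),
    "inclusions")
  disks <- dplyr::bind_rows(
    dplyr::mutate(nuclei, kind = "nucleus"),
    dplyr::mutate(inclusions, kind = "inclusion")
  )
  if (nrow(disks) > 1L) {
    d <- as.matrix(stats::dist(disks[, c("row", "col")]))
    rsum <- outer(disks$radius, disks$radius, `+`) + 1
    diag(d) <- Inf
    if (any(d <= rsum)) {
      abort("Planted disks overlap; the scene invariant requires disjoint objects.",
        class = "repquant_scene_error")
    }
  }
  set.seed(derive_seed(seed, 4L))
  img <- matrix(rnorm(width * height, background_mean, background_sd),
    nrow = height, ncol = width)
  areas <- integer(nrow(disks))
  if (nrow(disks) > 0L) {
    rows <- row(img)
    cols <- col(img)
    for (i in seq_len(nrow(disks))) {
      in_disk <- (rows - disks$row[i])^2 + (cols - disks$col[i])^2 <=
        disks$radius[i]^2
      img[in_disk] <- disks$intensity[i]
      areas[i] <- sum(in_disk)
    }
  }
  img <- matrix(as.integer(pmin(255, pmax(0, round(img)))), height, width)
  truth <- dplyr::mutate(disks, area = areas)
  list(
    image = img,
    truth = truth,
    truth_counts = tibble::tibble(
      n_objects = sum(truth$intensity > 190 & truth$area >= 80),
      n_inclusions = sum(truth$intensity > 150 & truth$area >= 2)
    )
  )
}

#' Random non-overlapping scene for synthetic staining images
#'
#' Places nuclei and inclusions by seeded rejection sampling with disjoint
#' margins, for use with [generate_inclusion_image()].
#'
#' @param n_nuclei,n_inclusions Number of disks of each kind.
#' @param width,height Image dimensions.
#' @param nucleus_radius,nucleus_intensity,inclusion_radius,inclusion_intensity
#'   Disk geometry and brightness.
#' @param seed Integer seed.
#' @return A list with `nuclei` and `inclusions` tibbles.
#' @export
random_scene <- function(n_nuclei = 8L, n_inclusions = 12L, width = 256L,
                         height = 256L, nucleus_radius = 6,
                         nucleus_intensity = 205, inclusion_radius = 1,
                         inclusion_intensity = 220, seed = 1L) {
  set.seed(derive_seed(seed, 5L))
  radii <- c(rep(nucleus_radius, n_nuclei),
    rep(inclusion_radius, n_inclusions))
  placed <- tibble::tibble(row = numeric(), col = numeric(),
    radius = numeric())
  for (r in radii) {
    for (attempt in 1:1000) {
      cand_row <- runif(1, r + 2, height - r - 1)
      cand_col <- runif(1, r + 2, width - r - 1)
      if (nrow(placed) == 0L ||
          all(sqrt((placed$row - cand_row)^2 + (placed$col - cand_col)^2) >
            placed$radius + r + 2)) {
        placed <- dplyr::add_row(placed, row = round(cand_row),
          col = round(cand_col), radius = r)
        break
      }
      if (attempt == 1000L) {
        abort("Could not place all disks without overlap; reduce counts.",
          class = "repquant_scene_error")
      }
    }
  }
  list(
    nuclei = placed[seq_len(n_nuclei), ] |>
      dplyr::mutate(intensity = nucleus_intensity),
    inclusions = placed[n_nuclei + seq_len(n_inclusions), ] |>
      dplyr::mutate(intensity = inclusion_intensity)
  )
}
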