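test_that("zero rates leave every cell at the inherited repeat", {
  pop <- simulate_repeat_population(sim_config(
    expansion_rate_per_month = 0, contraction_rate_per_month = 0,
    n_cells = 500L, seed = 2))
  expect_true(all(pop == 185L))
})

test_that("mean repeat gain matches the Poisson expectation", {
  # Expansion only: E[gain] = months * rate * factor * dosage = 0.6.
  cfg <- sim_config(n_cells = 10000L, months = 6,
    expansion_rate_per_month = 0.1, contraction_rate_per_month = 0,
    msh3_dosage = 1, tissue_factor = 1, seed = 14)
  pop <- simulate_repeat_population(cfg)
  gain <- mean(pop) - 185
  se <- sqrt(0.6 / 10000) # Poisson variance = mean, unit jumps
  expect_lt(abs(gain - 0.6), 3 * se)

  # Dosage 0: contraction-only drift, E[change] = -0.3.
  cfg0 <- sim_config(n_cells = 10000L, months = 6,
    expansion_rate_per_month = 0.1, contraction_rate_per_month = 0.05,
    msh3_dosage = 0, seed = 15)
  pop0 <- simulate_repeat_population(cfg0)
  drift <- mean(pop0) - 185
  expect_lt(abs(drift + 0.3), 3 * sqrt(0.3 / 10000))
  expect_lte(max(pop0), 185L) # no expansion at all without Msh3
})

test_that("dosage scales the expansion rate linearly", {
  gains <- purrr::map_dbl(c(1, 0.5), function(d) {
    pop <- simulate_repeat_population(sim_config(n_cells = 20000L,
      msh3_dosage = d, contraction_rate_per_month = 0, seed = 16))
    mean(pop) - 185
  })
  expect_equal(gains[2] / gains[1], 0.5, tolerance = 0.05)
})

test_that("geometric jump sizes raise the mean gain by 1/p", {
  pop <- simulate_repeat_population(sim_config(n_cells = 20000L,
    months = 4, expansion_rate_per_month = 0.5,
    contraction_rate_per_month = 0, step_geom_prob = 0.5, seed = 17))
  # E[gain] = lambda / p = 2 / 0.5 = 4.
  expect_equal(mean(pop) - 185, 4, tolerance = 0.15)
})

test_that("stutter spreads a geometric minus-ladder and keeps the mode", {
  mono <- rep(185L, 1000L)
  clean <- synthesize_peak_table(mono, stutter_fraction = 0,
    detection_floor_frac = 0, jitter = FALSE)
  expect_equal(clean$repeat_count, 185L)

  ladder <- synthesize_peak_table(mono, stutter_fraction = 0.2,
    detection_floor_frac = 0, jitter = FALSE)
  top3 <- ladder[ladder$repeat_count %in% 183:185, ]
  expect_equal(top3$height[top3$repeat_count == 184] /
    top3$height[top3$repeat_count == 185], 0.2, tolerance = 1e-9)
  expect_equal(top3$height[top3$repeat_count == 183] /
    top3$height[top3$repeat_count == 185], 0.04, tolerance = 1e-9)

  # Mode preservation whenever stutter < 0.5 and floor < stutter^2,
  # checked by brute force over a parameter grid and random populations.
  for (seed in 1:10) {
    set.seed(seed)
    pop <- sample(180:190, 400L, replace = TRUE,
      prob = c(1, 1, 2, 4, 10, 30, 10, 4, 2, 1, 1))
    pop_mode <- as.integer(names(which.max(table(pop))))
    for (s in c(0.1, 0.25, 0.4)) {
      peaks <- synthesize_peak_table(pop, stutter_fraction = s,
        detection_floor_frac = s^2 * 0.9, jitter = FALSE)
      expect_equal(modal_repeat(peaks), pop_mode)
    }
  }
})

test_that("generators are byte-deterministic given the seed", {
  cfg <- sim_config(n_cells = 500L, seed = 18)
  expect_identical(simulate_repeat_population(cfg),
    simulate_repeat_population(cfg))
  pop <- simulate_repeat_population(cfg)
  expect_identical(synthesize_peak_table(pop, seed = 18),
    synthesize_peak_table(pop, seed = 18))
  small <- generate_cohort(n_mice = 2L, dosages = c(1, 0),
    base = sim_config(n_cells = 300L, seed = 19))
  small2 <- generate_cohort(n_mice = 2L, dosages = c(1, 0),
    base = sim_config(n_cells = 300L, seed = 19))
  expect_identical(small, small2)
  de1 <- generate_de_tables(n_genes = 200L, seed = 20)
  de2 <- generate_de_tables(n_genes = 200L, seed = 20)
  expect_identical(de1, de2)
})

test_that("cohorts have the right shape and planted dosage ordering", {
  cohort <- generate_cohort(n_mice = 4L, dosages = c(1, 0.5, 0),
    base = sim_config(n_cells = 2000L, seed = 22))
  # 4 mice x 3 dosages x (3 tissues + ear).
  expect_equal(dplyr::n_distinct(cohort$peaks$sample_id), 4L * 3L * 4L)
  expect_equal(nrow(cohort$truth), 48L)
  expect_equal(sort(unique(cohort$peaks$tissue)),
    sort(c("ear", "striatum", "heart", "pituitary")))

  refs <- dplyr::filter(cohort$peaks, tissue == "ear")
  tissues <- dplyr::filter(cohort$peaks, tissue != "ear")
  metrics <- instability_metrics(tissues, refs) |>
    dplyr::left_join(
      dplyr::distinct(cohort$truth, sample_id, msh3_dosage),
      by = "sample_id")

  # Striatum-like: mean instability strictly ordered by dosage.
  stri <- metrics |>
    dplyr::filter(tissue == "striatum") |>
    dplyr::group_by(msh3_dosage) |>
    dplyr::summarise(ii = mean(instability_index), .groups = "drop") |>
    dplyr::arrange(msh3_dosage)
  expect_true(all(diff(stri$ii) > 0))

  # Heart-like: planted null, instability within noise of zero.
  heart <- dplyr::filter(metrics, tissue == "heart")
  expect_lt(max(abs(heart$instability_index)), 0.5)

  # Pituitary-like: the mode drifts down at every dosage.
  pit <- dplyr::filter(metrics, tissue == "pituitary")
  expect_lt(mean(pit$delta_mode), 0)
  expect_lt(mean(pit$instability_index), 0)
})

test_that("DE tables plant class proportions and a consistent null", {
  de <- generate_de_tables(n_genes = 3000L, seed = 23)
  expect_equal(nrow(de$hd), 3000L)
  expect_setequal(unique(de$truth$class),
    c(rescue_classes(), "null"))
  # Planted alpha lies in its class interval.
  sig <- dplyr::filter(de$truth, class != "null")
  expect_equal(as.character(classify_alpha(sig$true_alpha)), sig$class)
  expect_true(all(abs(sig$true_beta_hd) >= 0.3))

  # All-null tables: the signature filter retains at most a trace of genes
  # (padj < 0.05 is ~5%, and the 20% fold criterion removes nearly all).
  nulls <- generate_de_tables(n_genes = 2000L,
    class_mix = c(super_reversal = 0, full_reversal = 0,
      partial_reversal = 0, negligible = 0, exacerbation = 0, null = 1),
    seed = 24)
  kept <- filter_signature(nulls$hd)
  expect_lt(nrow(kept) / 2000, 0.01)
})

test_that("planted staining scenes are recovered exactly at zero noise", {
  empty <- generate_inclusion_image(64L, 64L, background_mean = 0,
    background_sd = 0, seed = 25)
  expect_true(all(empty$image == 0L))

  scene <- random_scene(n_nuclei = 2L, n_inclusions = 5L, width = 128L,
    height = 128L, nucleus_radius = 6, inclusion_radius = 1, seed = 26)
  out <- generate_inclusion_image(128L, 128L, scene$nuclei,
    scene$inclusions, background_sd = 0, seed = 26)
  both <- quantify_dual(out$image)
  # 5 planted inclusions, plus the 2 nuclei also exceed the 150/2 gate.
  expect_equal(both$inclusions$n_objects, 7L)
  expect_equal(both$inclusions$n_objects, out$truth_counts$n_inclusions)
  # Nucleus disks of radius 6 cover 113 px >= 80: counted as objects.
  expect_equal(both$objects$n_objects, 2L)
  expect_equal(both$objects$n_objects, out$truth_counts$n_objects)
  expect_equal(sort(unique(dplyr::filter(out$truth,
    kind == "nucleus")$area)), 113L)

  # Overlapping planted disks violate the scene invariant.
  expect_error(generate_inclusion_image(64L, 64L,
    nuclei = tibble::tibble(row = 30, col = 30, radius = 6,
      intensity = 200),
    inclusions = tibble::tibble(row = 32, col = 32, radius = 1,
      intensity = 220)),
    class = "repquant_scene_error")
})

test_that("stutter biases the measured instability downward, monotonically", {
  cfg <- sim_config(n_cells = 8000L, seed = 27)
  pop <- simulate_repeat_population(cfg)
  ear <- tibble::tibble(sample_id = "ear", repeat_count = 185L,
    height = 1000)
  measured <- purrr::map_dbl(c(0, 0.1, 0.2, 0.3), function(s) {
    peaks <- synthesize_peak_table(pop, stutter_fraction = s,
      detection_floor_frac = 0.01, jitter = FALSE, seed = 27) |>
      dplyr::mutate(sample_id = "tissue")
    instability_metrics(peaks, ear)$instability_index
  })
  truth <- mean(pop) - 185
  expect_lt(measured[4], measured[1])
  expect_true(all(diff(measured) < 0.05))
  expect_lt(measured[4], truth)
})
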