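worked_profile <- tibble::tibble(
  repeat_count = c(180L, 185L, 186L, 187L),
  height = c(50, 1000, 400, 100)
)

test_that("normalization thresholds, renormalizes and flags degeneracy", {
  norm <- normalize_profile(worked_profile, rel_threshold = 0.1)
  expect_equal(norm$repeat_count, c(185L, 186L, 187L))
  expect_equal(norm$prob, c(1000, 400, 100) / 1500, tolerance = 1e-12)
  expect_equal(sum(norm$height), 1500)
  # Threshold 0 retains every nonzero peak with height-proportional probs.
  all_kept <- normalize_profile(worked_profile, rel_threshold = 0)
  expect_equal(all_kept$prob, c(50, 1000, 400, 100) / 1550)
  # Single peak concentrates all mass.
  single <- normalize_profile(
    tibble::tibble(repeat_count = 142L, height = 7), 0.5)
  expect_equal(single$prob, 1)
  expect_error(
    normalize_profile(tibble::tibble(repeat_count = 185L, height = 0)),
    class = "repquant_degenerate_error")
})

test_that("threshold monotonicity: raising rel_threshold never raises n", {
  for (seed in 1:25) {
    prof <- random_profile(seed)
    n_tot <- vapply(c(0, 0.05, 0.1, 0.3, 0.6, 0.9),
      function(th) sum(normalize_profile(prof, th)$height), double(1L))
    expect_true(all(diff(n_tot) <= 0))
  }
})

test_that("modal repeat takes the tallest peak, ties to the smallest", {
  expect_equal(modal_repeat(normalize_profile(worked_profile, 0.1)), 185L)
  tie <- tibble::tibble(repeat_count = c(185L, 190L), height = c(5, 5))
  expect_equal(modal_repeat(tie), 185L)
  expect_equal(modal_repeat(
    tibble::tibble(repeat_count = 142L, height = 3)), 142L)
})

test_that("displacement indices match hand-derived arithmetic", {
  norm <- normalize_profile(worked_profile, 0.1)
  expect_equal(instability_indices(norm, 185),
    tibble::tibble(instability_index = 0.4, expansion_index = 0.4,
      contraction_index = 0), tolerance = 1e-9)
  ref186 <- instability_indices(norm, 186)
  expect_equal(ref186$instability_index, -0.6, tolerance = 1e-9)
  expect_equal(ref186$expansion_index, 1 / 15, tolerance = 1e-9)
  expect_equal(ref186$contraction_index, 10 / 15, tolerance = 1e-9)
  # A profile sitting at the reference mode has no displacement.
  at_ref <- tibble::tibble(repeat_count = 186L, height = 10)
  expect_equal(unlist(instability_indices(at_ref, 186)),
    c(instability_index = 0, expansion_index = 0, contraction_index = 0))
})

test_that("indices match a brute-force oracle and decompose exactly", {
  for (seed in 1:1000) {
    prof <- random_profile(seed)
    norm <- normalize_profile(prof, 0.1)
    ref_mode <- sample(150:220, 1L)
    got <- instability_indices(norm, ref_mode)
    want <- brute_indices(norm$repeat_count, norm$prob, ref_mode)
    expect_equal(got$instability_index, unname(want["instability"]),
      tolerance = 1e-12)
    expect_equal(got$expansion_index, unname(want["expansion"]),
      tolerance = 1e-12)
    expect_equal(got$contraction_index, unname(want["contraction"]),
      tolerance = 1e-12)
    expect_lt(abs(got$instability_index -
      (got$expansion_index - got$contraction_index)), 1e-12)
  }
})

test_that("weighted summary statistics match two-point arithmetic", {
  two <- tibble::tibble(repeat_count = c(100L, 102L), height = c(5, 5))
  stats <- weighted_summary_stats(two)
  expect_equal(stats$mean, 101)
  expect_equal(stats$variance, 1)
  expect_equal(stats$skewness, 0)
  expect_equal(stats$iqr, 1) # cumulative-interpolation quartiles: 101 - 100
  expect_false(stats$degenerate)
  # Single peak: zero spread, flagged degenerate, finite moments.
  one <- weighted_summary_stats(
    tibble::tibble(repeat_count = 142L, height = 9))
  expect_equal(one$variance, 0)
  expect_equal(one$iqr, 0)
  expect_equal(one$skewness, 0)
  expect_equal(one$kurtosis_excess, 0)
  expect_true(one$degenerate)
  # n carries the summed retained height.
  expect_equal(weighted_summary_stats(
    normalize_profile(worked_profile, 0.1))$n, 1500)
})

test_that("weighted moments agree with a brute-force oracle", {
  for (seed in 1:200) {
    norm <- normalize_profile(random_profile(seed), 0.1)
    got <- weighted_summary_stats(norm)
    want <- brute_moments(norm$repeat_count, norm$prob)
    expect_equal(got$mean, want$mean, tolerance = 1e-12)
    expect_equal(got$variance, want$variance, tolerance = 1e-12)
    expect_equal(got$skewness, want$skewness, tolerance = 1e-10)
    expect_equal(got$kurtosis_excess, want$kurtosis_excess,
      tolerance = 1e-10)
  }
})

test_that("self-comparison yields zero instability and zero mode change", {
  for (seed in 1:50) {
    prof <- random_profile(seed)
    m <- instability_metrics(prof, prof, rel_threshold = 0.1)
    expect_equal(m$instability_index, 0, tolerance = 1e-12)
    expect_equal(m$delta_mode, 0L)
  }
})

test_that("profiles symmetric about the reference mode give index 0 and skew 0", {
  for (seed in 1:20) {
    set.seed(seed)
    ref_mode <- sample(160:200, 1L)
    half <- sort(sample(1:10, 3L))
    h <- round(runif(3, 10, 1000))
    prof <- tibble::tibble(
      repeat_count = c(ref_mode - rev(half), ref_mode, ref_mode + half),
      height = c(rev(h), max(h) + 1, h)
    )
    norm <- normalize_profile(prof, rel_threshold = 0)
    idx <- instability_indices(norm, ref_mode)
    expect_equal(idx$instability_index, 0, tolerance = 1e-12)
    expect_equal(weighted_summary_stats(norm)$skewness, 0,
      tolerance = 1e-10)
  }
})

test_that("shift equivariance: joint shifts cancel, profile-only shifts add k", {
  for (seed in 1:20) {
    prof <- random_profile(seed)
    norm <- normalize_profile(prof, 0.1)
    ref_mode <- 180L
    k <- sample(c(-7L, -3L, 2L, 11L), 1L)
    shifted <- dplyr::mutate(prof, repeat_count = repeat_count + k)
    norm_shift <- normalize_profile(shifted, 0.1)
    base_idx <- instability_indices(norm, ref_mode)
    joint <- instability_indices(norm_shift, ref_mode + k)
    expect_equal(joint, base_idx, tolerance = 1e-10)
    base_stats <- weighted_summary_stats(norm)
    shift_stats <- weighted_summary_stats(norm_shift)
    expect_equal(shift_stats$variance, base_stats$variance,
      tolerance = 1e-10)
    expect_equal(shift_stats$skewness, base_stats$skewness,
      tolerance = 1e-10)
    expect_equal(shift_stats$iqr, base_stats$iqr, tolerance = 1e-10)
    profile_only <- instability_indices(norm_shift, ref_mode)
    expect_equal(profile_only$instability_index,
      base_idx$instability_index + k, tolerance = 1e-10)
  }
})

test_that("cohort metrics anchor displacements at the matched ear reference", {
  ref <- tibble::tibble(sample_id = "ear1", mouse_id = "m1",
    tissue = "ear", genotype = "zQ175", age_months = 0.4,
    repeat_count = 186L, height = 1000)
  tissue <- tibble::tibble(sample_id = "str1", mouse_id = "m1",
    tissue = "striatum", genotype = "zQ175", age_months = 6,
    repeat_count = 190L, height = 500)
  m <- instability_metrics(tissue, ref)
  expect_equal(m$mode, 190L)
  expect_equal(m$ref_mode, 186L)
  expect_equal(m$delta_mode, 4L)
  expect_equal(m$instability_index, 4)
  expect_equal(m$ref_sample_id, "ear1")

  # Contraction-dominant tissue (pituitary-like).
  pit <- dplyr::mutate(tissue, sample_id = "pit1", tissue = "pituitary",
    repeat_count = 183L)
  mp <- instability_metrics(pit, ref)
  expect_equal(mp$delta_mode, -3L)
  expect_equal(mp$contraction_index, 3)
  expect_equal(mp$expansion_index, 0)

  # Self-anchored option still reports delta_mode against the reference.
  ms <- instability_metrics(tissue, ref, ref_mode_source = "self")
  expect_equal(ms$instability_index, 0)
  expect_equal(ms$delta_mode, 4L)

  # Missing reference for a mouse is a reference error.
  orphan <- dplyr::mutate(tissue, mouse_id = "m2", sample_id = "str2")
  expect_error(
    instability_metrics(dplyr::bind_rows(tissue, orphan),
      dplyr::bind_rows(ref, dplyr::mutate(ref, sample_id = "ear9",
        mouse_id = "m9"))),
    class = "repquant_reference_error")
})

test_that("multi-sample metrics are invariant to row order", {
  peaks <- dplyr::bind_rows(
    dplyr::mutate(random_profile(101), mouse_id = "m1", tissue = "striatum",
      genotype = "zQ175", age_months = 6),
    dplyr::mutate(random_profile(102), mouse_id = "m2", tissue = "striatum",
      genotype = "zQ175", age_months = 6))
  refs <- dplyr::bind_rows(
    dplyr::mutate(random_profile(103), sample_id = "e1", mouse_id = "m1",
      tissue = "ear", genotype = "zQ175", age_months = 0.4),
    dplyr::mutate(random_profile(104), sample_id = "e2", mouse_id = "m2",
      tissue = "ear", genotype = "zQ175", age_months = 0.4))
  m1 <- instability_metrics(peaks, refs)
  set.seed(1)
  m2 <- instability_metrics(peaks[sample(nrow(peaks)), ],
    refs[sample(nrow(refs)), ])
  expect_equal(m1, m2[order(match(m2$sample_id, m1$sample_id)), ])
})
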