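test_that("peak tables parse, sort canonically and split by sample", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_fixture_peaks(path, tibble::tibble(
    sample_id = c("s1", "s2", "s1", "s2", "s1"),
    `repeat` = c(187, 190, 185, 189, 186),
    height = c(100, 50, 1000, 75, 400)
  ))
  peaks <- read_peak_table(path, quiet = TRUE)
  expect_equal(dplyr::n_distinct(peaks$sample_id), 2L)
  s1 <- dplyr::filter(peaks, sample_id == "s1")
  expect_equal(s1$repeat_count, c(185L, 186L, 187L))
  expect_equal(s1$height, c(1000, 400, 100))
  expect_equal(nrow(dplyr::filter(peaks, sample_id == "s2")), 2L)

  # Shuffled input yields an identical table: sorting is canonical.
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_fixture_peaks(path2, tibble::tibble(
    sample_id = c("s1", "s2", "s1", "s2", "s1")[c(3, 1, 5, 2, 4)],
    `repeat` = c(187, 190, 185, 189, 186)[c(3, 1, 5, 2, 4)],
    height = c(100, 50, 1000, 75, 400)[c(3, 1, 5, 2, 4)]
  ))
  expect_equal(read_peak_table(path2, quiet = TRUE), peaks)
})

test_that("zero-height rows are retained and dialects remap headers", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(
    Sample = "a", CAG = c(185, 186), Height = c(100, 0)), path)
  peaks <- read_peak_table(path,
    dialect = peak_dialect(sample_id = "Sample", repeat_count = "CAG",
      height = "Height"), quiet = TRUE)
  expect_equal(nrow(peaks), 2L)
  expect_equal(peaks$height, c(100, 0))
})

test_that("malformed peak tables fail with named columns", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_fixture_peaks(path,
    tibble::tibble(sample_id = "s1", `repeat` = 185))
  expect_error(read_peak_table(path, quiet = TRUE),
    class = "repquant_format_error", regexp = "height")

  dup <- withr::local_tempfile(fileext = ".tsv")
  write_fixture_peaks(dup, tibble::tibble(
    sample_id = c("s1", "s1"), `repeat` = c(185, 185),
    height = c(10, 20)))
  expect_error(read_peak_table(dup, quiet = TRUE),
    class = "repquant_format_error", regexp = "s1@185")
})

test_that("write -> read round-trips the canonical dialect bit-identically", {
  peaks <- dplyr::bind_rows(random_profile(11), random_profile(12)) |>
    dplyr::mutate(mouse_id = "m1", tissue = "striatum", genotype = "zQ175",
      age_months = 6, .after = "sample_id")
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_peak_table(peaks, p1)
  back <- read_peak_table(p1, quiet = TRUE)
  write_peak_table(back, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
    readBin(p2, "raw", file.size(p2)))
  expect_equal(back$repeat_count, peaks$repeat_count)
  expect_equal(back$height, peaks$height)
})

test_that("bp/repeat lattice maps follow the tie-away-from-zero rule", {
  expect_equal(bp_to_repeat(655.2, repeat_offset_bp = 100), 185L)
  expect_equal(bp_to_repeat(100 + 3 * 42, repeat_offset_bp = 100), 42L)
  # Half-repeat tie rounds away from zero.
  expect_equal(bp_to_repeat(101.5, repeat_offset_bp = 100), 1L)
  expect_error(bp_to_repeat(100.4, repeat_offset_bp = 100),
    class = "repquant_calibration_error")
  # Lattice identity over 1..1000 repeats.
  reps <- 1:1000
  expect_equal(
    bp_to_repeat(repeat_to_bp(reps, repeat_offset_bp = 87.5),
      repeat_offset_bp = 87.5), reps)
})

test_that("offset calibration anchors sizing to a known allele", {
  expect_equal(calibrate_offset(186, 658), 100)
  # Round-trip identity for arbitrary pairs.
  for (seed in 1:20) {
    set.seed(seed)
    known <- sample(50:400, 1L)
    obs <- 3 * known + runif(1, 50, 200)
    off <- calibrate_offset(known, obs)
    expect_equal(bp_to_repeat(obs, repeat_offset_bp = off), known)
  }
  expect_error(calibrate_offset(186, 500),
    class = "repquant_calibration_error")
})

test_that("call_peaks finds calibrated apexes and honours thresholds", {
  cal <- size_calibration(positions = c(1000, 2000, 3000),
    bp = c(400, 700, 1000))
  # Flat trace: no signal.
  flat <- tibble::tibble(position = seq(1000, 3000, 10), fluorescence = 0)
  expect_equal(nrow(call_peaks(flat, cal)), 0L)

  # Triangular apex at the position sizing to 655 bp:
  # 655 bp = 400 + 0.3 * (pos - 1000) -> pos = 1850.
  pos <- seq(1700, 2000, 10)
  tri <- tibble::tibble(position = pos,
    fluorescence = pmax(0, 1000 - 10 * abs(pos - 1850)))
  pk <- call_peaks(tri, cal)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$size_bp, 655)
  expect_equal(pk$height, 1000)
  expect_false(pk$extrapolated)

  # Prominence and noise-floor arithmetic: the 5-unit apex is kept by the
  # 1% prominence rule but removed by the floor of 10.
  two <- tibble::tibble(position = pos,
    fluorescence = pmax(0, 1000 - 10 * abs(pos - 1850)) +
      pmax(0, 5 - 5 * abs(pos - 1950) / 10))
  pk2 <- call_peaks(two, cal, noise_floor = 10, min_prominence_frac = 0.01)
  expect_equal(nrow(pk2), 1L)
  expect_equal(pk2$height, 1000)

  # Outside the standard range: extrapolated and flagged.
  out_tri <- tibble::tibble(position = seq(3000, 3200, 10),
    fluorescence = pmax(0, 500 - 10 * abs(seq(3000, 3200, 10) - 3100)))
  expect_warning(pk3 <- call_peaks(out_tri, cal),
    class = "repquant_extrapolation_warning")
  expect_true(pk3$extrapolated)
  expect_equal(pk3$size_bp, 1000 + 0.3 * 100)
})

test_that("call_peaks recovers planted peak lists on synthetic traces", {
  cal <- size_calibration(positions = c(0, 4000), bp = c(0, 400))
  set.seed(31)
  for (rep in 1:5) {
    # Planted sizes >= 4 bp apart so the 1.5 bp-wide triangles stay disjoint.
    sizes <- sort(sample(seq(50, 120, by = 4), 5L))
    heights <- runif(5, 200, 1000)
    pos <- seq(0, 4000, 5)
    f <- rep(0, length(pos))
    for (k in 1:5) {
      f <- f + pmax(0, heights[k] * (1 - abs(pos - sizes[k] * 10) / 15))
    }
    pk <- call_peaks(tibble::tibble(position = pos, fluorescence = f), cal,
      noise_floor = 50)
    expect_equal(pk$size_bp, sizes)
    expect_equal(pk$height, heights, tolerance = 1e-9)
  }
})

test_that("replicate merging averages per-replicate-normalized heights", {
  peaks <- tibble::tibble(
    sample_id = "s1", mouse_id = "m1", tissue = "ear", genotype = "zQ175",
    age_months = 0.4,
    replicate = rep(1:2, each = 2),
    repeat_count = c(185L, 186L, 185L, 186L),
    # Same shape, 2x amplification in replicate 2: merge must equal the
    # common shape scaled to the mean total.
    height = c(800, 200, 1600, 400)
  )
  merged <- merge_replicates(peaks)
  expect_equal(merged$repeat_count, c(185L, 186L))
  expect_equal(merged$height, c(0.8, 0.2) * 1500)
  expect_identical(merge_replicates(peaks, keep_replicates = TRUE), peaks)
})

test_that("ABIF containers round-trip through the reader", {
  path <- withr::local_tempfile(fileext = ".fsa")
  values <- c(0L, 5L, 80L, 900L, 120L, 7L, 0L, 0L, 300L, 2L)
  write_mini_abif(path, values)
  tags <- read_abif(path)
  expect_true("DATA.1" %in% names(tags))
  expect_equal(tags$DATA.1, values)
  trace <- fsa_trace(path)
  expect_equal(trace$fluorescence, as.double(values))
  cal <- size_calibration(positions = c(1, 10), bp = c(100, 190))
  pk <- call_peaks(trace, cal, noise_floor = 100)
  expect_equal(pk$height, c(900, 300))
  expect_error(fsa_trace(path, "DATA.2"), class = "repquant_format_error")
  # Non-ABIF input is rejected by magic.
  bad <- withr::local_tempfile(fileext = ".fsa")
  writeBin(charToRaw("NOPEnope"), bad)
  expect_error(read_abif(bad), class = "repquant_format_error")
})
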