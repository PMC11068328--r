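# Fixture builders and independent oracles shared across the suite.

# Random single-sample repeat profile with positive heights.
random_profile <- function(seed, n_min = 2L, n_max = 12L) {
  set.seed(seed)
  n <- sample(n_min:n_max, 1L)
  reps <- sort(sample(150:220, n))
  tibble::tibble(
    sample_id = sprintf("s%d", seed),
    repeat_count = reps,
    height = round(runif(n, 1, 2000))
  )
}

# Brute-force weighted-sum implementation of the displacement indices,
# written as an explicit loop so it shares nothing with the vectorized path.
brute_indices <- function(repeats, probs, ref_mode) {
  ii <- 0
  ei <- 0
  ci <- 0
  for (k in seq_along(repeats)) {
    d <- repeats[k] - ref_mode
    ii <- ii + probs[k] * d
    if (d > 0) ei <- ei + probs[k] * d
    if (d < 0) ci <- ci + probs[k] * (-d)
  }
  c(instability = ii, expansion = ei, contraction = ci)
}

# Brute-force weighted moments.
brute_moments <- function(repeats, probs) {
  mu <- sum(probs * repeats)
  m2 <- sum(probs * (repeats - mu)^2)
  m3 <- sum(probs * (repeats - mu)^3)
  m4 <- sum(probs * (repeats - mu)^4)
  list(mean = mu, variance = m2,
    skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    kurtosis_excess = if (m2 > 0) m4 / m2^2 - 3 else 0)
}

# Queue-based flood-fill labelling oracle for connected components.
flood_fill_labels <- function(mask, connectivity = 8) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  offsets <- if (connectivity == 8) {
    expand.grid(dr = -1:1, dc = -1:1)[-5, ]
  } else {
    data.frame(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))
  }
  next_label <- 0L
  for (start_r in seq_len(nr)) {
    for (start_c in seq_len(nc)) {
      if (!mask[start_r, start_c] || labels[start_r, start_c] > 0L) next
      next_label <- next_label + 1L
      queue <- list(c(start_r, start_c))
      labels[start_r, start_c] <- next_label
      while (length(queue) > 0L) {
        cur <- queue[[1L]]
        queue <- queue[-1L]
        for (k in seq_len(nrow(offsets))) {
          r <- cur[1L] + offsets$dr[k]
          c <- cur[2L] + offsets$dc[k]
          if (r >= 1L && r <= nr && c >= 1L && c <= nc &&
              mask[r, c] && labels[r, c] == 0L) {
            labels[r, c] <- next_label
            queue[[length(queue) + 1L]] <- c(r, c)
          }
        }
      }
    }
  }
  labels
}

# Minimal ABIF writer for round-trip testing of the reader: one int16
# DATA.1 channel. Layout: header, data block, then the directory.
write_mini_abif <- function(path, values) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("ABIF", con, eos = NULL)
  writeBin(101L, con, size = 2L, endian = "big") # version
  data_offset <- 128L
  dir_offset <- data_offset + 2L * length(values)
  # Header directory entry pointing at the entry table.
  writeChar("tdir", con, eos = NULL)
  writeBin(1L, con, size = 4L, endian = "big")
  writeBin(1023L, con, size = 2L, endian = "big")
  writeBin(28L, con, size = 2L, endian = "big")
  writeBin(1L, con, size = 4L, endian = "big") # numelements = 1 entry
  writeBin(28L, con, size = 4L, endian = "big")
  writeBin(dir_offset, con, size = 4L, endian = "big")
  writeBin(0L, con, size = 4L, endian = "big")
  # Pad to the data block.
  pad <- data_offset - (4L + 2L + 28L)
  writeBin(raw(pad), con)
  writeBin(as.integer(values), con, size = 2L, endian = "big")
  # Directory: one DATA.1 entry of type 4 (int16).
  writeChar("DATA", con, eos = NULL)
  writeBin(1L, con, size = 4L, endian = "big")
  writeBin(4L, con, size = 2L, endian = "big")
  writeBin(2L, con, size = 2L, endian = "big")
  writeBin(length(values), con, size = 4L, endian = "big")
  writeBin(2L * length(values), con, size = 4L, endian = "big")
  writeBin(data_offset, con, size = 4L, endian = "big")
  writeBin(0L, con, size = 4L, endian = "big")
  invisible(path)
}

# Tiny peak-table TSV on disk.
write_fixture_peaks <- function(path, df) {
  readr::write_tsv(df, path, progress = FALSE)
  path
}
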