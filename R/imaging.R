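#' Segmentation parameters: intensity threshold plus pixel-size gate
#'
#' @param intensity_threshold 8-bit intensity cutoff (0-255); pixels with
#'   values strictly above it are positive.
#' @param min_pixels Minimum connected-component area (pixels) for an
#'   object to be retained (>= 1).
#' @param connectivity Pixel adjacency: 8 (default, includes diagonal
#'   contact) or 4.
#' @return A list of class `segmentation_params`.
#' @examples
#' segmentation_params(190, 80) # S830-positive objects
#' segmentation_params(150, 2) # inclusions
#' @export
segmentation_params <- function(intensity_threshold, min_pixels,
                                connectivity = 8) {
  if (intensity_threshold < 0 || intensity_threshold > 255) {
    abort("`intensity_threshold` must lie in 0-255.",
      class = "repquant_argument_error")
  }
  if (min_pixels < 1) {
    abort("`min_pixels` must be >= 1.", class = "repquant_argument_error")
  }
  if (!connectivity %in% c(4L, 8L)) {
    abort("`connectivity` must be 4 or 8.", class = "repquant_argument_error")
  }
  structure(list(intensity_threshold = as.integer(intensity_threshold),
    min_pixels = as.integer(min_pixels),
    connectivity = as.integer(connectivity)),
    class = "segmentation_params")
}

#' Label connected components of a binary mask
#'
#' Two-pass run-merging labeller with union-find: runs of positive pixels
#' within each row are merged across adjacent rows when they overlap
#' (4-connectivity) or overlap within one column (8-connectivity). Labels
#' are positive integers in first-encounter (row-major) order; background
#' is 0.
#'
#' @param mask Logical (or 0/1) matrix.
#' @param connectivity 4 or 8.
#' @return Integer matrix of the same shape.
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask))
  mask <- mask != 0
  nr <- nrow(mask)
  nc <- ncol(mask)
  if (nr == 0L || nc == 0L || !any(mask)) {
    return(matrix(0L, nr, nc))
  }
  off <- if (connectivity == 8L) 1L else 0L
  # Collect runs per row.
  runs_by_row <- vector("list", nr)
  n_runs <- 0L
  for (r in seq_len(nr)) {
    row <- mask[r, ]
    if (!any(row)) next
    rl <- rle(row)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    pos <- which(rl$values)
    if (length(pos) == 0L) next
    ids <- n_runs + seq_along(pos)
    n_runs <- n_runs + length(pos)
    runs_by_row[[r]] <- cbind(id = ids, c1 = starts[pos], c2 = ends[pos])
  }
  parent <- seq_len(n_runs)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  prev <- NULL
  for (r in seq_len(nr)) {
    cur <- runs_by_row[[r]]
    if (!is.null(prev) && !is.null(cur)) {
      for (i in seq_len(nrow(cur))) {
        touch <- prev[, "c1"] <= cur[i, "c2"] + off &
          prev[, "c2"] >= cur[i, "c1"] - off
        for (j in which(touch)) {
          ra <- find(cur[i, "id"])
          rb <- find(prev[j, "id"])
          if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
        }
      }
    }
    prev <- cur
  }
  roots <- vapply(seq_len(n_runs), find, integer(1L))
  relabel <- integer(n_runs)
  relabel[unique(roots)] <- seq_along(unique(roots))
  labels <- matrix(0L, nr, nc)
  for (r in seq_len(nr)) {
    cur <- runs_by_row[[r]]
    if (is.null(cur)) next
    for (i in seq_len(nrow(cur))) {
      labels[r, cur[i, "c1"]:cur[i, "c2"]] <- relabel[roots[cur[i, "id"]]]
    }
  }
  labels
}

check_gray_image <- function(image) {
  if (!is.matrix(image) || length(image) == 0L) {
    abort("Image must be a non-empty 2-D matrix (single channel).",
      class = "repquant_argument_error")
  }
  if (any(image < 0 | image > 255, na.rm = TRUE)) {
    abort("Image values must lie in 0-255 (8-bit).",
      class = "repquant_argument_error")
  }
  image
}

#' Segment stained objects by intensity threshold and size gate
#'
#' Implements the intensity-threshold segmentation used for aggregate
#' immunostaining: pixels strictly above the intensity threshold form the
#' positive mask (for `dark_positive` material, e.g. DAB bright-field
#' images, intensities are inverted as `255 - v` first), connected
#' components are labelled under the requested connectivity, and components
#' smaller than the pixel gate are discarded. The percent image area is
#' computed over retained-object pixels; the raw-mask percentage is also
#' reported for comparison.
#'
#' @param image Integer matrix with values 0-255.
#' @param params A [segmentation_params()] object.
#' @param polarity `"bright_positive"` (default; stain is bright) or
#'   `"dark_positive"`.
#' @return An object of class `segmentation_result`: `objects` tibble
#'   (`label`, `area`, `centroid_row`, `centroid_col`), `n_objects`,
#'   `mean_area`, `percent_area`, `percent_area_mask`, and the parameters
#'   used.
#' @export
segment_objects <- function(image, params,
                            polarity = c("bright_positive",
                              "dark_positive")) {
  polarity <- match.arg(polarity)
  stopifnot(inherits(params, "segmentation_params"))
  check_gray_image(image)
  v <- if (polarity == "dark_positive") 255 - image else image
  mask <- v > params$intensity_threshold
  labels <- label_components(mask, params$connectivity)
  n_labels <- max(labels)
  total_px <- length(image)
  if (n_labels == 0L) {
    objects <- tibble::tibble(label = integer(), area = integer(),
      centroid_row = double(), centroid_col = double())
  } else {
    areas <- tabulate(labels[labels > 0L], nbins = n_labels)
    keep <- which(areas >= params$min_pixels)
    rows <- row(labels)[labels > 0L]
    cols <- col(labels)[labels > 0L]
    labs <- labels[labels > 0L]
    objects <- tibble::tibble(
      label = seq_along(keep),
      area = areas[keep],
      centroid_row = vapply(keep, function(k) mean(rows[labs == k]),
        double(1L)),
      centroid_col = vapply(keep, function(k) mean(cols[labs == k]),
        double(1L))
    )
  }
  n_objects <- nrow(objects)
  structure(
    list(
      objects = objects,
      n_objects = n_objects,
      mean_area = if (n_objects > 0L) mean(objects$area) else NA_real_,
      percent_area = 100 * sum(objects$area) / total_px,
      percent_area_mask = 100 * sum(mask) / total_px,
      params = params, polarity = polarity,
      dim = dim(image)
    ),
    class = "segmentation_result"
  )
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf(
    "<segmentation_result> %d object(s) (threshold > %d, gate >= %d px, %d-connected); mean area %s px, %.3f%% of image\n",
    x$n_objects, x$params$intensity_threshold, x$params$min_pixels,
    x$params$connectivity,
    ifelse(is.na(x$mean_area), "-", format(round(x$mean_area, 1))),
    x$percent_area))
  invisible(x)
}

#' @describeIn segment_objects Per-object tibble.
#' @param x A `segmentation_result`.
#' @param ... Unused.
#' @export
tidy.segmentation_result <- function(x, ...) {
  x$objects
}

#' @describeIn segment_objects One-row summary.
#' @export
glance.segmentation_result <- function(x, ...) {
  tibble::tibble(
    n_objects = x$n_objects, mean_area = x$mean_area,
    percent_area = x$percent_area, percent_area_mask = x$percent_area_mask,
    intensity_threshold = x$params$intensity_threshold,
    min_pixels = x$params$min_pixels,
    connectivity = x$params$connectivity, polarity = x$polarity
  )
}

#' Dual-threshold quantification of aggregate immunostaining
#'
#' Runs two independent segmentations of the same image with the two
#' standard parameter pairs: stained objects (signal over 190 with an
#' 80-pixel gate) and inclusions (signal over 150 with a 2-pixel gate).
#'
#' @param image Integer matrix with values 0-255.
#' @param object_params,inclusion_params [segmentation_params()] for the
#'   two passes.
#' @param polarity See [segment_objects()].
#' @return A list with elements `objects` and `inclusions`, each a
#'   `segmentation_result`.
#' @export
quantify_dual <- function(image,
                          object_params = segmentation_params(190, 80),
                          inclusion_params = segmentation_params(150, 2),
                          polarity = c("bright_positive", "dark_positive")) {
  polarity <- match.arg(polarity)
  list(
    objects = segment_objects(image, object_params, polarity),
    inclusions = segment_objects(image, inclusion_params, polarity)
  )
}

#' Read an 8-bit grayscale image (PNG or TIFF)
#'
#' @param path Path to a single-channel PNG or TIFF; multi-channel images
#'   are rejected (pre-extract the channel of interest).
#' @return Integer matrix with values 0-255.
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Image `%s` does not exist.", path),
      class = "repquant_io_error")
  }
  arr <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::readPNG(path)
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    tiff::readTIFF(path)
  } else {
    abort(sprintf("Unsupported image format: `%s` (use PNG or TIFF).", path),
      class = "repquant_format_error")
  }
  if (length(dim(arr)) == 3L) {
    if (dim(arr)[3L] > 1L) {
      abort(sprintf(
        "`%s` has %d channels; extract a single channel before quantification.",
        path, dim(arr)[3L]), class = "repquant_format_error")
    }
    arr <- arr[, , 1L]
  }
  matrix(as.integer(round(arr * 255)), nrow(arr), ncol(arr))
}

#' Write an 8-bit grayscale image
#'
#' @param image Integer matrix with values 0-255.
#' @param path Output path ending in `.png` or `.tif`/`.tiff`.
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(image, path) {
  check_gray_image(image)
  scaled <- image / 255
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(scaled, path)
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    tiff::writeTIFF(scaled, path, bits.per.sample = 8L)
  } else {
    abort(sprintf("Unsupported image format: `%s`.", path),
      class = "repquant_format_error")
  }
  invisible(path)
}

#' Batch quantification over an image manifest
#'
#' Applies [quantify_dual()] to every image listed in a manifest; a failing
#' row (missing or malformed image) is recorded with its error message and
#' the batch continues.
#'
#' @param manifest Data frame with a `path` column plus any metadata
#'   columns (carried through to the output).
#' @param object_params,inclusion_params,polarity See [quantify_dual()].
#' @return A tibble with two rows per readable image (`param_set` =
#'   `"objects"` / `"inclusions"`) holding `n_objects`, `mean_area`,
#'   `percent_area`, `percent_area_mask`, and an `error` column (`NA` on
#'   success).
#' @export
quantify_images <- function(manifest,
                            object_params = segmentation_params(190, 80),
                            inclusion_params = segmentation_params(150, 2),
                            polarity = "bright_positive") {
  check_columns(manifest, "path", "manifest")
  purrr::map_dfr(seq_len(nrow(manifest)), function(i) {
    meta <- manifest[i, , drop = FALSE]
    res <- tryCatch({
      img <- read_gray_image(meta$path)
      both <- quantify_dual(img, object_params, inclusion_params,
        polarity = polarity)
      dplyr::bind_rows(
        dplyr::mutate(glance(both$objects), param_set = "objects"),
        dplyr::mutate(glance(both$inclusions), param_set = "inclusions")
      ) |>
        dplyr::mutate(error = NA_character_)
    }, error = function(e) {
      tibble::tibble(param_set = NA_character_,
        error = conditionMessage(e))
    })
    dplyr::bind_cols(meta[rep(1L, nrow(res)), , drop = FALSE], res)
  })
}
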