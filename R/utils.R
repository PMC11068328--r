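#' Round to nearest integer, ties away from zero
#'
#' Fragment sizes land between repeat lattice points; the nearest-integer map
#' used throughout sizing rounds half-repeat ties away from zero (so 0.5 -> 1,
#' -0.5 -> -1), unlike [base::round()]'s round-half-even.
#'
#' @param x Numeric vector.
#' @return Integer vector.
#' @examples
#' round_half_away(c(184.5, 185.07, 0.5))
#' @export
round_half_away <- function(x) {
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

# Derive a per-stream seed from a global seed and a stream counter so that
# adding one stream (tissue, gene block, image) never perturbs another
# stream's draws. Kept below 2^31 - 1 for R's 32-bit integers.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(stream))
  as.integer((as.double(seed) * 48271 + as.double(stream) * 16807) %%
    2147483647)
}

# Shared argument checks ------------------------------------------------------

check_fraction <- function(x, name, allow_one = FALSE) {
  hi_ok <- if (allow_one) x <= 1 else x < 1
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || !hi_ok) {
    abort(sprintf("`%s` must be a single fraction in [0, %s).", name,
      if (allow_one) "1]" else "1"), class = "repquant_argument_error")
  }
  invisible(x)
}

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    abort(
      sprintf("%s is missing required column%s: %s.", what,
        if (length(missing) > 1L) "s" else "",
        paste0("`", missing, "`", collapse = ", ")),
      class = "repquant_format_error"
    )
  }
  invisible(df)
}
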