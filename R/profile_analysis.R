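#' Candidate boundary slopes for the sweep
#'
#' Growth-ring boundaries are rarely perfectly horizontal, so row profiles are
#' re-counted along slanted paths with slope `s = k / w` (rise in rows per
#' column). Candidates are returned in sweep order: `0` first, then
#' `+1/w, -1/w, +2/w, -2/w, ...` up to `k_max / w` — deterministic, and
#' favouring the unsheared solution. The default `k_max = floor(w / 10)`;
#' a larger cap (25 for a 128-px strip, i.e. max slope 0.195) may be set to
#' tolerate steeper boundaries, at increasing risk of latching onto vertical
#' wood rays.
#'
#' @param w Strip width in pixels.
#' @param k_max Maximum integer slope numerator; default `floor(w / 10)`.
#' @param include_negative Sweep negative slopes too (default `TRUE`).
#' @return Numeric vector of slopes, `0` first.
#' @export
slope_candidates <- function(w, k_max = max(1L, w %/% 10L),
                             include_negative = TRUE) {
  w <- as.integer(w)
  k_max <- as.integer(k_max)
  if (w < 1L || k_max < 1L) stop("w and k_max must be >= 1", call. = FALSE)
  ks <- seq_len(k_max)
  s <- if (include_negative) {
    as.numeric(rbind(ks, -ks)) / w   # +1, -1, +2, -2, ...
  } else {
    ks / w
  }
  c(0, s)
}

# half-up rounding; base round() is round-half-even and would shift the
# sampled path at exact .5 offsets
round_half_up <- function(x) floor(x + 0.5)

#' Count black pixels per row along a slanted path
#'
#' For each base row `r` the count is taken along the path that rises `s`
#' rows per column: column `x` (0-based) samples row `r + round(s * x)` when
#' `s >= 0`, and `r + round(|s| * (w - x))` when `s < 0`, rows clamped to the
#' image. The base-row range is trimmed so every path stays inside the strip:
#' the profile has `h - ceiling(|s| * w)` rows. With
#' `strict_row_bound = TRUE` the more conservative cap of `h - w + 1` rows is
#' used instead.
#'
#' Black pixels (value 0) are the tracheid-wall signal; the count for a row is
#' the number of sampled pixels equal to 0, i.e. `sum(1 - p/255)` over the
#' path. (The literal column sum of `p/255` would count white pixels.)
#'
#' @param binary Numeric matrix over `{0, 255}` (a binarized strip).
#' @param s Slope, rise in rows per column; may be negative.
#' @param strict_row_bound Use the conservative `h - w` maximum base row.
#' @return Integer vector of black counts, one per base row (top to bottom),
#'   each in `[0, w]`.
#' @export
count_black_rows <- function(binary, s = 0, strict_row_bound = FALSE) {
  if (!is.matrix(binary)) stop("binary must be a matrix", call. = FALSE)
  h <- nrow(binary)
  w <- ncol(binary)
  drop_rows <- ceiling(abs(s) * w)
  nr <- h - drop_rows
  if (strict_row_bound) nr <- min(nr, h - w + 1L)
  if (nr < 1L) {
    stop("strip too short for slope ", s, " (height ", h, ")", call. = FALSE)
  }
  x <- 0:(w - 1L)
  off <- if (s >= 0) round_half_up(s * x) else round_half_up(abs(s) * (w - x))
  black <- binary == 0
  idx <- outer(seq_len(nr), as.integer(off), `+`)
  idx[idx > h] <- h
  idx[idx < 1L] <- 1L
  sampled <- black[cbind(as.vector(idx), rep(seq_len(w), each = nr))]
  as.integer(rowSums(matrix(sampled, nrow = nr)))
}

#' Min-max normalize a row-count profile to 0--100
#'
#' Rescales raw black-pixel counts so every profile spans the same vertical
#' axis: `100 * (Y - Y_min) / (Y_max - Y_min)`. A constant profile (no
#' spread, e.g. an all-white strip) is degenerate: all values map to 0 and
#' the `"degenerate"` attribute is set, which guarantees no transition is
#' found downstream.
#'
#' @param raw Numeric vector of row counts.
#' @return Numeric vector in `[0, 100]` with logical attribute `degenerate`.
#' @export
normalize_profile <- function(raw) {
  if (length(raw) == 0L) stop("empty profile", call. = FALSE)
  rng <- range(raw)
  if (rng[1L] == rng[2L]) {
    out <- rep(0, length(raw))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  out <- 100 * (raw - rng[1L]) / (rng[2L] - rng[1L])
  attr(out, "degenerate") <- FALSE
  out
}

#' Binarize a normalized profile at a cut of 60
#'
#' Normalized values at or above `cut` map to 100 (latewood-like rows), the
#' rest to 0 (earlywood-like rows).
#'
#' @param normalized Numeric vector in `[0, 100]`.
#' @param cut Threshold in normalized units (default 60).
#' @return Numeric vector over `{0, 100}`.
#' @export
binarize_profile <- function(normalized, cut = 60) {
  ifelse(normalized >= cut, 100, 0)
}

#' Build the full row profile of a binarized strip
#'
#' Convenience wrapper chaining [count_black_rows()], [normalize_profile()]
#' and [binarize_profile()] into one tidy table.
#'
#' @inheritParams count_black_rows
#' @inheritParams binarize_profile
#' @return Tibble of class `ring_profile` with columns `row` (1-based base
#'   row), `count`, `normalized`, `binarized`; attributes `slope`, `w`,
#'   `degenerate`.
#' @export
row_profile <- function(binary, s = 0, cut = 60, strict_row_bound = FALSE) {
  raw <- count_black_rows(binary, s, strict_row_bound = strict_row_bound)
  norm <- normalize_profile(raw)
  out <- tibble::tibble(
    row = seq_along(raw),
    count = raw,
    normalized = as.numeric(norm),
    binarized = binarize_profile(as.numeric(norm), cut = cut)
  )
  attr(out, "slope") <- s
  attr(out, "w") <- ncol(binary)
  attr(out, "degenerate") <- isTRUE(attr(norm, "degenerate"))
  class(out) <- c("ring_profile", class(out))
  out
}

#' Write a profile as a two-column CSV
#'
#' Exports the raw counts in the `row,count` dialect (header included),
#' matching the spreadsheet layout used for manual inspection.
#'
#' @param profile A `ring_profile` tibble (or any tibble with `row`, `count`).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  readr::write_csv(dplyr::select(tibble::as_tibble(profile), "row", "count"),
                   path)
  invisible(path)
}
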