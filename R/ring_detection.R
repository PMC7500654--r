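#' Transition-criterion parameters
#'
#' Constants of the six-condition test that decides whether a strip shows an
#' abrupt earlywood-to-latewood transition band. Defaults are the method's
#' printed constants: a 10-row all-zero run above the candidate row, a 20-row
#' all-100 run below it, a profile cut at 60 normalized units, a latewood
#' band density above 0.3 and a latewood/earlywood contrast above 0.5.
#'
#' `density_norm` chooses how the density condition is normalized:
#' `"band"` (default) divides the latewood-band black-pixel sum by
#' `one_run * w`, i.e. requires the mean black fraction of the band to exceed
#' `density_min`; `"literal"` divides the 20-row sum by `w` alone, a nearly
#' vacuous reading kept for completeness.
#'
#' @param zero_run Rows of the earlywood (all-zero) run, candidate row
#'   included (default 10).
#' @param one_run Rows of the latewood (all-100) run below the candidate row
#'   (default 20).
#' @param cut Profile binarization threshold in normalized units (default 60).
#' @param density_min Minimum latewood density fraction (default 0.3).
#' @param contrast_min Minimum latewood/earlywood contrast (default 0.5).
#' @param density_norm `"band"` or `"literal"` (see Details).
#' @return A list of class `criterion_params`.
#' @export
criterion_params <- function(zero_run = 10L, one_run = 20L, cut = 60,
                             density_min = 0.3, contrast_min = 0.5,
                             density_norm = c("band", "literal")) {
  density_norm <- match.arg(density_norm)
  zero_run <- as.integer(zero_run)
  one_run <- as.integer(one_run)
  stopifnot(zero_run >= 1L, one_run >= 1L,
            density_min > 0, density_min < 1,
            contrast_min > 0, contrast_min < 1)
  structure(
    list(zero_run = zero_run, one_run = one_run, cut = cut,
         density_min = density_min, contrast_min = contrast_min,
         density_norm = density_norm),
    class = "criterion_params"
  )
}

#' Slope-sweep configuration
#'
#' @param k_max Maximum integer slope numerator; `NULL` (default) resolves to
#'   `floor(w / 10)` for the strip width at hand. Set to 25 for 128-px strips
#'   to allow the steeper 0.195 maximum slope.
#' @param include_negative Sweep negative (upward-going) slopes (default
#'   `TRUE`).
#' @param strict_row_bound Use the conservative `h - w` base-row cap when
#'   counting (default `FALSE`; see [count_black_rows()]).
#' @return A list of class `sweep_config`.
#' @export
sweep_config <- function(k_max = NULL, include_negative = TRUE,
                         strict_row_bound = FALSE) {
  if (!is.null(k_max)) {
    k_max <- as.integer(k_max)
    stopifnot(k_max >= 1L)
  }
  structure(
    list(k_max = k_max, include_negative = include_negative,
         strict_row_bound = strict_row_bound),
    class = "sweep_config"
  )
}

resolve_k_max <- function(sweep, w) {
  if (is.null(sweep$k_max)) max(1L, w %/% 10L) else sweep$k_max
}

profile_vectors <- function(profile) {
  if (is.data.frame(profile)) {
    list(raw = profile$count, yb = profile$binarized,
         degenerate = isTRUE(attr(profile, "degenerate")))
  } else {
    stop("profile must be a ring_profile tibble", call. = FALSE)
  }
}

#' Find the earlywood-to-latewood transition row of a profile
#'
#' Scans the binarized profile top to bottom for the smallest row index `i`
#' (1-based) such that: (a) `YB[i] == 0`; (b) `YB[i+1] == 100`; (c) the
#' `zero_run` rows ending at `i` are all 0; (d) the `one_run` rows following
#' `i` are all 100; (e) the latewood band below `i` is dense enough
#' (see [criterion_params()]); and (f) the black-pixel mass of the latewood
#' band exceeds that of the earlywood run by the contrast margin:
#' `(S_late - S_early) / S_late > contrast_min` (fails when `S_late` is 0).
#' The returned index is the last earlywood row of the transition band.
#'
#' Profiles shorter than `zero_run + one_run`, and degenerate (constant)
#' profiles, yield no transition.
#'
#' @param profile A `ring_profile` tibble from [row_profile()].
#' @param params A [criterion_params()] list.
#' @param w Strip width in pixels; defaults to the profile's `w` attribute.
#' @return Integer row index (1-based), or `NA_integer_` when no row
#'   qualifies.
#' @export
find_transition_row <- function(profile, params = criterion_params(),
                                w = attr(profile, "w")) {
  pv <- profile_vectors(profile)
  if (pv$degenerate) return(NA_integer_)
  y <- as.numeric(pv$raw)
  yb <- as.numeric(pv$yb)
  n <- length(yb)
  zr <- params$zero_run
  on <- params$one_run
  if (n < zr + on) return(NA_integer_)
  if (is.null(w)) stop("strip width w is required", call. = FALSE)

  i <- zr:(n - on)                       # candidate rows
  Syb <- c(0, cumsum(yb))
  Sy <- c(0, cumsum(y))
  zero_before <- (Syb[i + 1L] - Syb[i - zr + 1L]) == 0
  one_after <- (Syb[i + on + 1L] - Syb[i + 1L]) == 100 * on
  s_early <- Sy[i + 1L] - Sy[i - zr + 1L]
  s_late <- Sy[i + on + 1L] - Sy[i + 1L]
  dens <- if (params$density_norm == "band") {
    s_late / (on * w) > params$density_min
  } else {
    s_late / w > params$density_min
  }
  contr <- s_late > 0 & (s_late - s_early) / s_late > params$contrast_min
  ok <- yb[i] == 0 & yb[i + 1L] == 100 & zero_before & one_after &
    dens & contr
  hit <- which(ok)
  if (length(hit) == 0L) NA_integer_ else i[hit[1L]]
}

#' Brute-force reference for the transition criterion
#'
#' Checks every candidate row with naive re-summation of all six conditions.
#' Exists purely as an independent cross-check of the cumulative-sum
#' implementation in [find_transition_row()]; the two must agree on every
#' input.
#'
#' @inheritParams find_transition_row
#' @return Integer row index (1-based) or `NA_integer_`.
#' @export
transition_row_oracle <- function(profile, params = criterion_params(),
                                  w = attr(profile, "w")) {
  pv <- profile_vectors(profile)
  if (pv$degenerate) return(NA_integer_)
  y <- as.numeric(pv$raw)
  yb <- as.numeric(pv$yb)
  n <- length(yb)
  zr <- params$zero_run
  on <- params$one_run
  if (n < zr + on) return(NA_integer_)
  for (i in seq_len(n)) {
    if (i < zr || i + on > n) next
    if (yb[i] != 0) next
    if (yb[i + 1L] != 100) next
    if (sum(yb[(i - zr + 1L):i]) != 0) next
    if (sum(yb[(i + 1L):(i + on)]) != 100 * on) next
    s_late <- sum(y[(i + 1L):(i + on)])
    s_early <- sum(y[(i - zr + 1L):i])
    dens <- if (params$density_norm == "band") s_late / (on * w) else s_late / w
    if (!(dens > params$density_min)) next
    if (s_late <= 0) next
    if (!((s_late - s_early) / s_late > params$contrast_min)) next
    return(i)
  }
  NA_integer_
}

#' Classify one strip
#'
#' Runs the full per-strip pipeline: grayscale conversion, automatic
#' mean-plus-sd thresholding, binarization, then the slope sweep. For each
#' candidate slope (0 first) the slope-corrected row profile is built and the
#' transition criterion applied; the first slope with a qualifying row wins
#' and the sweep stops. If every slope is exhausted without a hit — or the
#' strip is too small to host the runs at any slope — the strip is reported
#' as not distinct.
#'
#' @param strip Numeric RGB array `h x w x 3` (one strip).
#' @param criterion A [criterion_params()] list.
#' @param sweep A [sweep_config()] list.
#' @param strip_index Optional index carried into the result.
#' @return One-row tibble: `strip_index`, `distinct`, `transition_row`,
#'   `slope_used`, `mu`, `sigma`, `tau`.
#' @export
classify_subimage <- function(strip, criterion = criterion_params(),
                              sweep = sweep_config(), strip_index = NA_integer_) {
  strip <- as_micro_image(strip)
  gray <- rgb_to_gray(strip)
  stats <- threshold_stats(gray)
  binary <- binarize_image(gray, stats)
  h <- nrow(binary)
  w <- ncol(binary)
  min_rows <- criterion$zero_run + criterion$one_run
  slopes <- slope_candidates(w, k_max = resolve_k_max(sweep, w),
                             include_negative = sweep$include_negative)
  attempted <- FALSE
  for (s in slopes) {
    nr <- h - ceiling(abs(s) * w)
    if (sweep$strict_row_bound) nr <- min(nr, h - w + 1L)
    if (nr < min_rows) next
    attempted <- TRUE
    prof <- row_profile(binary, s, cut = criterion$cut,
                        strict_row_bound = sweep$strict_row_bound)
    if (isTRUE(attr(prof, "degenerate"))) next
    row <- find_transition_row(prof, criterion, w = w)
    if (!is.na(row)) {
      return(tibble::tibble(
        strip_index = strip_index, distinct = TRUE,
        transition_row = as.integer(row), slope_used = s,
        mu = stats$mu, sigma = stats$sigma, tau = stats$tau
      ))
    }
  }
  if (!attempted) {
    warning("strip ", strip_index, " too small for the transition criterion (",
            h, " rows); counted as not distinct", call. = FALSE)
  }
  tibble::tibble(
    strip_index = strip_index, distinct = FALSE,
    transition_row = NA_integer_, slope_used = NA_real_,
    mu = stats$mu, sigma = stats$sigma, tau = stats$tau
  )
}

#' Classify a whole slide
#'
#' Crops the slide into `count` vertical strips, classifies each strip
#' independently ([classify_subimage()]) and aggregates by majority vote.
#' The distinct degree is the percentage of strips in which the transition
#' criterion fired; the slide is called "distinct" when strictly more than
#' 50% of strips are distinct (a 50/50 split is "indistinct or absent").
#'
#' @param image Numeric RGB array, or a path readable by
#'   [read_micro_image()].
#' @param criterion A [criterion_params()] list.
#' @param sweep A [sweep_config()] list.
#' @param count Number of strips (default 20).
#' @return An object of class `ring_verdict`: a list with `strips` (tibble of
#'   per-strip verdicts), `n_strips`, `n_distinct`, `distinct_degree`,
#'   `label`, `iawa_code`, and the parameter lists used. Supports
#'   [generics::tidy()], [generics::glance()] and [ggplot2::autoplot()].
#' @export
classify_slide <- function(image, criterion = criterion_params(),
                           sweep = sweep_config(), count = 20L) {
  if (is.character(image)) image <- read_micro_image(image)
  strips <- crop_subimages(image, count)
  per_strip <- purrr::map2(strips$image, strips$strip_index,
                           function(img, i) {
                             classify_subimage(img, criterion, sweep,
                                               strip_index = i)
                           })
  per_strip <- dplyr::bind_rows(per_strip)
  n_distinct <- sum(per_strip$distinct)
  degree <- 100 * n_distinct / nrow(per_strip)
  label <- if (degree > 50) "distinct" else "indistinct or absent"
  structure(
    list(
      strips = per_strip,
      n_strips = nrow(per_strip),
      n_distinct = n_distinct,
      distinct_degree = degree,
      label = label,
      iawa_code = iawa_feature_code(label),
      strip_width = attr(strips, "strip_width"),
      criterion = criterion,
      sweep = sweep
    ),
    class = "ring_verdict"
  )
}

#' IAWA softwood feature code for a verdict label
#'
#' Maps the qualitative verdict to the IAWA microscopic feature code for
#' softwood identification: `"40p"` for growth-ring boundaries distinct,
#' `"41p"` for indistinct or absent.
#'
#' @param label `"distinct"` or `"indistinct or absent"` (case-insensitive).
#' @return `"40p"` or `"41p"`.
#' @export
iawa_feature_code <- function(label) {
  label <- tolower(as.character(label))
  if (!label %in% c("distinct", "indistinct or absent")) {
    stop("unknown verdict label: ", label, call. = FALSE)
  }
  if (label == "distinct") "40p" else "41p"
}

#' @export
print.ring_verdict <- function(x, ...) {
  cat("Growth-ring boundary verdict\n")
  cat(sprintf("  strips:          %d (width %s px)\n", x$n_strips,
              x$strip_width %||% "?"))
  cat(sprintf("  distinct strips: %d\n", x$n_distinct))
  cat(sprintf("  distinct degree: %.1f%%\n", x$distinct_degree))
  cat(sprintf("  verdict:         %s (IAWA %s)\n", x$label, x$iawa_code))
  invisible(x)
}

#' Tidy per-strip results of a slide verdict
#'
#' @param x A `ring_verdict` object.
#' @param ... Unused.
#' @return The per-strip tibble (`strip_index`, `distinct`, `transition_row`,
#'   `slope_used`, `mu`, `sigma`, `tau`).
#' @method tidy ring_verdict
#' @export
tidy.ring_verdict <- function(x, ...) {
  x$strips
}

#' One-row summary of a slide verdict
#'
#' @param x A `ring_verdict` object.
#' @param ... Unused.
#' @return One-row tibble: `distinct_degree`, `label`, `iawa_code`,
#'   `n_distinct`, `n_strips`.
#' @method glance ring_verdict
#' @export
glance.ring_verdict <- function(x, ...) {
  tibble::tibble(
    distinct_degree = x$distinct_degree,
    label = x$label,
    iawa_code = x$iawa_code,
    n_distinct = x$n_distinct,
    n_strips = x$n_strips
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
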