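# RGB rendering constants for synthetic sections. Safranin-stained material:
# tracheid walls render dark red, lumina a light pink. The achromatic jitter
# half-width keeps within-class gray spread small enough that the automatic
# mu + sigma threshold always falls in the gap between the two classes
# (see the methods vignette for the margin analysis).
ring_palette <- function() {
  list(
    wall = c(120, 20, 30),     # gray level 51.0
    lumen = c(250, 205, 210),  # gray level 219.0
    jitter = 8                 # +/- gray levels, uniform, all channels equally
  )
}

#' Specification of a synthetic ring image
#'
#' Parameterizes a synthetic conifer cross-section: alternating low-density
#' (earlywood) and high-density (latewood) horizontal bands with controllable
#' transition abruptness, boundary slope, pixel noise and vertical ray
#' streaks. Texture is modelled at the black-pixel-fraction level (each
#' pixel's wall/lumen class is sampled independently from a per-row dark
#' probability), because the detector consumes only row black-pixel counts.
#'
#' The default dark fractions (0.9 latewood, 0.3 earlywood at half-period
#' latewood) keep the overall dark-pixel fraction above one half. That is a
#' hard requirement of the mean-plus-sd threshold: for any gray distribution
#' at most half the pixels can sit at or above `mu + sigma`, so a synthetic
#' section whose wall class is a minority could never binarize to its
#' intended class map.
#'
#' @param width,height Image size in pixels (defaults 2560 x 1920, the
#'   nominal 5x micro-image size).
#' @param ring_period Vertical distance between successive boundaries, rows
#'   (default `height / 4`, i.e. four rings per slide).
#' @param latewood_fraction Fraction of each period occupied by the dark
#'   band (default 0.5).
#' @param abruptness Real in `[0, 1]`: 1 is a step transition, 0 a pure
#'   sinusoidal density modulation; intermediate values blend the two.
#' @param dark_fraction_late,dark_fraction_early Target black-pixel fractions
#'   of latewood and earlywood rows (defaults 0.9 and 0.3).
#' @param boundary_slope Rise per column applied as a shear to the band
#'   pattern (default 0).
#' @param noise Probability of flipping a pixel's wall/lumen class
#'   (default 0).
#' @param ray_count Number of 1-px vertical dark streaks emulating wood rays
#'   (default 0).
#' @param seed Integer seed; the generated image is reproducible for a fixed
#'   spec and seed.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(width = 2560L, height = 1920L,
                           ring_period = height / 4,
                           latewood_fraction = 0.5,
                           abruptness = 1,
                           dark_fraction_late = 0.9,
                           dark_fraction_early = 0.3,
                           boundary_slope = 0,
                           noise = 0,
                           ray_count = 0L,
                           seed = 1L) {
  width <- as.integer(width)
  height <- as.integer(height)
  if (width < 1L || height < 1L) stop("invalid image size", call. = FALSE)
  if (ring_period <= 1) stop("ring_period must exceed 1 row", call. = FALSE)
  if (abruptness < 0 || abruptness > 1) {
    stop("abruptness must lie in [0, 1]", call. = FALSE)
  }
  if (!(dark_fraction_early >= 0 && dark_fraction_early < dark_fraction_late &&
        dark_fraction_late <= 1)) {
    stop("need 0 <= dark_fraction_early < dark_fraction_late <= 1",
         call. = FALSE)
  }
  if (latewood_fraction <= 0 || latewood_fraction >= 1) {
    stop("latewood_fraction must lie in (0, 1)", call. = FALSE)
  }
  if (noise < 0 || noise > 1) stop("noise must lie in [0, 1]", call. = FALSE)
  structure(
    list(width = width, height = height, ring_period = ring_period,
         latewood_fraction = latewood_fraction, abruptness = abruptness,
         dark_fraction_late = dark_fraction_late,
         dark_fraction_early = dark_fraction_early,
         boundary_slope = boundary_slope, noise = noise,
         ray_count = as.integer(ray_count), seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

# ground-truth label: a transition band is abrupt enough to count as a
# distinct boundary when the step component dominates and the dark-fraction
# contrast clears the criterion thresholds by construction
synthetic_label <- function(spec, params = criterion_params()) {
  dl <- spec$dark_fraction_late
  de <- spec$dark_fraction_early
  abrupt <- spec$abruptness >= 0.8
  contrast_ok <- (dl - de) / dl > params$contrast_min
  density_ok <- dl > params$density_min
  if (abrupt && contrast_ok && density_ok) "distinct" else "indistinct or absent"
}

with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Generate a synthetic ring image with ground truth
#'
#' Builds the per-row dark-probability profile implied by the spec (a step,
#' a sinusoid, or their blend, sheared by `boundary_slope`), samples every
#' pixel's wall/lumen class independently, optionally flips classes with the
#' `noise` probability and overlays `ray_count` vertical dark streaks, then
#' renders wall pixels in a dark safranin red and lumen pixels in a light
#' pink with a small achromatic jitter.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with elements `image` (numeric `h x w x 3` array,
#'   0--255), `label` (`"distinct"` or `"indistinct or absent"`, the ground
#'   truth by construction) and `spec`.
#' @export
generate_ring_image <- function(spec) {
  if (!inherits(spec, "synthetic_spec")) {
    stop("spec must be a synthetic_spec", call. = FALSE)
  }
  h <- spec$height
  w <- spec$width
  P <- spec$ring_period
  f <- spec$latewood_fraction
  a <- spec$abruptness
  pal <- ring_palette()

  r0 <- matrix(0:(h - 1L), nrow = h, ncol = w)
  x0 <- matrix(0:(w - 1L), nrow = h, ncol = w, byrow = TRUE)
  phase <- ((r0 - spec$boundary_slope * x0) %% P) / P

  g_step <- (phase >= 1 - f) * 1
  centre <- 1 - f / 2                       # latewood band centre
  g_sin <- 0.5 * (1 + cos(2 * pi * (phase - centre)))
  g <- a * g_step + (1 - a) * g_sin

  d <- spec$dark_fraction_early +
    (spec$dark_fraction_late - spec$dark_fraction_early) * g
  d <- d * (1 - spec$noise) + (1 - d) * spec$noise

  img <- with_local_seed(spec$seed, {
    dark <- matrix(stats::runif(h * w) < d, nrow = h)
    if (spec$ray_count > 0L) {
      dark[, sample.int(w, min(spec$ray_count, w))] <- TRUE
    }
    jitter <- matrix(stats::runif(h * w, -pal$jitter, pal$jitter), nrow = h)
    out <- array(0, dim = c(h, w, 3L))
    for (ch in 1:3) {
      v <- ifelse(dark, pal$wall[ch], pal$lumen[ch]) + jitter
      out[, , ch] <- pmin(pmax(v, 0), 255)
    }
    out
  })

  list(image = img, label = synthetic_label(spec), spec = spec)
}

#' Fixed battery of labelled synthetic slides
#'
#' Emits the default validation battery: 10 abrupt (ground truth "distinct")
#' and 10 gradual (ground truth "indistinct or absent") slides spanning
#' boundary slopes `{0, +-1/128, +-5/128}` and class-flip noise levels
#' `{0, 0.02, 0.05}`; within each group of ten, the five noise-free slides
#' cover all five slopes. Specs are fully determined by `seed`, so the same
#' seed reproduces the same battery.
#'
#' Images are not materialized by default (a full battery of 2560 x 1920
#' slides is large); generate them per row with [generate_ring_image()], or
#' pass `include_images = TRUE`.
#'
#' @param seed Integer master seed.
#' @param width,height Slide size passed to [synthetic_spec()].
#' @param include_images Materialize an `image` list-column (default
#'   `FALSE`).
#' @return Tibble with columns `fixture_id`, `truth`, `abruptness`, `slope`,
#'   `noise`, `seed`, `spec` (list of [synthetic_spec()]), and optionally
#'   `image`.
#' @export
fixture_suite <- function(seed = 1L, width = 2560L, height = 1920L,
                          include_images = FALSE) {
  slopes <- c(0, 1 / 128, -1 / 128, 5 / 128, -5 / 128)
  noises <- c(0, 0, 0, 0, 0, 0.02, 0.02, 0.02, 0.05, 0.05)
  slope_of <- function(i) slopes[(i - 1L) %% 5L + 1L]
  grid <- tibble::tibble(
    fixture_id = 1:20,
    abruptness = rep(c(1, 0), each = 10L),
    slope = vapply(1:20, function(i) slope_of((i - 1L) %% 10L + 1L),
                   numeric(1)),
    noise = rep(noises, 2L),
    seed = as.integer((as.numeric(seed) * 131 + 1:20) %% 2147483647)
  )
  grid$spec <- purrr::pmap(grid, function(fixture_id, abruptness, slope,
                                          noise, seed) {
    synthetic_spec(width = width, height = height, abruptness = abruptness,
                   boundary_slope = slope, noise = noise, seed = seed)
  })
  grid$truth <- vapply(grid$spec, synthetic_label, character(1))
  if (include_images) {
    grid$image <- purrr::map(grid$spec, function(s) generate_ring_image(s)$image)
  }
  grid[, c("fixture_id", "truth", "abruptness", "slope", "noise", "seed",
           intersect(c("spec", "image"), names(grid)))]
}

#' Write a synthetic image to PNG with a JSON sidecar
#'
#' @param generated Result of [generate_ring_image()].
#' @param path Output PNG path; the sidecar is written next to it with a
#'   `.json` extension.
#' @return `path`, invisibly.
#' @export
write_synthetic_png <- function(generated, path) {
  png::writePNG(generated$image / 255, path)
  sidecar <- sub("\\.png$", ".json", path, ignore.case = TRUE)
  if (identical(sidecar, path)) sidecar <- paste0(path, ".json")
  meta <- c(unclass(generated$spec), list(label = generated$label))
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
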