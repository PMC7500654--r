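# Build a ring_profile tibble straight from raw row counts, bypassing the
# image stage, so the transition criterion can be exercised on hand-crafted
# profiles.
profile_from_counts <- function(raw, w = 128L, cut = 60) {
  norm <- normalize_profile(raw)
  out <- tibble::tibble(
    row = seq_along(raw),
    count = as.integer(raw),
    normalized = as.numeric(norm),
    binarized = binarize_profile(as.numeric(norm), cut = cut)
  )
  attr(out, "slope") <- 0
  attr(out, "w") <- as.integer(w)
  attr(out, "degenerate") <- isTRUE(attr(norm, "degenerate"))
  class(out) <- c("ring_profile", class(out))
  out
}

# Random profiles for oracle-equivalence checks: a mix of pure noise and
# blocky earlywood/latewood-like alternations (the latter actually produce
# transitions, so both branches of the criterion are exercised).
random_profile <- function(w = 128L) {
  n <- sample(30:400, 1L)
  raw <- if (runif(1) < 0.5) {
    sample(0:w, n, replace = TRUE)                       # unstructured
  } else {
    lvls <- sample(0:w, 2L)
    out <- integer(0)
    while (length(out) < n) {                            # blocky
      len <- sample(5:40, 1L)
      lvl <- sample(lvls, 1L)
      out <- c(out, pmin(pmax(lvl + sample(-3:3, len, TRUE), 0L), w))
    }
    out[seq_len(n)]
  }
  profile_from_counts(raw, w = w)
}

# An RGB strip whose binarized form has exactly `counts[r]` black pixels in
# row r: dark pixels at gray 40, light at 220, so the mean-plus-sd threshold
# lands between the classes whenever dark pixels are the majority overall.
strip_from_counts <- function(counts, w) {
  h <- length(counts)
  gray <- matrix(220, h, w)
  for (r in seq_len(h)) {
    if (counts[r] > 0) gray[r, seq_len(counts[r])] <- 40
  }
  array(rep(gray, 3L), dim = c(h, w, 3L))
}
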