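# Reverse conservation analysis: standardize per-site conservation scores,
# sliding-window smoothing, peak calling at an intensity threshold, and
# comparison of clade-specific profiles.

#' Standardize a score vector
#'
#' Centers and scales to mean 0 and sample standard deviation 1 (n-1
#' denominator).
#'
#' @param S numeric vector, length >= 2, non-constant.
#' @return Standardized numeric vector.
#' @export
normalize_scores <- function(S) {
  if (length(S) < 2) stop("need at least 2 scores")
  s <- sd(S)
  if (s == 0) stop("zero variance: scores are constant")
  (S - mean(S)) / s
}

#' Centered sliding-window mean
#'
#' `W[i]` is the mean of `z` over the window of width `n` centered at `i`,
#' intersected with the sequence (edge windows shrink).
#'
#' @param z numeric vector.
#' @param n odd window width (default 7).
#' @return Numeric vector of window means, same length as `z`.
#' @export
window_mean <- function(z, n = 7) {
  if (n %% 2 == 0) stop("window width n must be odd")
  if (n < 1) stop("n must be >= 1")
  h <- (n - 1) / 2
  L <- length(z)
  cs <- cumsum(c(0, z))
  lo <- pmax(seq_len(L) - h, 1)
  hi <- pmin(seq_len(L) + h, L)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

roman_labels <- function(k) {
  if (k == 0) return(character(0))
  as.character(utils::as.roman(seq_len(k)))
}

#' Call peaks in a window-mean profile
#'
#' Maximal runs of consecutive positions with `W >= I` (the threshold is
#' inclusive), ordered N- to C-terminally. Peaks spanning at least
#' `label_min` positions get Roman-numeral labels.
#'
#' @param W numeric vector of window means.
#' @param I intensity threshold (default 0.5).
#' @param positions optional position numbering (default `seq_along(W)`).
#' @param label_min minimum run length for a label (default 3).
#' @return A tibble with columns `start`, `end`, `max_W`, `label`.
#' @export
call_peaks <- function(W, I = 0.5, positions = seq_along(W), label_min = 3) {
  above <- W >= I
  if (!any(above)) {
    return(tibble(start = integer(0), end = integer(0),
                  max_W = numeric(0), label = character(0)))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- which(r$values)
  out <- tibble(
    start = positions[starts[runs]],
    end = positions[ends[runs]],
    max_W = vapply(runs, function(k) max(W[starts[k]:ends[k]]), 0),
    label = NA_character_
  )
  lab <- which(ends[runs] - starts[runs] + 1 >= label_min)
  out$label[lab] <- roman_labels(length(lab))
  out
}

#' Build a reverse-conservation profile
#'
#' Takes per-site conservation scores (high = variable), standardizes
#' them, applies the sliding-window mean, and calls peaks.
#'
#' @param x a `site_rate_profile` from [eb_site_rates()], or a numeric
#'   vector of raw S scores.
#' @param n odd window width (default 7).
#' @param I intensity threshold in standard-deviation units (default 0.5).
#' @param positions optional position numbering; defaults to the profile's
#'   reference positions when complete, else 1..L.
#' @param edges `"shrink"` (default) keeps edge windows with fewer terms;
#'   `"drop"` sets W to `NA` where the full window does not fit.
#' @return A tibble of class `rca_profile` with columns `position`, `S`,
#'   `z`, `W`, `peak` (label or NA). Attributes: `peaks` (tibble from
#'   [call_peaks()]), `window_n`, `intensity`.
#' @export
rca_profile <- function(x, n = 7, I = 0.5, positions = NULL,
                        edges = c("shrink", "drop")) {
  edges <- match.arg(edges)
  S <- if (is.data.frame(x)) x$S else as.numeric(x)
  L <- length(S)
  if (is.null(positions)) {
    positions <- if (is.data.frame(x) && !anyNA(x$ref_pos)) x$ref_pos
                 else seq_len(L)
  }
  z <- normalize_scores(S)
  W <- window_mean(z, n)
  if (edges == "drop") {
    h <- (n - 1) / 2
    if (h > 0) W[c(seq_len(h), (L - h + 1):L)] <- NA_real_
  }
  Wp <- ifelse(is.na(W), -Inf, W)
  peaks <- call_peaks(Wp, I, positions = positions)
  peak_col <- rep(NA_character_, L)
  for (k in seq_len(nrow(peaks))) {
    sel <- positions >= peaks$start[k] & positions <= peaks$end[k]
    peak_col[sel] <- if (is.na(peaks$label[k])) sprintf("peak%d", k) else peaks$label[k]
  }
  out <- tibble(position = positions, S = S, z = z, W = W, peak = peak_col)
  attr(out, "peaks") <- peaks
  attr(out, "window_n") <- n
  attr(out, "intensity") <- I
  class(out) <- c("rca_profile", class(out))
  out
}

#' Peaks of an RCA profile
#'
#' @param profile an `rca_profile`.
#' @return The peak tibble attached by [rca_profile()].
#' @export
rca_peaks <- function(profile) attr(profile, "peaks")

#' Compare two clade-specific RCA profiles
#'
#' Finds maximal runs of positions where exactly one of the two profiles
#' has `W >= I` — the operational definition of regions with different
#' window-mean score distributions between clades.
#'
#' @param a,b `rca_profile` objects on the same coordinate frame.
#' @param I intensity threshold (default 0.5).
#' @return A tibble of class `clade_comparison` with columns `start`,
#'   `end`, `above_in` (`"a"` or `"b"`); per-position detail in attribute
#'   `detail` (position, W_a, W_b, S_a, S_b).
#' @export
compare_clade_profiles <- function(a, b, I = 0.5) {
  if (nrow(a) != nrow(b) || any(a$position != b$position))
    stop("profiles are not on the same coordinate frame")
  above_a <- !is.na(a$W) & a$W >= I
  above_b <- !is.na(b$W) & b$W >= I
  diff <- xor(above_a, above_b)
  out <- tibble(start = integer(0), end = integer(0), above_in = character(0))
  if (any(diff)) {
    r <- rle(diff)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      seg <- starts[k]:ends[k]
      # split segments by which profile is above
      ra <- rle(above_a[seg])
      e2 <- cumsum(ra$lengths); s2 <- e2 - ra$lengths + 1
      for (m in seq_along(ra$values)) {
        idx <- seg[s2[m]:e2[m]]
        out <- dplyr::bind_rows(out, tibble(
          start = a$position[idx[1]], end = a$position[idx[length(idx)]],
          above_in = if (ra$values[m]) "a" else "b"))
      }
    }
  }
  attr(out, "detail") <- tibble(position = a$position,
                                W_a = a$W, W_b = b$W, S_a = a$S, S_b = b$S)
  class(out) <- c("clade_comparison", class(out))
  out
}

#' @export
autoplot.rca_profile <- function(object, ...) {
  I <- attr(object, "intensity")
  peaks <- rca_peaks(object)
  p <- ggplot2::ggplot(as_tibble(object),
                       ggplot2::aes(x = .data$position, y = .data$W)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = I, linetype = "dashed") +
    ggplot2::labs(x = "residue position", y = "W mean score")
  if (nrow(peaks) > 0) {
    p <- p + ggplot2::geom_rect(
      data = peaks, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = -Inf, ymax = Inf),
      alpha = 0.15)
  }
  p
}
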