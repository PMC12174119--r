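#' Stroke template for the writing task character
#'
#' The writing paradigm asks the subject to write the six-stroke Chinese
#' character for "rice" ten times. This template encodes the canonical six
#' strokes as polylines in the unit box, in dictionary stroke order:
#' dot, short left-falling, horizontal, vertical, left-falling,
#' right-falling. Coordinates follow the touch-screen convention
#' (origin top-left, y increases downward), so the template can be scaled
#' and translated directly into device pixels.
#'
#' @return A tibble with one row per template point and columns
#'   `stroke` (1..6), `x`, `y` (both in `[0, 1]`).
#' @examples
#' glyph_template()
#' @export
glyph_template <- function() {
  strokes <- list(
    # dot: upper-left, a falling flick toward the centre
    cbind(x = c(0.29, 0.45), y = c(0.05, 0.31)),
    # short left-falling: upper-right, falling toward centre
    cbind(x = c(0.71, 0.55), y = c(0.05, 0.31)),
    # horizontal
    cbind(x = c(0.08, 0.92), y = c(0.42, 0.42)),
    # vertical, crossing the horizontal
    cbind(x = c(0.50, 0.50), y = c(0.30, 0.95)),
    # left-falling from the crossing
    cbind(x = c(0.48, 0.30, 0.10), y = c(0.48, 0.70, 0.92)),
    # right-falling from the crossing
    cbind(x = c(0.52, 0.70, 0.90), y = c(0.48, 0.70, 0.92))
  )
  purrr::imap_dfr(strokes, function(m, j) {
    tibble(stroke = j, x = m[, "x"], y = m[, "y"])
  })
}

# polyline length of a two-column coordinate matrix
polyline_length <- function(x, y) {
  if (length(x) < 2) return(0)
  sum(sqrt(diff(x)^2 + diff(y)^2))
}

# per-stroke unit lengths of the template (used by the simulator)
glyph_stroke_lengths <- function(template = glyph_template()) {
  template %>%
    group_by(.data$stroke) %>%
    summarise(len = polyline_length(.data$x, .data$y), .groups = "drop") %>%
    pull("len")
}

# bbox centre of a stroke: immune to sampling density and to repeated
# (stationary) samples, unlike the mean of the sampled points
stroke_center <- function(x, y) {
  c((min(x) + max(x)) / 2, (min(y) + max(y)) / 2)
}

# compact per-stroke shape descriptor: bbox centre plus the unit
# start-to-end direction (down-weighted), in normalised character
# coordinates. The centre is invariant to a subject's per-stroke length
# style (scaling about the centre) and to stationary holds; the unit
# direction is length-free. Used for stroke-order matching.
stroke_features <- function(x, y) {
  n <- length(x)
  dx <- x[n] - x[1]; dy <- y[n] - y[1]
  nrm <- sqrt(dx^2 + dy^2)
  if (nrm < 1e-12) {
    ux <- 0; uy <- 0
  } else {
    ux <- dx / nrm; uy <- dy / nrm
  }
  c(stroke_center(x, y), 0.3 * ux, 0.3 * uy)
}

glyph_stroke_features <- function(template = glyph_template()) {
  # bbox-normalise the template the same way score_task() normalises a
  # detected character, so descriptors live in the same frame
  x0 <- min(template$x); y0 <- min(template$y)
  scale <- max(diff(range(template$x)), diff(range(template$y)))
  template <- mutate(template,
                     x = (.data$x - x0) / scale,
                     y = (.data$y - y0) / scale)
  feats <- template %>%
    group_by(.data$stroke) %>%
    summarise(f = list(stroke_features(.data$x, .data$y)), .groups = "drop") %>%
    pull("f")
  do.call(rbind, feats)
}
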