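#' Score the writing task
#'
#' The task score (`EFDB_1`) rates the completed writing on two binary
#' components, giving a 0..2 score:
#'
#' * *count component* — 1 if the number of detected characters equals the
#'   task's requested count (ten);
#' * *order component* — 1 if, in every detected character, the temporal
#'   stroke order matches the canonical six-stroke dictionary order of the
#'   template.
#'
#' Characters are detected by spatial grouping of the temporally ordered
#' strokes: a stroke starts a new character when its centroid lies more
#' than `char_gap_factor` times the estimated width unit away from the
#' running centroid of the current character. Within each detected
#' character, strokes are similarity-normalised to the unit box and each
#' stroke is matched to the nearest template stroke by a shape descriptor
#' (centroid plus endpoints); the order component requires the match
#' sequence to be the identity on all characters (which implies six
#' strokes per character).
#'
#' This rubric is deliberately simple and isolated here so it can be
#' replaced without touching the rest of the biomarker battery.
#'
#' @param seg A [segment_strokes()] result.
#' @param template Glyph template, see [glyph_template()].
#' @param char_gap_factor New-character threshold as a multiple of the
#'   estimated width unit (default 1.9). The width unit is the median
#'   distance between temporally consecutive stroke centroids: centroids
#'   sit at the template positions regardless of how large or small a
#'   subject draws individual strokes, so the unit is immune to personal
#'   stroke-size style. Within a character no centroid strays further
#'   than ~1.4 units from the running centroid, while the next character
#'   starts >2.5 units away.
#' @return A list: `score` (0..2), `order_component`, `count_component`,
#'   `n_chars`, and `char_of_stroke` (integer character index per stroke).
#' @examples
#' s <- simulate_session(group = "HC", seed = 1)
#' score_task(segment_strokes(s))
#' @export
score_task <- function(seg, template = glyph_template(),
                       char_gap_factor = 1.9) {
  stopifnot(inherits(seg, "segmented_session"))
  st <- seg$strokes
  J <- nrow(st)
  if (J == 0) {
    return(list(score = 0L, order_component = 0L, count_component = 0L,
                n_chars = 0L, char_of_stroke = integer(0),
                diagnostic = "no strokes detected"))
  }

  # bbox centres, not sample means: stationary holds repeat samples and
  # would drag a mean toward the hold position
  cent <- t(vapply(st$points, function(p) stroke_center(p$x, p$y),
                   numeric(2)))
  # width unit: the median distance between temporally consecutive
  # stroke centroids. Stroke bbox sizes vary with each subject's
  # personal stroke proportions (and would both over-split for subjects
  # who draw small and merge for subjects who draw large), but centroids
  # sit at the glyph's template positions, so their typical consecutive
  # distance tracks glyph layout, not stroke style.
  glyph_w <- if (J > 1) {
    max(median(sqrt(rowSums((cent[-1, , drop = FALSE] -
                               cent[-J, , drop = FALSE])^2))), 1e-9)
  } else {
    1e-9
  }
  threshold <- char_gap_factor * glyph_w

  char_of_stroke <- integer(J)
  char_of_stroke[1] <- 1L
  run_centroid <- cent[1, ]
  run_n <- 1L
  for (j in seq_len(J)[-1]) {
    if (sqrt(sum((cent[j, ] - run_centroid)^2)) > threshold) {
      char_of_stroke[j] <- char_of_stroke[j - 1] + 1L
      run_centroid <- cent[j, ]
      run_n <- 1L
    } else {
      char_of_stroke[j] <- char_of_stroke[j - 1]
      run_centroid <- (run_centroid * run_n + cent[j, ]) / (run_n + 1L)
      run_n <- run_n + 1L
    }
  }
  n_chars <- max(char_of_stroke)

  count_component <- as.integer(n_chars == seg$task_char_count)

  tmpl_feat <- glyph_stroke_features(template)
  n_tmpl <- nrow(tmpl_feat)
  order_ok <- TRUE
  for (ch in seq_len(n_chars)) {
    idx <- which(char_of_stroke == ch)
    if (length(idx) != n_tmpl) {
      order_ok <- FALSE
      break
    }
    pts <- dplyr::bind_rows(st$points[idx])
    # similarity-normalise: translate to bbox corner, scale by the larger
    # dimension so aspect is preserved
    x0 <- min(pts$x); y0 <- min(pts$y)
    scale <- max(diff(range(pts$x)), diff(range(pts$y)), 1e-9)
    match_seq <- vapply(idx, function(j) {
      p <- st$points[[j]]
      f <- stroke_features((p$x - x0) / scale, (p$y - y0) / scale)
      which.min(colSums((t(tmpl_feat) - f)^2))
    }, integer(1))
    if (!identical(match_seq, seq_len(n_tmpl))) {
      order_ok <- FALSE
      break
    }
  }
  order_component <- as.integer(order_ok)

  list(
    score = order_component + count_component,
    order_component = order_component,
    count_component = count_component,
    n_chars = n_chars,
    char_of_stroke = char_of_stroke
  )
}
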