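#' Fuzzy elicitation scale for 9-point judgments
#'
#' Maps Saaty-style integer scores 1..9 (1 = equal importance, 9 = extreme
#' dominance) and their reciprocals to triangular fuzzy numbers. The default
#' convention fuzzifies score `s` as `(max(s - delta, 1), s, min(s + delta, 9))`
#' with spread `delta = 1`, keeps score 1 crisp at `(1, 1, 1)`, and maps a
#' reciprocal score `1/s` to the fuzzy reciprocal of the score-`s` TFN, so the
#' scale is reciprocal-consistent by construction.
#'
#' @param delta Spread of the triangular fuzzification, in scale units
#'   (default 1). `delta = 0` gives a crisp scale.
#' @param ceiling Upper clip of the scale (default 9).
#' @return An object of class `"fuzzy_scale"`.
#' @seealso [scale_to_tfn()]
#' @export
fuzzy_scale <- function(delta = 1, ceiling = 9) {
  if (!is.numeric(delta) || length(delta) != 1L || is.na(delta) || delta < 0)
    stop("delta must be a single non-negative number", call. = FALSE)
  if (!is.numeric(ceiling) || length(ceiling) != 1L || ceiling < 1)
    stop("ceiling must be >= 1", call. = FALSE)
  structure(list(delta = delta, ceiling = ceiling), class = "fuzzy_scale")
}

#' @export
print.fuzzy_scale <- function(x, ...) {
  cat("<fuzzy_scale> 9-point triangular scale, delta =", x$delta,
      ", ceiling =", x$ceiling, "\n")
  invisible(x)
}

#' Fuzzify a 9-point score
#'
#' Converts a single elicited score to a TFN under a [fuzzy_scale()].
#' Admissible scores are the integers 1..9 and their reciprocals 1/2..1/9
#' (reciprocals are recognised numerically, e.g. `1/3`).
#'
#' @param score An admissible score.
#' @param scale A [fuzzy_scale()].
#' @return A [tfn()].
#' @examples
#' scale_to_tfn(5)      # (4, 5, 6)
#' scale_to_tfn(9)      # (8, 9, 9), clipped at the scale ceiling
#' scale_to_tfn(1 / 5)  # fuzzy reciprocal of (4, 5, 6)
#' @export
scale_to_tfn <- function(score, scale = fuzzy_scale()) {
  if (!inherits(scale, "fuzzy_scale"))
    stop("scale must be a fuzzy_scale object", call. = FALSE)
  if (!is.numeric(score) || length(score) != 1L || is.na(score) || score <= 0)
    stop("score must be a single positive number", call. = FALSE)
  tol <- 1e-8
  if (score >= 1 - tol) {
    s <- round(score)
    if (abs(score - s) > tol || s < 1 || s > scale$ceiling)
      stop("score ", score, " is not an admissible 9-point value", call. = FALSE)
    if (s == 1) return(tfn(1, 1, 1))
    tfn(max(s - scale$delta, 1), s, min(s + scale$delta, scale$ceiling))
  } else {
    s <- round(1 / score)
    if (abs(1 / score - s) > 1e-6 || s < 2 || s > scale$ceiling)
      stop("score ", score, " is not an admissible reciprocal 9-point value",
           call. = FALSE)
    tfn_invert(scale_to_tfn(s, scale))
  }
}
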