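#' Signed acute orientation difference
#'
#' Orientations of a Gabor patch live on a 180-degree-periodic circle, so the
#' meaningful difference between two orientations is the signed acute angle
#' between them. `acute_diff(a, b)` returns `a - b` wrapped into
#' `(-90, 90]` degrees; the 90-degree ambiguity (two orientations exactly
#' orthogonal) is resolved to `+90`.
#'
#' Throughout the package the history variable Delta is defined as
#' *previous minus present* orientation, so `acute_diff(previous, present)`
#' is the Delta used by the bias analyses: an adjustment error with the same
#' sign as Delta is a bias *toward* the previous orientation (attraction),
#' an error with opposite sign is a bias *away* from it (repulsion).
#'
#' @param a,b orientations in degrees; vectors are recycled.
#' @return signed difference in degrees, in `(-90, 90]`.
#' @examples
#' acute_diff(10, 170)   # +20: wrap-around across 0
#' acute_diff(100, 120)  # -20
#' @export
acute_diff <- function(a, b) {
  90 - ((90 - (a - b)) %% 180)
}

#' Wrap angles to the orientation circle
#'
#' @param x angles in degrees.
#' @return `x` modulo 180, in `[0, 180)`.
#' @export
wrap_orientation <- function(x) {
  x %% 180
}
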