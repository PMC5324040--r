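#' @keywords internal
"_PACKAGE"

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so generators never perturb user code.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive a child seed for an independent substream; kept well below 2^31.
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) %% 1000000L) * 1009L + as.integer(offset)
}

# Fold a value into [lo, hi] by reflection at both edges.
reflect_into <- function(x, lo, hi) {
  width <- hi - lo
  stopifnot(width > 0)
  y <- (x - lo) %% (2 * width)
  y <- ifelse(y > width, 2 * width - y, y)
  y + lo
}

stop_config <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

#' Convert a visual angle to on-screen pixels
#'
#' Small-geometry helper used to set the spatial smoothing kernel of
#' fixation maps in degrees of visual angle rather than raw pixels.
#'
#' @param deg Visual angle in degrees.
#' @param distance_cm Viewing distance in centimetres (default 65).
#' @param screen_px Screen extent in pixels along the relevant axis.
#' @param screen_cm Physical screen extent in centimetres along the same
#'   axis (default 52, a typical 24-inch 5:4 monitor width).
#' @return Extent in pixels subtended by `deg` at the given distance.
#' @examples
#' visual_angle_px(1.2, 65, 1280, 52)
#' @export
visual_angle_px <- function(deg, distance_cm = 65, screen_px = 1280,
                            screen_cm = 52) {
  stopifnot(deg > 0, distance_cm > 0, screen_px > 0, screen_cm > 0)
  cm <- 2 * distance_cm * tan(deg * pi / 360)
  cm * screen_px / screen_cm
}
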