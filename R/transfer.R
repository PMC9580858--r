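# Per-channel transfer function: a monotonic quadratic mapping normalized
# voxel intensity to emissive intensity. Parameterized by three levels:
#   dark   — largest input that is completely transparent (maps to 0)
#   bright — smallest input that is fully emissive and opaque (maps to 1)
#   mid    — output at the midpoint input (dark + bright)/2, i.e. curvature:
#            mid > 0.5 concave down, mid < 0.5 concave up, mid = 0.5 linear.
#
# In normalized coordinates u = (v - dark)/(bright - dark), the quadratic is
# f(u) = A u^2 + B u with A + B = 1 and f(1/2) = mid, giving
# A = 2 - 4 mid, B = 4 mid - 1. Endpoint derivatives f'(0) = B and
# f'(1) = 2A + B are both non-negative exactly when mid is in [1/4, 3/4];
# requested mid values are clamped into that interval to keep the mapping
# monotone (slider semantics: clamp, don't reject).

MID_MIN <- 0.25
MID_MAX <- 0.75

clamp01 <- function(x) pmin(1, pmax(0, x))

#' Per-channel transfer parameters
#'
#' @param dark largest fully-transparent input level, in `[0, 1)`.
#' @param mid output at the midpoint input; clamped into `[0.25, 0.75]`
#'   (the interval in which the quadratic stays monotone).
#' @param bright smallest fully-opaque input level, in `(dark, 1]`.
#' @param alpha global channel opacity in `[0, 1]`.
#' @param color RGB triple in `[0, 1]`.
#' @param visible logical; invisible channels are skipped when compositing.
#' @return an object of class `vox_transfer`.
#' @export
channel_transfer <- function(dark = 0, mid = 0.5, bright = 1, alpha = 1,
                             color = c(1, 0, 0), visible = TRUE) {
  dark <- as.numeric(dark); bright <- as.numeric(bright)
  mid <- as.numeric(mid); alpha <- as.numeric(alpha)
  if (!is.finite(dark) || !is.finite(bright) || dark < 0 || bright > 1 ||
      dark >= bright)
    stop("require 0 <= dark < bright <= 1", call. = FALSE)
  if (!is.finite(mid) || mid < 0 || mid > 1)
    stop("mid must be in [0, 1]", call. = FALSE)
  if (!is.finite(alpha) || alpha < 0 || alpha > 1)
    stop("alpha must be in [0, 1]", call. = FALSE)
  color <- as.numeric(color)
  if (length(color) != 3L || any(!is.finite(color)) || any(color < 0) ||
      any(color > 1))
    stop("color must be an RGB triple in [0, 1]", call. = FALSE)
  structure(list(dark = dark, mid = min(MID_MAX, max(MID_MIN, mid)),
                 bright = bright, alpha = alpha, color = color,
                 visible = isTRUE(visible)),
            class = "vox_transfer")
}

#' @export
print.vox_transfer <- function(x, ...) {
  cat(sprintf("<vox_transfer> dark %.3g mid %.3g bright %.3g alpha %.3g color (%.2g, %.2g, %.2g)%s\n",
              x$dark, x$mid, x$bright, x$alpha, x$color[1], x$color[2],
              x$color[3], if (x$visible) "" else " (hidden)"))
  invisible(x)
}

#' Solve the quadratic transfer coefficients
#'
#' Returns the unique coefficients of `i_out = a i_in^2 + b i_in + c` that
#' interpolate the three constraints: 0 at `dark`, 1 at `bright`, and the
#' (clamped) `mid` output at the midpoint input `(dark + bright)/2`. With
#' `mid` in `[0.25, 0.75]` the quadratic is non-decreasing on
#' `[dark, bright]`; `mid = 0.5` gives `a = 0` exactly (a linear map).
#'
#' @param t a [channel_transfer()].
#' @return list with components `a`, `b`, `c`.
#' @export
solve_coefficients <- function(t) {
  stopifnot(inherits(t, "vox_transfer"))
  w <- t$bright - t$dark
  A <- 2 - 4 * t$mid
  B <- 4 * t$mid - 1
  d <- t$dark
  list(a = A / w^2,
       b = B / w - 2 * A * d / w^2,
       c = A * d^2 / w^2 - B * d / w)
}

#' Apply a channel transfer function
#'
#' Maps normalized voxel values to emissive intensity: 0 at or below `dark`,
#' 1 at or above `bright`, the monotone quadratic in between. Inputs outside
#' `[0, 1]` are clamped (dequantized codes are already normalized, so this is
#' a guard, not a code path).
#'
#' @param t a [channel_transfer()].
#' @param i_in numeric vector of normalized intensities.
#' @return emissive intensities in `[0, 1]`, same length as `i_in`.
#' @export
apply_transfer <- function(t, i_in) {
  stopifnot(inherits(t, "vox_transfer"))
  if (any(i_in < 0 | i_in > 1, na.rm = TRUE)) {
    warning("transfer input outside [0, 1]; clamping", call. = FALSE)
    i_in <- clamp01(i_in)
  }
  co <- solve_coefficients(t)
  out <- clamp01(co$a * i_in^2 + co$b * i_in + co$c)
  out[i_in <= t$dark] <- 0
  out[i_in >= t$bright] <- 1
  out
}

#' Curvature class of a transfer function
#'
#' @param t a [channel_transfer()].
#' @return `"concave_down"` (mid > 0.5), `"linear"` (mid = 0.5) or
#'   `"concave_up"` (mid < 0.5), i.e. the sign of the quadratic coefficient.
#' @export
concavity <- function(t) {
  a <- solve_coefficients(t)$a
  if (a < 0) "concave_down" else if (a > 0) "concave_up" else "linear"
}

# default channel colors: red, green, blue, magenta, yellow, cyan, cycled
default_channel_colors <- function(n) {
  base <- list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
               c(1, 0, 1), c(1, 1, 0), c(0, 1, 1))
  lapply(seq_len(n), function(i) base[[(i - 1L) %% 6L + 1L]])
}

#' Default transfer list for a channel count
#'
#' One identity-ish transfer per channel: `dark = 0`, `mid = 0.5` (linear),
#' `bright = 1`, `alpha = 1`, colors cycling red/green/blue/magenta/yellow/cyan.
#'
#' @param num_channels number of channels.
#' @return list of [channel_transfer()] objects.
#' @export
default_transfers <- function(num_channels) {
  cols <- default_channel_colors(num_channels)
  lapply(seq_len(num_channels), function(i)
    channel_transfer(color = cols[[i]]))
}
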