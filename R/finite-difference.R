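#' Finite-difference time derivatives
#'
#' Central differences in the interior with one-sided differences at the two
#' boundary frames, applied `order` times. This replaces the vendor's
#' proprietary derivative estimates with a documented, testable scheme; the
#' output has the same length as the input, and the first/last `order` frames
#' are boundary-estimated (first-order accurate) while interior frames are
#' second-order accurate.
#'
#' @param channel numeric vector or matrix (frames in rows).
#' @param order derivative order, 1, 2 or 3.
#' @param framerate sampling rate in Hz.
#' @return Same shape as `channel`, units divided by s^order.
#' @export
#' @examples
#' t <- seq(0, 1, by = 1 / 240)
#' v <- finite_difference(t, 1, 240)        # derivative of a ramp: all 1
finite_difference <- function(channel, order = 1, framerate) {
  stopifnot(order %in% 1:3, framerate > 0)
  x <- as.matrix(channel)
  n <- nrow(x)
  if (n < order + 1L)
    stop(sprintf("finite_difference of order %d needs at least %d frames, got %d",
                 order, order + 1L, n))
  h <- 1 / framerate
  d <- x * NA_real_
  sl <- function(i) x[i, , drop = FALSE]
  if (order == 1L) {
    if (n >= 3L) d[2:(n - 1L), ] <- (sl(3:n) - sl(1:(n - 2L))) / (2 * h)
    d[1L, ] <- (x[2L, ] - x[1L, ]) / h
    d[n, ] <- (x[n, ] - x[n - 1L, ]) / h
  } else if (order == 2L) {
    if (n >= 3L)
      d[2:(n - 1L), ] <- (sl(3:n) - 2 * sl(2:(n - 1L)) + sl(1:(n - 2L))) / h^2
    d[1L, ] <- (x[1L, ] - 2 * x[2L, ] + x[3L, ]) / h^2
    d[n, ] <- (x[n, ] - 2 * x[n - 1L, ] + x[n - 2L, ]) / h^2
  } else {
    # third derivative: wide central stencil in the interior, third
    # forward/backward differences (exact for cubics) at the edges
    if (n >= 5L)
      d[3:(n - 2L), ] <- (sl(5:n) - 2 * sl(4:(n - 1L)) +
                          2 * sl(2:(n - 3L)) - sl(1:(n - 4L))) / (2 * h^3)
    fwd <- function(i) {
      if (i + 4L <= n)   # second-order one-sided stencil
        (-2.5 * sl(i) + 9 * sl(i + 1L) - 12 * sl(i + 2L) + 7 * sl(i + 3L) -
           1.5 * sl(i + 4L)) / h^3
      else
        (sl(i + 3L) - 3 * sl(i + 2L) + 3 * sl(i + 1L) - sl(i)) / h^3
    }
    bwd <- function(i) {
      if (i - 4L >= 1L)
        (2.5 * sl(i) - 9 * sl(i - 1L) + 12 * sl(i - 2L) - 7 * sl(i - 3L) +
           1.5 * sl(i - 4L)) / h^3
      else
        (sl(i) - 3 * sl(i - 1L) + 3 * sl(i - 2L) - sl(i - 3L)) / h^3
    }
    for (i in 1:2) d[i, ] <- fwd(min(i, n - 3L))
    for (i in (n - 1L):n) d[i, ] <- bwd(max(i, 4L))
  }
  if (is.null(dim(channel))) drop(d) else d
}

# Unwrap Euler-angle columns: fold jumps larger than pi so differentiation
# across the +/- pi seam does not produce spurious spikes.
.unwrap_angles <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) return(x)
  d <- diff(x)
  corr <- -2 * pi * round(d / (2 * pi))
  x[-1L, ] <- x[-1L, ] + apply(corr, 2, cumsum)
  x
}
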