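# shared numeric helpers

# trapezoidal rule on an arbitrary grid; NA values are dropped pairwise
.trapz <- function(x, y) {
  keep <- !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 2L) return(0)
  sum(diff(x) * (y[-length(y)] + y[-1L]) / 2)
}

# median absolute deviation exactly as defined for the summary statistics:
# median of absolute deviations from the median, no consistency constant
.mad_plain <- function(x) {
  x <- x[!is.na(x)]
  stats::median(abs(stats::median(x) - x))
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
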