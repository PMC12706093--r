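# Internal geometry and sampling helpers. All coordinates are in nm with the
# x axis pointing right and the y axis pointing DOWN (image row direction);
# pixel (r, c) of an intensity matrix has its centre at ((c-1)*p, (r-1)*p).

#' Bilinear interpolation of an intensity grid at arbitrary nm positions
#'
#' @param img numeric matrix (rows = y, cols = x), intensities.
#' @param x,y numeric vectors of nm coordinates.
#' @param pixel_size_nm grid spacing in nm.
#' @return numeric vector of interpolated intensities; positions outside the
#'   grid are clamped to the border.
#' @keywords internal
sample_intensity <- function(img, x, y, pixel_size_nm) {
  nr <- nrow(img); nc <- ncol(img)
  cx <- x / pixel_size_nm + 1
  cy <- y / pixel_size_nm + 1
  cx <- pmin(pmax(cx, 1), nc)
  cy <- pmin(pmax(cy, 1), nr)
  x0 <- pmin(floor(cx), nc - 1L); x1 <- x0 + 1
  y0 <- pmin(floor(cy), nr - 1L); y1 <- y0 + 1
  fx <- cx - x0; fy <- cy - y0
  img[cbind(y0, x0)] * (1 - fx) * (1 - fy) +
    img[cbind(y0, x1)] * fx * (1 - fy) +
    img[cbind(y1, x0)] * (1 - fx) * fy +
    img[cbind(y1, x1)] * fx * fy
}

# Resample a polyline at approximately equal arc-length spacing `ds`.
resample_polyline <- function(xy, ds = 0.2) {
  x <- xy[, 1]; y <- xy[, 2]
  seg <- sqrt(diff(x)^2 + diff(y)^2)
  keep <- c(TRUE, seg > 1e-9)
  x <- x[keep]; y <- y[keep]
  seg <- seg[seg > 1e-9]
  s <- c(0, cumsum(seg))
  L <- s[length(s)]
  if (L < ds) return(cbind(x = x, y = y))
  si <- seq(0, L, by = ds)
  cbind(x = stats::approx(s, x, xout = si)$y,
        y = stats::approx(s, y, xout = si)$y)
}

# Points on a circular arc (y-down coordinates). Angles in radians measured
# from +x axis, increasing toward +y (clockwise on screen).
arc_points <- function(cx, cy, r, a0, a1, ds = 0.2) {
  n <- max(2L, ceiling(abs(a1 - a0) * r / ds))
  a <- seq(a0, a1, length.out = n)
  cbind(x = cx + r * cos(a), y = cy + r * sin(a))
}

# Width (horizontal extent) of a trace per y-bin. Returns tibble(y, width,
# xl, xr) for bins containing points on both sides of the bin median x.
trace_widths <- function(xy, bin_nm = 0.4) {
  y <- xy[, 2]; x <- xy[, 1]
  b <- round(y / bin_nm)
  sp <- split(seq_along(y), b)
  res <- lapply(sp, function(ii) {
    c(y = mean(y[ii]), xl = min(x[ii]), xr = max(x[ii]))
  })
  m <- do.call(rbind, res)
  tibble::tibble(y = m[, "y"], xl = m[, "xl"], xr = m[, "xr"],
                 width = m[, "xr"] - m[, "xl"])
}

# Linear interpolation of a boundary trace y(x); x must span the query range.
interp_trace_y <- function(trace, x) {
  stats::approx(trace[, 1], trace[, 2], xout = x, rule = 2)$y
}

# Truncated normal draw: redraw until within [lo, hi] (vectorised, seeded by
# the caller's RNG state).
rtruncnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  if (sd <= 0) return(rep(mean, n))
  out <- rnorm(n, mean, sd)
  bad <- which(out < lo | out > hi)
  k <- 0L
  while (length(bad) > 0 && k < 100L) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(out < lo | out > hi)
    k <- k + 1L
  }
  out[out < lo] <- lo; out[out > hi] <- hi
  out
}
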