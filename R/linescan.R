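#' Construct a line scan
#'
#' A line scan is a 1D sequence of grayscale intensities sampled along a
#' vertical or horizontal line of a membrane-profile image, used to decide
#' whether two membranes are continuous or separated by a cytosolic gap.
#' Membranes are rendered/recorded as intensity-HIGH; the gap between two
#' bilayers therefore reads as a local intensity minimum.
#'
#' @param values numeric vector of intensities (length >= 3).
#' @param pixel_size_nm spacing between consecutive samples, nm.
#' @param orientation "vertical" or "horizontal".
#' @param averaging_width_nm lateral averaging width used when the scan was
#'   extracted from an image (recorded for provenance; default 3 nm).
#' @return an object of class `line_scan`.
#' @export
line_scan <- function(values, pixel_size_nm,
                      orientation = c("vertical", "horizontal"),
                      averaging_width_nm = 3) {
  orientation <- match.arg(orientation)
  if (length(values) < 3) abort("line scan needs at least 3 samples")
  if (!is.numeric(pixel_size_nm) || pixel_size_nm <= 0)
    abort("pixel_size_nm must be > 0")
  structure(
    list(values = as.numeric(values), pixel_size_nm = pixel_size_nm,
         orientation = orientation, averaging_width_nm = averaging_width_nm),
    class = "line_scan")
}

#' Grayscale line-scan gap statistic
#'
#' Decides whether a line scan across the space between two membranes contains
#' a gap (missing membrane continuity). The scan mean \eqn{\mu} and standard
#' deviation \eqn{\sigma} are computed; contiguous runs of samples below
#' \eqn{\mu - \sigma} of physical length at least `min_run_nm` are located.
#' If a run exists, the deepest run's `window_nm`-averaged minimum region is
#' divided by the mean of the `window_nm`-averaged local maxima on either
#' side of it. If no qualifying run exists the ratio is defined as 1. A gap
#' is called when the ratio is strictly below `threshold`.
#'
#' @param scan a [line_scan()] object.
#' @param min_run_nm minimal run length in nm (default 1).
#' @param window_nm averaging window around the minimum and each flanking
#'   maximum, nm (default 1).
#' @param threshold gap decision threshold on the min/max ratio (default 0.6,
#'   strict inequality).
#' @return a `gap_result` list with elements `ratio`, `has_gap`, `run_start`,
#'   `run_end` (sample indices, `NA` if no run), `mu`, `sigma`.
#' @export
line_scan_gap_statistic <- function(scan, min_run_nm = 1, window_nm = 1,
                                    threshold = 0.6) {
  stopifnot(inherits(scan, "line_scan"))
  v <- scan$values
  p <- scan$pixel_size_nm
  w <- max(1L, round(window_nm / p))
  if (length(v) < w) abort("scan shorter than one averaging window")
  mu <- mean(v); sg <- sd(v)

  nrun <- max(1L, round(min_run_nm / p))
  below <- v < (mu - sg)
  runs <- rle(below)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values & runs$lengths >= nrun
  if (sg == 0 || !any(keep)) {
    return(structure(list(ratio = 1, has_gap = FALSE,
                          run_start = NA_integer_, run_end = NA_integer_,
                          mu = mu, sigma = sg), class = "gap_result"))
  }
  rs <- starts[keep]; re <- ends[keep]
  depth <- vapply(seq_along(rs), function(i) min(v[rs[i]:re[i]]), 0)
  k <- which.min(depth)
  a <- rs[k]; b <- re[k]
  # window-average centred on the deepest sample of the run; tied minima
  # (flat-bottomed dips) resolve to the middle of the tie
  seg <- v[a:b]
  ties <- which(seg == min(seg))
  m_idx <- (a:b)[ties[ceiling(length(ties) / 2)]]
  win_mean <- function(center) {
    lo <- max(1L, center - (w %/% 2))
    hi <- min(length(v), lo + w - 1L)
    lo <- max(1L, hi - w + 1L)
    mean(v[lo:hi])
  }
  min_region <- win_mean(m_idx)
  flank_max <- c(
    if (a > 1) win_mean(which.max(v[1:(a - 1L)])) else NA_real_,
    if (b < length(v)) win_mean(b + which.max(v[(b + 1L):length(v)])) else NA_real_
  )
  flank_max <- flank_max[!is.na(flank_max)]
  ratio <- if (length(flank_max) == 0) 1 else min_region / mean(flank_max)
  structure(list(ratio = ratio, has_gap = ratio < threshold,
                 run_start = a, run_end = b, mu = mu, sigma = sg),
            class = "gap_result")
}

# Extract a vertical line scan from a profile image, averaging horizontally
# over `averaging_width_nm`, sampled at half-pixel steps from y0 to y1.
extract_vscan <- function(img, pixel_size_nm, x, y0, y1,
                          averaging_width_nm = 3) {
  step <- pixel_size_nm / 2
  ys <- seq(min(y0, y1), max(y0, y1), by = step)
  xs <- seq(x - averaging_width_nm / 2, x + averaging_width_nm / 2,
            by = pixel_size_nm / 2)
  vals <- rowMeans(vapply(
    xs, function(xi) sample_intensity(img, rep(xi, length(ys)), ys,
                                      pixel_size_nm),
    numeric(length(ys))))
  line_scan(vals, step, "vertical", averaging_width_nm)
}

# Extract a horizontal line scan at height y from x0 to x1 (no averaging).
extract_hscan <- function(img, pixel_size_nm, y, x0, x1) {
  step <- pixel_size_nm / 2
  xs <- seq(min(x0, x1), max(x0, x1), by = step)
  vals <- sample_intensity(img, xs, rep(y, length(xs)), pixel_size_nm)
  line_scan(vals, step, "horizontal", 0)
}
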