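#' Morphometric measurements of one membrane-rearrangement profile
#'
#' Computes the morphometric record used to classify SV fusion intermediates
#' from an annotated membrane-profile image. Distances are measured between
#' leaflet-peak boundary traces; continuity of membranes is assessed with the
#' grayscale [line_scan_gap_statistic()] on scans extracted from the image.
#'
#' Measured quantities (NA where not applicable to the annotated topology):
#' * `a_nm` widest horizontal extent of the event between outer borders;
#' * `b_nm` height of the event top above the interpolated AZ baseline;
#' * `c_nm` gap between the SV outer leaflet and the AZ outer leaflet at the
#'   lowest SV point, with AZ in/evaginations interpolated (detached SVs
#'   only);
#' * `d_nm` height of the AZ invagination below the event;
#' * `e1_nm`, `e2_nm`, `droplet_ratio` circle-fit deviations at the SV top /
#'   bottom and their ratio ([droplet_test()]);
#' * `f_ratio` vertical line-scan gap ratio between the event inner leaflet
#'   and the AZ bottom leaflet (membrane continuity along the stalk axis);
#' * `g_nm` closed-neck height (event inner leaflet bottom to AZ bottom
#'   leaflet), defined when the neck scan shows no gap;
#' * `h_ratio` horizontal line-scan gap ratio across the pore neck at its
#'   narrowest position;
#' * `i_nm` open-pore width between inner leaflets at the narrowest neck;
#' * `j1_deg`, `outward_curvature` signed-turning analysis of the outer
#'   boundary along the neck (flared open pore vs straight/inward walls);
#' * `k1_nm`, `k2_nm`, `thickening_ratio` membrane thickness (FWHM of the
#'   intensity profile) at the event top and on the AZ next to the event.
#'
#' @param profile a `profile_image` (from [render_profile()] or
#'   [read_profile()]); must carry `az_outer` and `az_inner` boundary
#'   annotations, plus `event_outer`/`event_inner` when an event is present.
#' @param gap_threshold gap-ratio threshold used only to decide whether the
#'   closed-neck height `g_nm` is defined (default 0.6).
#' @return a one-row tibble of measurements.
#' @export
measure_event <- function(profile, gap_threshold = 0.6) {
  stopifnot(inherits(profile, "profile_image"))
  bnd <- profile$boundaries
  for (need in c("az_outer", "az_inner")) {
    if (is.null(bnd[[need]]))
      abort(paste0("missing boundary annotation: ", need))
  }
  img <- profile$intensity
  p <- profile$pixel_size_nm
  sep <- mean(bnd$az_inner[, 2]) - mean(bnd$az_outer[, 2])

  na_row <- tibble::tibble(
    a_nm = NA_real_, b_nm = NA_real_, c_nm = NA_real_, d_nm = NA_real_,
    e1_nm = NA_real_, e2_nm = NA_real_, droplet_ratio = NA_real_,
    f_ratio = NA_real_, g_nm = NA_real_, h_ratio = NA_real_,
    i_nm = NA_real_, j1_deg = NA_real_, outward_curvature = NA,
    k1_nm = NA_real_, k2_nm = NA_real_, thickening_ratio = NA_real_)
  if (is.null(bnd$event_outer)) return(na_row)
  if (is.null(bnd$event_inner))
    abort("missing boundary annotation: event_inner")

  outer <- bnd$event_outer
  inner <- bnd$event_inner
  closed <- isTRUE(attr(outer, "closed"))
  xr <- range(outer[, 1])
  xc_evt <- mean(xr)

  # AZ baseline across the event footprint, interpolated from the flanks
  az <- bnd$az_outer
  left <- az[az[, 1] < xr[1], , drop = FALSE]
  right <- az[az[, 1] > xr[2], , drop = FALSE]
  yl <- if (nrow(left)) left[which.max(left[, 1]), 2] else NA_real_
  yr <- if (nrow(right)) right[which.min(right[, 1]), 2] else NA_real_
  if (is.na(yl)) yl <- yr
  if (is.na(yr)) yr <- yl
  xl_anchor <- if (nrow(left)) max(left[, 1]) else xr[1]
  xr_anchor <- if (nrow(right)) min(right[, 1]) else xr[2]
  baseline <- function(x) {
    if (xr_anchor == xl_anchor) return(rep(yl, length(x)))
    yl + (yr - yl) * (x - xl_anchor) / (xr_anchor - xl_anchor)
  }

  infoot <- az[, 1] >= xr[1] & az[, 1] <= xr[2]
  d_nm <- if (any(infoot)) {
    max(c(0, baseline(az[infoot, 1]) - az[infoot, 2]))
  } else 0
  if (d_nm < 0.05) d_nm <- 0

  out <- na_row
  out$d_nm <- d_nm
  tw <- trace_widths(outer)
  out$a_nm <- max(tw$width)
  out$b_nm <- baseline(xc_evt) - min(outer[, 2])

  if (closed) {
    ibot <- which.max(outer[, 2])
    x_tip <- outer[ibot, 1]
    out$c_nm <- baseline(x_tip) - outer[ibot, 2]
    fit <- fit_outer_circle(outer)
    dr <- droplet_test(outer, fit)
    out$e1_nm <- dr$e1_nm; out$e2_nm <- dr$e2_nm
    out$droplet_ratio <- dr$droplet_ratio
    y_start <- max(inner[, 2])
    y_end <- baseline(x_tip) + sep
    fs <- extract_vscan(img, p, x_tip, y_start, y_end)
    out$f_ratio <- line_scan_gap_statistic(fs)$ratio
    return(out)
  }

  # --- open (membrane-continuous) protrusion ---------------------------
  y0b <- baseline(xc_evt)
  y_top <- min(outer[, 2])
  # topmost level at which the maximal width is attained
  ymw <- min(tw$y[tw$width >= out$a_nm - 0.3])
  band_lo <- ymw + 2
  band_hi <- y0b - 1
  if (band_lo >= band_hi) {
    band_lo <- ymw + 0.5; band_hi <- y0b - 0.5
  }
  # The neck scan is defined only where a neck exists: the outer-border
  # separation must drop clearly below the widest extent of the event.
  # Dilating/collapsing pores and bumps have straight or inward walls with
  # no width minimum, hence no closed-neck candidate (h undefined).
  band <- tw$y >= band_lo & tw$y <= band_hi
  if (any(band)) {
    wb <- tw[band, ]
    if (min(wb$width) <= 0.8 * out$a_nm) {
      k <- which(wb$width <= min(wb$width) + 0.2)
      k <- k[order(wb$y[k])][ceiling(length(k) / 2)]  # ties -> mid-neck
      y_star <- wb$y[k]
      hs <- extract_hscan(img, p, y_star, wb$xl[k], wb$xr[k])
      out$h_ratio <- line_scan_gap_statistic(hs)$ratio
    }
  }

  # vertical continuity scan along the event axis
  central <- abs(inner[, 1] - xc_evt) <= 2
  y_start <- if (any(central)) max(inner[central, 2]) else y_top + sep
  fs <- extract_vscan(img, p, xc_evt, y_start, y0b + sep)
  out$f_ratio <- line_scan_gap_statistic(fs)$ratio

  if (!is.na(out$h_ratio) && out$h_ratio >= gap_threshold) {
    out$g_nm <- (y0b + sep) - max(inner[, 2])
  } else {
    # open neck: pore width between inner leaflets at the narrowest point
    ti <- trace_widths(inner)
    bi <- ti$y >= band_lo & ti$y <= band_hi & ti$width > 1
    if (any(bi)) out$i_nm <- min(ti$width[bi])
  }

  curv <- neck_curvature(outer, band_lo, band_hi)
  out$outward_curvature <- curv$present
  out$j1_deg <- curv$j1_deg

  # membrane thickness at the event top vs the AZ next to the base
  near_top <- outer[, 2] < y_top + 0.5
  x_top <- mean(outer[near_top, 1])
  out$k1_nm <- measure_fwhm(img, p, x_top, y_top - 8, y_top + 12)
  W <- (ncol(img) - 1) * p
  x_ref <- if (xr[2] + 10 < W) xr[2] + 8 else xr[1] - 8
  out$k2_nm <- measure_fwhm(img, p, x_ref, y0b - 8, y0b + sep + 6)
  out$thickening_ratio <- out$k1_nm / out$k2_nm
  out
}

# Signed-turning analysis of the outer boundary within the neck band.
# The polyline is smoothed over ~3 nm, resampled at 1 nm, and the z component
# of the cross product of successive unit tangents (= sin of the turning
# angle) is evaluated; outward curvature is present when turns of both signs
# occur inside the band (a flared neck wrapping into a wider head), absent
# when the walls run straight or turn with a single sign.
neck_curvature <- function(outer, band_lo, band_hi, turn_min = 0.03) {
  xy <- resample_polyline(outer, ds = 1)
  n <- nrow(xy)
  if (n < 7) return(list(present = FALSE, j1_deg = NA_real_))
  w <- 3
  sm <- cbind(stats::filter(xy[, 1], rep(1 / w, w), sides = 2),
              stats::filter(xy[, 2], rep(1 / w, w), sides = 2))
  sm <- sm[complete.cases(sm), , drop = FALSE]
  t_ <- diff(sm)
  len <- sqrt(rowSums(t_^2))
  t_ <- t_ / len
  cz <- t_[-nrow(t_), 1] * t_[-1, 2] - t_[-nrow(t_), 2] * t_[-1, 1]
  ymid <- sm[2:(nrow(sm) - 1), 2]
  inband <- ymid >= band_lo & ymid <= band_hi
  cz <- cz[inband]
  if (length(cz) == 0) return(list(present = FALSE, j1_deg = NA_real_))
  pos <- cz > turn_min; neg <- cz < -turn_min
  present <- any(pos) && any(neg)
  j1 <- if (present) {
    # total convex turning within the band, in degrees
    s <- sum(abs(asin(pmax(pmin(cz[neg], 1), -1)))) * 180 / pi
    min(s + 90, 180)
  } else NA_real_
  list(present = present, j1_deg = j1)
}

# Apparent membrane thickness: full width at half maximum of the vertical
# intensity profile at x, between ylo and yhi (nm), averaged over 1 nm
# horizontally.
measure_fwhm <- function(img, p, x, ylo, yhi) {
  ys <- seq(ylo, yhi, by = 0.05)
  xs <- x + c(-0.5, 0, 0.5)
  vals <- rowMeans(vapply(
    xs, function(xi) sample_intensity(img, rep(xi, length(ys)), ys, p),
    numeric(length(ys))))
  thr <- (min(vals) + max(vals)) / 2
  above <- which(vals >= thr)
  if (length(above) < 2) return(NA_real_)
  ys[max(above)] - ys[min(above)]
}

#' Measure a collection of profiles
#'
#' @param profiles a list of `profile_image` objects (e.g. from
#'   [make_fixture_set()]).
#' @return tibble with one row per profile: an id, the truth label carried by
#'   the profile (NA if none), and all [measure_event()] columns.
#' @export
measure_events <- function(profiles) {
  rows <- lapply(seq_along(profiles), function(i) {
    pr <- profiles[[i]]
    m <- measure_event(pr)
    tibble::tibble(event_id = i,
                   truth = pr$truth_label %||% NA_character_) |>
      dplyr::bind_cols(m)
  })
  dplyr::bind_rows(rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
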