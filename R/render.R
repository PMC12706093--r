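# Rendering of synthetic membrane-profile images.
#
# Geometry conventions: nm coordinates, x right, y DOWN; the AZ membrane runs
# horizontally near the bottom of the image (outer/upper leaflet at the
# baseline y0), the presynaptic cytosol is above it. Each bilayer is drawn as
# two Gaussian ridges (the leaflet density peaks) separated by
# leaflet_peak_sep_nm; boundary annotations are the leaflet peak polylines.
# Merged, compacted membranes (the thickened tops of collapsing pores and
# bumps) are drawn as a single broad ridge whose apparent width is calibrated
# so that the measured thickness ratio equals the requested
# thickening_factor.

ridge_sigma <- function(spec) {
  (spec$bilayer_thickness_nm - spec$leaflet_peak_sep_nm) /
    (2 * sqrt(2 * log(2)))
}

az_baseline_y <- function(spec) {
  0.82 * (spec$image_shape[1] - 1) * spec$pixel_size_nm
}

# Max-splat a Gaussian ridge along a polyline onto the canvas.
splat_curve <- function(canvas, xy, sigma, amp, p) {
  nr <- nrow(canvas); nc <- ncol(canvas)
  xy <- resample_polyline(xy, ds = max(0.05, sigma / 3))
  rad <- ceiling(3 * sigma / p)
  for (i in seq_len(nrow(xy))) {
    ci <- round(xy[i, 1] / p) + 1
    ri <- round(xy[i, 2] / p) + 1
    rows <- max(1, ri - rad):min(nr, ri + rad)
    cols <- max(1, ci - rad):min(nc, ci + rad)
    if (length(rows) == 0 || length(cols) == 0) next
    dy <- ((rows - 1) * p - xy[i, 2])
    dx <- ((cols - 1) * p - xy[i, 1])
    g <- amp * exp(-(outer(dy^2, dx^2, "+")) / (2 * sigma^2))
    canvas[rows, cols] <- pmax(canvas[rows, cols], g)
  }
  canvas
}

# --- geometry builders ------------------------------------------------------
# Each returns list(boundaries, curves, az_mask_halfwidth) where boundaries
# is a named list of annotation polylines (matrices with columns x, y and a
# "closed" attribute) and curves is a list of list(xy, sigma, amp) to render.

closed_trace <- function(xy) { attr(xy, "closed") <- TRUE; xy }
open_trace <- function(xy) { attr(xy, "closed") <- FALSE; xy }

build_az_traces <- function(spec, dimple_d = 0, dimple_x = NULL,
                            dimple_w = 6) {
  W <- (spec$image_shape[2] - 1) * spec$pixel_size_nm
  y0 <- az_baseline_y(spec)
  x <- seq(0, W, by = 0.2)
  y <- rep(y0, length(x))
  if (dimple_d > 0) {
    y <- y0 - dimple_d * exp(-(x - dimple_x)^2 / (2 * dimple_w^2))
  }
  sep <- spec$leaflet_peak_sep_nm
  list(az_outer = open_trace(cbind(x = x, y = y)),
       az_inner = open_trace(cbind(x = x, y = y + sep)))
}

# closed SV / droplet geometry (states 1, 2, tethered_sv)
build_sv_geometry <- function(spec) {
  xc <- (spec$image_shape[2] - 1) * spec$pixel_size_nm / 2
  y0 <- az_baseline_y(spec)
  sep <- spec$leaflet_peak_sep_nm
  R <- spec$sv_outer_diameter_nm / 2
  cc <- spec$gap_c_nm
  d <- spec$invagination_d_nm
  e1 <- if (!is.null(spec$droplet_e1_nm)) spec$droplet_e1_nm else 0
  e2 <- if (!is.null(spec$droplet_e2_nm)) spec$droplet_e2_nm else 0

  th <- seq(0, 2 * pi, length.out = 721)[-721]
  sig_th <- 0.35
  angdiff <- function(a, b) {
    d <- (a - b) %% (2 * pi); pmin(d, 2 * pi - d)
  }
  mk_boundary <- function(a1, a2) {
    r <- R +
      a2 * exp(-(angdiff(th, pi / 2))^2 / (2 * sig_th^2)) +
      a1 * exp(-(angdiff(th, 3 * pi / 2))^2 / (2 * sig_th^2))
    cbind(x = r * cos(th), y = r * sin(th))
  }
  # calibrate rendered bump amplitudes so that the measured circle-fit
  # deviations at top/bottom reproduce the requested e1/e2
  a1 <- e1; a2 <- e2
  if (e1 > 0 || e2 > 0) {
    for (it in 1:6) {
      b <- mk_boundary(a1, a2)
      fit <- fit_outer_circle(b)
      dr <- droplet_test(b, fit)
      a1 <- max(0, a1 + (e1 - dr$e1_nm))
      a2 <- max(0, a2 + (e2 - dr$e2_nm))
    }
  }
  b <- mk_boundary(a1, a2)
  cy <- y0 - cc - max(b[, 2])          # bottom tip sits at y0 - c
  outer <- cbind(x = b[, 1] + xc, y = b[, 2] + cy)
  rin <- sqrt(b[, 1]^2 + b[, 2]^2) - sep
  thh <- atan2(b[, 2], b[, 1])
  inner <- cbind(x = xc + rin * cos(thh), y = cy + rin * sin(thh))

  az <- build_az_traces(spec, dimple_d = d, dimple_x = xc)
  sig <- ridge_sigma(spec)
  amp <- spec$membrane_intensity - spec$background_intensity
  list(
    boundaries = list(event_outer = closed_trace(outer),
                      event_inner = closed_trace(inner),
                      az_outer = az$az_outer, az_inner = az$az_inner),
    curves = list(
      list(xy = rbind(outer, outer[1, ]), sigma = sig, amp = amp),
      list(xy = rbind(inner, inner[1, ]), sigma = sig, amp = amp),
      list(xy = az$az_outer, sigma = sig, amp = amp),
      list(xy = az$az_inner, sigma = sig, amp = amp)),
    az_mask_halfwidth = 0)
}

# state 3: SV-sized head continuous with the AZ through a solid closed neck
build_closed_pore_geometry <- function(spec) {
  xc <- (spec$image_shape[2] - 1) * spec$pixel_size_nm / 2
  y0 <- az_baseline_y(spec)
  sep <- spec$leaflet_peak_sep_nm
  Rh <- spec$event_width_a_nm / 2
  g <- spec$neck_height_g_nm
  wn <- sep            # neck outer half-width: two bilayers in contact
  yh <- y0 + 2 * sep - Rh - g          # head centre; inner bottom at y0+sep-g
  yj <- yh + sqrt(Rh^2 - wn^2)

  al <- atan2(yj - yh, -wn)            # left junction angle, in (pi/2, pi)
  ar <- atan2(yj - yh, wn)             # right junction angle, in (0, pi/2)
  head_arc <- arc_points(xc, yh, Rh, al, 2 * pi + ar)
  outer <- rbind(cbind(x = xc - wn, y = seq(y0, yj, by = -0.2)),
                 head_arc,
                 cbind(x = xc + wn, y = seq(yj, y0, by = 0.2)))
  th <- seq(0, 2 * pi, length.out = 541)[-541]
  inner <- cbind(x = xc + (Rh - sep) * cos(th), y = yh + (Rh - sep) * sin(th))

  az <- build_az_traces(spec)
  sig <- ridge_sigma(spec)
  amp <- spec$membrane_intensity - spec$background_intensity
  fill <- lapply(seq(-wn + 0.3, wn - 0.3, by = 0.45), function(dx) {
    ytop <- yh + sqrt(max((Rh - sep)^2 - dx^2, 0)) - 0.3
    list(xy = cbind(x = c(xc + dx, xc + dx), y = c(ytop, y0 + sep)),
         sigma = sig, amp = amp)
  })
  list(
    boundaries = list(event_outer = open_trace(outer),
                      event_inner = closed_trace(inner),
                      az_outer = az$az_outer, az_inner = az$az_inner),
    curves = c(list(
      list(xy = outer, sigma = sig, amp = amp),
      list(xy = rbind(inner, inner[1, ]), sigma = sig, amp = amp),
      list(xy = az$az_outer, sigma = sig, amp = amp),
      list(xy = az$az_inner, sigma = sig, amp = amp)),
      fill),
    az_mask_halfwidth = 0)
}

# state 4: head on an open neck; walls flare outward into the head
build_open_pore_geometry <- function(spec) {
  xc <- (spec$image_shape[2] - 1) * spec$pixel_size_nm / 2
  y0 <- az_baseline_y(spec)
  sep <- spec$leaflet_peak_sep_nm
  Rh <- spec$event_width_a_nm / 2
  b <- spec$event_height_b_nm
  wi <- spec$pore_width_i_nm / 2
  wo <- wi + sep
  yh <- y0 - b + Rh
  yj <- yh + sqrt(Rh^2 - wo^2)
  al <- atan2(yj - yh, -wo); ar <- atan2(yj - yh, wo)
  outer <- rbind(cbind(x = xc - wo, y = seq(y0, yj, by = -0.2)),
                 arc_points(xc, yh, Rh, al, 2 * pi + ar),
                 cbind(x = xc + wo, y = seq(yj, y0, by = 0.2)))
  Ri <- Rh - sep
  yji <- yh + sqrt(Ri^2 - wi^2)
  ali <- atan2(yji - yh, -wi); ari <- atan2(yji - yh, wi)
  inner <- rbind(cbind(x = xc - wi, y = seq(y0, yji, by = -0.2)),
                 arc_points(xc, yh, Ri, ali, 2 * pi + ari),
                 cbind(x = xc + wi, y = seq(yji, y0, by = 0.2)))

  az <- build_az_traces(spec)
  sig <- ridge_sigma(spec)
  amp <- spec$membrane_intensity - spec$background_intensity
  list(
    boundaries = list(event_outer = open_trace(outer),
                      event_inner = open_trace(inner),
                      az_outer = az$az_outer, az_inner = az$az_inner),
    curves = list(
      list(xy = outer, sigma = sig, amp = amp),
      list(xy = inner, sigma = sig, amp = amp),
      list(xy = az$az_outer, sigma = sig, amp = amp),
      list(xy = az$az_inner, sigma = sig, amp = amp)),
    az_mask_halfwidth = wo)
}

# dome outline for states 5-7: vertical walls, rounded top corners
dome_outline <- function(xc, y0, a, b, rc) {
  rc <- min(rc, a / 2 - 0.5, b - 0.5)
  rbind(
    cbind(x = xc - a / 2, y = seq(y0, y0 - b + rc, by = -0.2)),
    arc_points(xc - a / 2 + rc, y0 - b + rc, rc, pi, 3 * pi / 2),
    cbind(x = seq(xc - a / 2 + rc, xc + a / 2 - rc, by = 0.2), y = y0 - b),
    arc_points(xc + a / 2 - rc, y0 - b + rc, rc, 3 * pi / 2, 2 * pi),
    cbind(x = xc + a / 2, y = seq(y0 - b + rc, y0, by = 0.2)))
}

# states 5 (bilayer top), 6 and 7 (merged thickened top)
build_dome_geometry <- function(spec) {
  xc <- (spec$image_shape[2] - 1) * spec$pixel_size_nm / 2
  y0 <- az_baseline_y(spec)
  sep <- spec$leaflet_peak_sep_nm
  a <- spec$event_width_a_nm
  b <- spec$event_height_b_nm
  thick <- spec$thickening_factor
  rc <- 3
  sig <- ridge_sigma(spec)
  amp <- spec$membrane_intensity - spec$background_intensity
  p <- spec$pixel_size_nm

  outer <- dome_outline(xc, y0, a, b, rc)
  az <- build_az_traces(spec)
  merged_top <- thick > 1.15
  curves <- list(list(xy = az$az_outer, sigma = sig, amp = amp),
                 list(xy = az$az_inner, sigma = sig, amp = amp))
  if (!merged_top) {
    inner <- dome_outline(xc, y0, a - 2 * sep, b - sep,
                          max(rc - sep, 0.5))
    curves <- c(curves, list(
      list(xy = outer, sigma = sig, amp = amp),
      list(xy = inner, sigma = sig, amp = amp)))
  } else {
    # walls as bilayer; top as one merged broad ridge calibrated so the
    # measured thickness ratio vs the AZ bilayer equals thickening_factor
    sig_top <- calibrate_merged_sigma(spec, y_top = y0 - b)
    rcx <- min(rc, a / 2 - 0.5, b - 0.5)
    wallL_o <- cbind(x = xc - a / 2, y = seq(y0, y0 - b + rcx, by = -0.2))
    wallR_o <- cbind(x = xc + a / 2, y = seq(y0 - b + rcx, y0, by = 0.2))
    wallL_i <- cbind(x = xc - a / 2 + sep, y = seq(y0, y0 - b + rcx + sep,
                                                   by = -0.2))
    wallR_i <- cbind(x = xc + a / 2 - sep, y = seq(y0 - b + rcx + sep, y0,
                                                   by = 0.2))
    top <- rbind(arc_points(xc - a / 2 + rcx, y0 - b + rcx, rcx,
                            pi, 3 * pi / 2),
                 cbind(x = seq(xc - a / 2 + rcx, xc + a / 2 - rcx, by = 0.2),
                       y = y0 - b),
                 arc_points(xc + a / 2 - rcx, y0 - b + rcx, rcx,
                            3 * pi / 2, 2 * pi))
    inner <- dome_outline(xc, y0, a - 2 * sep, b - sep, max(rc - sep, 0.5))
    curves <- c(curves, list(
      list(xy = wallL_o, sigma = sig, amp = amp),
      list(xy = wallR_o, sigma = sig, amp = amp),
      list(xy = wallL_i, sigma = sig, amp = amp),
      list(xy = wallR_i, sigma = sig, amp = amp),
      list(xy = top, sigma = sig_top, amp = amp)))
  }
  list(
    boundaries = list(event_outer = open_trace(outer),
                      event_inner = open_trace(
                        dome_outline(xc, y0, a - 2 * sep,
                                     max(b - sep * thick, 1),
                                     max(rc - sep, 0.5))),
                      az_outer = az$az_outer, az_inner = az$az_inner),
    curves = curves,
    az_mask_halfwidth = a / 2)
}

# Solve for the sigma of a single merged ridge such that its measured FWHM
# (half-pixel bilinear sampling, as in measure_event) equals
# thickening_factor times the measured FWHM of the normal AZ bilayer.
calibrate_merged_sigma <- function(spec, y_top) {
  p <- spec$pixel_size_nm
  sep <- spec$leaflet_peak_sep_nm
  sig <- ridge_sigma(spec)
  y0 <- az_baseline_y(spec)

  sim_fwhm <- function(centers, sigmas) {
    lo <- min(centers) - 10; hi <- max(centers) + 10
    jlo <- floor(lo / p); jhi <- ceiling(hi / p)
    yp <- (jlo:jhi) * p
    vals <- rep(0, length(yp))
    for (k in seq_along(centers))
      vals <- pmax(vals, exp(-(yp - centers[k])^2 / (2 * sigmas[k]^2)))
    yf <- seq(min(yp), max(yp), by = 0.05)
    vf <- stats::approx(yp, vals, xout = yf)$y
    thr <- (min(vf) + max(vf)) / 2
    above <- which(vf >= thr)
    yf[max(above)] - yf[min(above)]
  }
  target <- spec$thickening_factor * sim_fwhm(c(y0, y0 + sep), c(sig, sig))
  f <- function(s) sim_fwhm(y_top, s) - target
  stats::uniroot(f, c(0.4, 8), tol = 1e-4)$root
}

build_geometry <- function(spec) {
  switch(spec$state_label,
    "1" = , "2" = , tethered_sv = build_sv_geometry(spec),
    "3" = build_closed_pore_geometry(spec),
    "4" = build_open_pore_geometry(spec),
    "5" = , "6" = , "7" = build_dome_geometry(spec),
    none = {
      az <- build_az_traces(spec)
      sig <- ridge_sigma(spec)
      amp <- spec$membrane_intensity - spec$background_intensity
      list(boundaries = list(az_outer = az$az_outer,
                             az_inner = az$az_inner),
           curves = list(list(xy = az$az_outer, sigma = sig, amp = amp),
                         list(xy = az$az_inner, sigma = sig, amp = amp)),
           az_mask_halfwidth = 0)
    })
}

#' Render a synthetic membrane-profile image
#'
#' Draws the membranes described by a [profile_spec()] as bright Gaussian
#' ridges (one per leaflet density peak) on a dark background, adds Gaussian
#' noise, and returns the image together with its ground-truth boundary
#' annotations. Rendering is deterministic given the spec (the seed drives
#' only the noise field).
#'
#' @param spec a [profile_spec()].
#' @return a `profile_image`: list with `intensity` (matrix, rows = y),
#'   `pixel_size_nm`, `boundaries` (named list of polyline matrices with a
#'   `closed` attribute), `truth_label`, and the generating `spec`.
#' @export
render_profile <- function(spec) {
  stopifnot(inherits(spec, "profile_spec"))
  geo <- build_geometry(spec)
  H <- spec$image_shape[1]; W <- spec$image_shape[2]
  p <- spec$pixel_size_nm
  canvas <- matrix(0, H, W)
  xc <- (W - 1) * p / 2
  for (cv in geo$curves) {
    xy <- cv$xy
    if (geo$az_mask_halfwidth > 0 && .is_az_curve(cv, spec)) {
      keep <- abs(xy[, 1] - xc) > geo$az_mask_halfwidth
      if (!any(keep)) next
      # split into contiguous kept pieces to avoid bridging the gap
      r <- rle(keep); idx <- cumsum(r$lengths)
      start <- c(1, head(idx, -1) + 1)
      for (k in which(r$values)) {
        piece <- xy[start[k]:idx[k], , drop = FALSE]
        if (nrow(piece) > 1)
          canvas <- splat_curve(canvas, piece, cv$sigma, cv$amp, p)
      }
      next
    }
    canvas <- splat_curve(canvas, xy, cv$sigma, cv$amp, p)
  }
  img <- spec$background_intensity + canvas
  if (spec$noise_sigma > 0) {
    set.seed(spec$seed)
    img <- img + matrix(rnorm(H * W, 0, spec$noise_sigma), H, W)
    img[img < 0] <- 0
  }
  structure(list(intensity = img, pixel_size_nm = p,
                 boundaries = geo$boundaries,
                 truth_label = spec$state_label, spec = spec),
            class = "profile_image")
}

.is_az_curve <- function(cv, spec) {
  W <- (spec$image_shape[2] - 1) * spec$pixel_size_nm
  xr <- range(cv$xy[, 1])
  xr[1] < 1 && xr[2] > W - 1
}

#' @export
print.profile_image <- function(x, ...) {
  cat("<profile_image>", nrow(x$intensity), "x", ncol(x$intensity),
      "px,", format(x$pixel_size_nm), "nm/px, truth =", x$truth_label, "\n")
  invisible(x)
}
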