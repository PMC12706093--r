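#' Least-squares circle fit to boundary points
#'
#' Fits a circle to the outer border of a synaptic vesicle by minimising the
#' sum of squared radial residuals \eqn{\sum_i (|p_i - c| - r)^2} (geometric
#' fit, Gauss-Newton refinement of the algebraic Kasa estimate).
#'
#' @param points two-column matrix or data frame of (x, y) positions in nm,
#'   at least 3 non-collinear points.
#' @return a `circle_fit` list with `center` (x, y), `radius_nm`,
#'   `rms_residual_nm`.
#' @export
fit_outer_circle <- function(points) {
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  storage.mode(pts) <- "double"
  if (nrow(pts) < 3) abort("circle fit needs at least 3 points")
  x <- pts[, 1]; y <- pts[, 2]
  # collinearity check via covariance rank
  sv <- svd(cbind(x - mean(x), y - mean(y)))$d
  if (sv[2] < 1e-9 * max(sv[1], 1)) abort("points are collinear")

  # Kasa algebraic fit: x^2+y^2 = 2a x + 2b y + c
  A <- cbind(2 * x, 2 * y, 1)
  z <- x^2 + y^2
  ab <- qr.solve(A, z)
  cx <- ab[1]; cy <- ab[2]
  r <- sqrt(ab[3] + cx^2 + cy^2)

  # Gauss-Newton on (cx, cy, r)
  for (it in 1:50) {
    dx <- x - cx; dy <- y - cy
    di <- sqrt(dx^2 + dy^2)
    ri <- di - r
    J <- cbind(-dx / di, -dy / di, -1)
    step <- tryCatch(qr.solve(J, -ri), error = function(e) rep(0, 3))
    cx <- cx + step[1]; cy <- cy + step[2]; r <- r + step[3]
    if (sqrt(sum(step^2)) < 1e-12) break
  }
  dx <- x - cx; dy <- y - cy
  res <- sqrt(dx^2 + dy^2) - r
  structure(list(center = c(x = cx, y = cy), radius_nm = r,
                 rms_residual_nm = sqrt(mean(res^2))),
            class = "circle_fit")
}

#' Droplet-shape test for a synaptic vesicle boundary
#'
#' Measures the absolute radial deviation of the boundary from its fitted
#' circle at the topmost (e1) and bottommost (e2) boundary points. A vesicle
#' is droplet-shaped (evagination toward the active zone, stalk candidate)
#' when e2/e1 strictly exceeds `threshold`. To keep the ratio defined for
#' near-perfect spheres, e1 is floored at `e1_floor_nm`; deviations below the
#' floor can never make a droplet.
#'
#' @param boundary two-column matrix of boundary points (x, y) nm; y is the
#'   image-down axis, so the bottommost point has the largest y.
#' @param fit a [fit_outer_circle()] result for this boundary.
#' @param threshold droplet decision threshold (default 1.3, strict).
#' @param e1_floor_nm denominator floor in nm (default 0.25).
#' @return list with `e1_nm`, `e2_nm`, `droplet_ratio`, `is_droplet`.
#' @export
droplet_test <- function(boundary, fit, threshold = 1.3, e1_floor_nm = 0.25) {
  stopifnot(inherits(fit, "circle_fit"))
  b <- as.matrix(boundary)[, 1:2, drop = FALSE]
  itop <- which.min(b[, 2]); ibot <- which.max(b[, 2])
  dev_at <- function(i) {
    abs(sqrt(sum((b[i, ] - fit$center)^2)) - fit$radius_nm)
  }
  e1 <- dev_at(itop); e2 <- dev_at(ibot)
  ratio <- e2 / max(e1, e1_floor_nm)
  list(e1_nm = e1, e2_nm = e2, droplet_ratio = ratio,
       is_droplet = ratio > threshold)
}
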