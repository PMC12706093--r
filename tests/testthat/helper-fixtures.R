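# Shared, lazily built fixtures (rendered once per test run).

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.fixture_cache[[name]]))
    .fixture_cache[[name]] <- force(expr)
  .fixture_cache[[name]]
}

# the stimulated-sample event census: per-category counts printed for the
# seven membrane-rearrangement states
event_census_counts <- c(10L, 22L, 6L, 7L, 8L, 12L, 21L)

fixture_set_clean <- function() {
  cached("clean", make_fixture_set(event_census_counts, seed = 1))
}

fixture_measured_clean <- function() {
  cached("clean_measured", measure_events(fixture_set_clean()))
}

fixture_classified_clean <- function() {
  cached("clean_classified", classify_events(fixture_measured_clean()))
}

fixture_classified_noisy <- function() {
  cached("noisy_classified", {
    fs <- make_fixture_set(event_census_counts,
                           geometry_defaults = list(noise_sigma = 12),
                           seed = 7)
    classify_events(measure_events(fs))
  })
}

# docking runs for the copy-number comparison (5 seeds per arm, reduced
# preset, stopped at the curvature trigger)
docking_runs <- function() {
  cached("docking", {
    out <- list()
    for (cp in c(0L, 30L)) {
      runs <- lapply(3:7, function(sd) {
        run_docking(sim_config(reduced_preset = TRUE, seed = sd,
                               curvature_protein_copies = cp),
                    stop_at_trigger = TRUE)
      })
      out[[as.character(cp)]] <- runs
    }
    out
  })
}

# independent direct-arithmetic evaluation of the line-scan gap statistic
oracle_gap_statistic <- function(values, pixel_nm, min_run_nm = 1,
                                 window_nm = 1, threshold = 0.6) {
  mu <- mean(values); s <- sd(values)
  w <- max(1L, round(window_nm / pixel_nm))
  nrun <- max(1L, round(min_run_nm / pixel_nm))
  below <- values < mu - s
  # locate contiguous runs by explicit scanning
  runs <- list(); start <- NA
  for (i in seq_along(below)) {
    if (below[i] && is.na(start)) start <- i
    if ((!below[i] || i == length(below)) && !is.na(start)) {
      end <- if (below[i]) i else i - 1L
      if (end - start + 1L >= nrun) runs[[length(runs) + 1L]] <- c(start, end)
      start <- NA
    }
  }
  if (s == 0 || length(runs) == 0)
    return(list(ratio = 1, has_gap = FALSE, run = NULL))
  depths <- vapply(runs, function(r) min(values[r[1]:r[2]]), 0)
  r <- runs[[which.min(depths)]]
  seg <- values[r[1]:r[2]]
  tie <- which(seg == min(seg))
  m_idx <- (r[1]:r[2])[tie[ceiling(length(tie) / 2)]]
  avg_at <- function(center) {
    lo <- max(1L, center - (w %/% 2)); hi <- min(length(values), lo + w - 1L)
    lo <- max(1L, hi - w + 1L)
    mean(values[lo:hi])
  }
  flanks <- c()
  if (r[1] > 1) flanks <- c(flanks, avg_at(which.max(values[1:(r[1] - 1)])))
  if (r[2] < length(values))
    flanks <- c(flanks, avg_at(r[2] + which.max(values[(r[2] + 1):length(values)])))
  ratio <- if (length(flanks) == 0) 1 else avg_at(m_idx) / mean(flanks)
  list(ratio = ratio, has_gap = ratio < threshold, run = r)
}

# brute-force grid-search circle fit (independent oracle)
oracle_circle_gridsearch <- function(pts, levels = 6) {
  x <- pts[, 1]; y <- pts[, 2]
  obj <- function(cx, cy, r) sum((sqrt((x - cx)^2 + (y - cy)^2) - r)^2)
  cx <- mean(x); cy <- mean(y)
  r <- mean(sqrt((x - cx)^2 + (y - cy)^2))
  span <- max(diff(range(x)), diff(range(y))) / 4
  for (lev in seq_len(levels)) {
    grid <- expand.grid(cx = cx + seq(-span, span, length.out = 13),
                        cy = cy + seq(-span, span, length.out = 13),
                        r = r + seq(-span, span, length.out = 13))
    vals <- mapply(obj, grid$cx, grid$cy, grid$r)
    k <- which.min(vals)
    cx <- grid$cx[k]; cy <- grid$cy[k]; r <- grid$r[k]
    span <- span / 5
  }
  list(center = c(cx, cy), radius = r)
}
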