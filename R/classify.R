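#' Classifier thresholds
#'
#' Decision thresholds of the fusion-state cascade. Inequalities are strict
#' where noted in the individual criteria: droplet when e2/e1 > 1.3, gap
#' when the line-scan ratio < 0.6, thickened when k1/k2 > 1.3, collapsing
#' pore when height b > 10 nm. The state-1 criteria (invagination of at
#' least `invagination_min_nm` below a round SV within the
#' `state1_distance_band_nm` distance band) use closed intervals.
#'
#' @param droplet_ratio,gap_ratio,thickening_ratio,bump_height_nm,
#'   invagination_min_nm,state1_distance_band_nm threshold overrides.
#' @return a `classifier_thresholds` list.
#' @export
classifier_thresholds <- function(droplet_ratio = 1.3,
                                  gap_ratio = 0.6,
                                  thickening_ratio = 1.3,
                                  bump_height_nm = 10,
                                  invagination_min_nm = 1.2,
                                  state1_distance_band_nm = c(4, 8)) {
  th <- list(droplet_ratio = droplet_ratio, gap_ratio = gap_ratio,
             thickening_ratio = thickening_ratio,
             bump_height_nm = bump_height_nm,
             invagination_min_nm = invagination_min_nm,
             state1_distance_band_nm = state1_distance_band_nm)
  num <- unlist(th[1:5])
  if (any(num <= 0)) abort("all thresholds must be > 0")
  structure(th, class = "classifier_thresholds")
}

#' Exclusion flags for a candidate fusion event
#'
#' Events are excluded from all analyses when they are not located at an
#' active zone with a recognisable postsynaptic density, when a halo
#' resembling a clathrin coat surrounds the pore, or when the tomogram
#' resolution is poor.
#'
#' @param at_active_zone event lies at an AZ with recognisable PSD.
#' @param clathrin_halo a clathrin-coat-like halo is visible.
#' @param resolution_ok tomogram resolution sufficient.
#' @return a named logical list.
#' @export
exclusion_flags <- function(at_active_zone = TRUE, clathrin_halo = FALSE,
                            resolution_ok = TRUE) {
  list(at_active_zone = isTRUE(at_active_zone),
       clathrin_halo = isTRUE(clathrin_halo),
       resolution_ok = isTRUE(resolution_ok))
}

#' Classify one morphometric record into a fusion state
#'
#' Implements the morphometric decision cascade over states 1-7:
#' detached SVs (gap `c_nm` defined) are droplets (stalk formation, state 2)
#' when the circle-deviation ratio exceeds the droplet threshold, state 1
#' when round with a clear AZ invagination within the 4-8 nm distance band,
#' and tethered SVs otherwise. Membrane-continuous protrusions are closed
#' fusion pores (state 3) when both the axial continuity scan and the neck
#' scan show no gap; open necks with outward curvature are open pores
#' (state 4); without outward curvature they are dilating pores (state 5)
#' unless the top membrane is thickened, in which case height discriminates
#' collapsing pores (state 6, b > 10 nm) from bumps (state 7).
#'
#' @param m one-row data frame (or named list) of [measure_event()] fields.
#' @param flags an [exclusion_flags()] list.
#' @param th a [classifier_thresholds()] list.
#' @return a single character state: `"1"`..`"7"`, `"tethered_sv"`, or
#'   `"excluded"`.
#' @export
classify_event <- function(m, flags = exclusion_flags(),
                           th = classifier_thresholds()) {
  g <- function(f) {
    v <- m[[f]]
    if (is.null(v) || length(v) == 0) NA else v[[1]]
  }
  if (!flags$at_active_zone || flags$clathrin_halo || !flags$resolution_ok)
    return("excluded")
  c_nm <- g("c_nm")
  h_ratio <- g("h_ratio")
  if (!is.na(c_nm) && !is.na(h_ratio))
    abort("contradictory record: both c_nm (detached SV) and h_ratio (pore neck) defined")
  if (!is.na(c_nm)) {
    dr <- g("droplet_ratio")
    if (!is.na(dr) && dr > th$droplet_ratio) return("2")
    d_nm <- g("d_nm")
    band <- th$state1_distance_band_nm
    if (!is.na(d_nm) && d_nm >= th$invagination_min_nm &&
        c_nm >= band[1] && c_nm <= band[2]) return("1")
    return("tethered_sv")
  }
  f_ratio <- g("f_ratio")
  if (!is.na(h_ratio) && h_ratio >= th$gap_ratio &&
      !is.na(f_ratio) && f_ratio >= th$gap_ratio) return("3")
  if (isTRUE(g("outward_curvature"))) return("4")
  tr <- g("thickening_ratio")
  if (is.na(tr) || tr <= th$thickening_ratio) return("5")
  b <- g("b_nm")
  if (!is.na(b) && b > th$bump_height_nm) return("6")
  "7"
}

#' Classify a table of morphometric records
#'
#' @param m tibble of [measure_events()] rows.
#' @param flags optional tibble with logical columns `at_active_zone`,
#'   `clathrin_halo`, `resolution_ok` (one row per event); defaults to no
#'   exclusions.
#' @param th a [classifier_thresholds()] list.
#' @return the input tibble with a `state` column appended.
#' @export
classify_events <- function(m, flags = NULL, th = classifier_thresholds()) {
  states <- vapply(seq_len(nrow(m)), function(i) {
    fl <- if (is.null(flags)) exclusion_flags() else
      exclusion_flags(flags$at_active_zone[i], flags$clathrin_halo[i],
                      flags$resolution_ok[i])
    classify_event(m[i, ], fl, th)
  }, character(1))
  dplyr::mutate(m, state = states)
}

#' Overall state of a synapse with several events
#'
#' When a synapse contains more than one membrane rearrangement, its overall
#' state is the event closest to the open fusion pore (state 4, taken as the
#' centre of the sequence); ties are broken toward the higher state index,
#' i.e. the more advanced event.
#'
#' @param event_states vector of states (`1`..`7`, numeric or character);
#'   non-numeric labels (tethered/excluded) are ignored.
#' @return integer synapse state in 1..7.
#' @export
assign_synapse_state <- function(event_states) {
  s <- suppressWarnings(as.integer(as.character(event_states)))
  s <- s[!is.na(s) & s >= 1 & s <= 7]
  if (length(s) == 0) abort("no classified events in 1..7")
  d <- abs(s - 4)
  cand <- s[d == min(d)]
  max(cand)
}

#' Synapse group from its event states
#'
#' A synapse counts as "ongoing fusion" when at least one stalk formation,
#' closed, open, dilating or collapsing fusion pore (states 2-6) is present;
#' otherwise as "bumps" when a bump (state 7) is present; otherwise "none".
#'
#' @param event_states vector of states (possibly empty).
#' @return one of `"ongoing_fusion"`, `"bumps"`, `"none"`.
#' @export
group_synapse <- function(event_states) {
  s <- suppressWarnings(as.integer(as.character(event_states)))
  s <- s[!is.na(s)]
  if (any(s >= 2 & s <= 6)) return("ongoing_fusion")
  if (any(s == 7)) return("bumps")
  "none"
}
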