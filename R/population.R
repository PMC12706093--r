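#' Specification of a synthetic synapse population
#'
#' Describes per-group synapse counts and compositions, the distribution of
#' membrane-near SV distances, the linear tether-count trend, interconnector
#' probabilities per fusion state, and the nearest-neighbor distance model,
#' from which [sample_population()] draws per-synapse tables. The defaults
#' emulate the composition of the optogenetically stimulated and TTX-treated
#' samples: 75 stimulated synapses of which 39 show ongoing fusion, 11 only
#' bumps and 25 no membrane rearrangements; 28 TTX synapses composed 3/5/20;
#' fusion-state probabilities proportional to (22, 6, 7, 8, 12) for states
#' 2-6; about a quarter of fusing synapses with multivesicular release.
#'
#' @param groups tibble with columns `group`, `n_synapses`, `n_ongoing`,
#'   `n_bumps` (the remainder has no rearrangements).
#' @param state_probs probabilities of states 2-6 for fusion events.
#' @param mvr_fraction fraction of ongoing-fusion synapses with >= 2 events.
#' @param multi_bump_fraction fraction of bump synapses with >= 2 bumps.
#' @param n_state1 number of state-1 (AZ invagination) events, distributed
#'   over stimulated synapses.
#' @param mean_sv_per_synapse Poisson mean of membrane-near SVs (<= 24 nm).
#' @param distance_weights relative weights of the 12 2-nm distance bins on
#'   0-24 nm (distances drawn uniformly within the bin).
#' @param tether_intercept,tether_slope,tether_sd linear tether model:
#'   counts are Gaussian around intercept + slope * distance, rounded and
#'   floored at 0.
#' @param interconnector_prob named vector, probability that an event of a
#'   given state carries a filamentous interconnector to a neighboring SV.
#' @param nn_interconnected_nm,nn_not_interconnected_nm c(mean, sd) of the
#'   nearest-neighbor distance for events with/without interconnector.
#' @param box_nm lateral extent of the AZ region used for coordinates.
#' @param seed RNG seed.
#' @return a `population_spec` list.
#' @export
population_spec <- function(
    groups = tibble::tibble(
      group = c("stimulated", "ttx"),
      n_synapses = c(75L, 28L),
      n_ongoing = c(39L, 3L),
      n_bumps = c(11L, 5L)),
    state_probs = c("2" = 22, "3" = 6, "4" = 7, "5" = 8, "6" = 12) / 55,
    mvr_fraction = 9 / 39,
    multi_bump_fraction = 6 / 11,
    n_state1 = 10L,
    mean_sv_per_synapse = 9.5,
    distance_weights = c(1.2, 1.6, 2.0, 1.4, 1.1, 1, 1, 1, 1, 1, 1, 1),
    tether_intercept = 5,
    tether_slope = -0.1,
    tether_sd = 0.8,
    interconnector_prob = c("2" = 0.8, "3" = 0.7, "4" = 0.6,
                            "5" = 0.5, "6" = 0.3),
    nn_interconnected_nm = c(25, 6),
    nn_not_interconnected_nm = c(45, 10),
    box_nm = 300,
    seed = 1L) {
  if (any(state_probs < 0) || abs(sum(state_probs) - 1) > 1e-9)
    abort("state_probs must be a probability vector over states 2-6")
  if (any(interconnector_prob < 0 | interconnector_prob > 1))
    abort("interconnector probabilities must lie in [0, 1]")
  if (any(groups$n_ongoing + groups$n_bumps > groups$n_synapses))
    abort("group composition exceeds n_synapses")
  if (any(distance_weights < 0)) abort("distance weights must be >= 0")
  structure(as.list(environment()), class = "population_spec")
}

#' Sample per-synapse SV and event tables from a population spec
#'
#' Draws the SV/event records of every synapse: group compositions are
#' reproduced exactly (counts, not sampled); event states, SV distances,
#' tether counts, interconnector flags and nearest-neighbor distances are
#' drawn from the models in the spec. Deterministic given the spec seed.
#'
#' Coordinates are uniform over the AZ box with `z_nm` the height above the
#' AZ plane equal to the drawn SV distance; the `nn_distance_nm` column of
#' event rows is drawn from the stratum model (interconnected vs not),
#' emulating the measured nearest-neighbor readout.
#'
#' @param pop a [population_spec()].
#' @return tibble with columns `synapse_id`, `object_id`, `kind` (sv/event),
#'   `state`, `distance_nm`, `tether_count`, `x_nm`, `y_nm`, `z_nm`,
#'   `interconnected`, `nn_distance_nm`, plus `group`.
#' @export
sample_population <- function(pop) {
  stopifnot(inherits(pop, "population_spec"))
  set.seed(pop$seed)
  edges <- seq(0, 24, by = 2)
  wt <- pop$distance_weights / sum(pop$distance_weights)

  draw_distance <- function(n) {
    bin <- sample.int(12, n, replace = TRUE, prob = wt)
    stats::runif(n, edges[bin], edges[bin + 1])
  }
  draw_tethers <- function(d) {
    mu <- pop$tether_intercept + pop$tether_slope * d
    pmax(0, round(mu + if (pop$tether_sd > 0)
      rnorm(length(d), 0, pop$tether_sd) else 0))
  }

  rows <- list()
  for (gi in seq_len(nrow(pop$groups))) {
    g <- pop$groups[gi, ]
    if (g$n_synapses == 0) next
    syn_type <- c(rep("ongoing", g$n_ongoing), rep("bumps", g$n_bumps),
                  rep("none", g$n_synapses - g$n_ongoing - g$n_bumps))
    n_mvr <- round(pop$mvr_fraction * g$n_ongoing)
    is_mvr <- rep(FALSE, g$n_ongoing)
    if (n_mvr > 0) is_mvr[sample.int(g$n_ongoing, n_mvr)] <- TRUE
    state1_syn <- if (g$group == "stimulated" && pop$n_state1 > 0)
      sample.int(g$n_synapses, min(pop$n_state1, g$n_synapses)) else integer(0)

    oi <- 0L
    for (si in seq_len(g$n_synapses)) {
      sid <- paste0(g$group, "_", si)
      n_sv <- stats::rpois(1, pop$mean_sv_per_synapse)
      syn_rows <- list()
      if (n_sv > 0) {
        d <- draw_distance(n_sv)
        syn_rows$sv <- tibble::tibble(
          synapse_id = sid, object_id = paste0(sid, "_sv", seq_len(n_sv)),
          kind = "sv", state = NA_character_, distance_nm = d,
          tether_count = draw_tethers(d),
          x_nm = stats::runif(n_sv, 0, pop$box_nm),
          y_nm = stats::runif(n_sv, 0, pop$box_nm),
          z_nm = d, interconnected = NA, nn_distance_nm = NA_real_)
      }
      ev_states <- character(0)
      if (syn_type[si] == "ongoing") {
        k <- which(si == which(syn_type == "ongoing"))
        n_ev <- if (is_mvr[si]) 2L + stats::rpois(1, 0.5) else 1L
        ev_states <- sample(names(pop$state_probs), n_ev, replace = TRUE,
                            prob = pop$state_probs)
      } else if (syn_type[si] == "bumps") {
        n_b <- if (stats::runif(1) < pop$multi_bump_fraction)
          2L + stats::rpois(1, 0.3) else 1L
        ev_states <- rep("7", n_b)
      }
      if (si %in% state1_syn) ev_states <- c(ev_states, "1")
      if (length(ev_states) > 0) {
        ic <- unname(vapply(ev_states, function(s) {
          pr <- pop$interconnector_prob[s]
          if (is.na(pr)) pr <- 0
          stats::runif(1) < pr
        }, logical(1)))
        nn <- ifelse(ic,
          rtruncnorm(length(ic), pop$nn_interconnected_nm[1],
                     pop$nn_interconnected_nm[2], lo = 5),
          rtruncnorm(length(ic), pop$nn_not_interconnected_nm[1],
                     pop$nn_not_interconnected_nm[2], lo = 5))
        ev_d <- ifelse(ev_states == "1", stats::runif(length(ic), 4, 8), 0)
        syn_rows$ev <- tibble::tibble(
          synapse_id = sid,
          object_id = paste0(sid, "_ev", seq_along(ev_states)),
          kind = "event", state = ev_states, distance_nm = ev_d,
          tether_count = ifelse(ev_states == "1", draw_tethers(ev_d),
                                NA_integer_),
          x_nm = stats::runif(length(ic), 0, pop$box_nm),
          y_nm = stats::runif(length(ic), 0, pop$box_nm),
          z_nm = ev_d, interconnected = ic, nn_distance_nm = nn)
      }
      if (length(syn_rows) > 0) {
        out <- dplyr::bind_rows(syn_rows)
        out$group <- g$group
        rows[[length(rows) + 1L]] <- out
      }
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(
      synapse_id = character(0), object_id = character(0),
      kind = character(0), state = character(0), distance_nm = numeric(0),
      tether_count = integer(0), x_nm = numeric(0), y_nm = numeric(0),
      z_nm = numeric(0), interconnected = logical(0),
      nn_distance_nm = numeric(0), group = character(0)))
  }
  dplyr::bind_rows(rows)
}
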