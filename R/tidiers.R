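#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted Markov state model
#'
#' @param x an `msm_fit` from [fit_rates()].
#' @param ... unused.
#' @return tibble with one row per transition rate: `edge`, `from`, `to`,
#'   `rate_per_ms`, `fixed` (whether the rate was held at a convention).
#' @export
tidy.msm_fit <- function(x, ...) {
  edges <- names(x$rates)
  ft <- do.call(rbind, strsplit(edges, "->", fixed = TRUE))
  tibble::tibble(edge = edges, from = ft[, 1], to = ft[, 2],
                 rate_per_ms = unname(x$rates),
                 fixed = !edges %in% x$free_edges) |>
    dplyr::arrange(.data$from, .data$to)
}

#' @rdname tidy.msm_fit
#' @export
glance.msm_fit <- function(x, ...) {
  dwell <- mean_dwell_times(x)
  tibble::tibble(
    logLik = x$logLik,
    n_events = sum(x$counts),
    n_states = length(x$model$states),
    variant = x$model$variant,
    T_ms = x$model$T_ms,
    convergence = x$convergence,
    longest_dwell_state = dwell$state[which.max(dwell$dwell_ms)],
    mfpt_1F_ms = mean_waiting_time(x$model, "1", "F"))
}

#' Mean dwell times of the transient states of a fitted chain
#'
#' The mean dwell (residence) time of a state is the inverse of its total
#' exit rate.
#'
#' @param x an `msm_fit` or `chain_model`.
#' @return tibble with `state`, `exit_rate_per_ms`, `dwell_ms`.
#' @export
mean_dwell_times <- function(x) {
  model <- if (inherits(x, "msm_fit")) x$model else x
  states <- setdiff(model$states, "F")
  exit <- -diag(model$Q)[states]
  tibble::tibble(state = states, exit_rate_per_ms = unname(exit),
                 dwell_ms = ifelse(exit > 0, 1 / unname(exit), Inf))
}

#' Tidy a census
#'
#' @param x a `census` from [census_tables()].
#' @param ... unused.
#' @return long tibble with `table` ("groups"/"state_fractions"/"release"),
#'   `category`, `n`, `fraction`.
#' @export
tidy.census <- function(x, ...) {
  dplyr::bind_rows(
    x$groups |>
      dplyr::transmute(table = "groups", category = .data$group,
                       n = .data$n, fraction = .data$fraction),
    x$state_fractions |>
      dplyr::transmute(table = "state_fractions", category = .data$state,
                       n = .data$n, fraction = .data$fraction),
    tibble::tibble(table = "release", category = c("uvr", "mvr"),
                   n = c(x$release$uvr, x$release$mvr),
                   fraction = c(x$release$uvr, x$release$mvr) /
                     max(1, x$release$uvr + x$release$mvr)))
}

#' @rdname tidy.census
#' @export
glance.census <- function(x, ...) {
  tibble::tibble(n_synapses = nrow(x$synapse_states),
                 n_events_26 = x$n_events_26,
                 frac_ongoing = x$groups$fraction[
                   x$groups$group == "ongoing_fusion"],
                 frac_mvr = x$release$mvr /
                   max(1, x$release$mvr + x$release$uvr))
}
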