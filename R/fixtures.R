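#' Generate a labelled set of synthetic fusion-state profiles
#'
#' Renders `counts_per_state[s]` membrane-profile images for each fusion
#' state s = 1..7, with the geometry of each profile drawn from truncated
#' normal distributions around the state's default means (means from the
#' measured state geometries; the SD of each drawn field is the per-state
#' standard error of the corresponding measurement, truncated at 2 SD so
#' individual draws stay within their state's morphometric definition).
#' Deterministic given the seed.
#'
#' @param counts_per_state integer vector of length 7 (profiles per state).
#' @param geometry_defaults named list of [profile_spec()] field overrides
#'   applied to every profile (e.g. `list(noise_sigma = 12)`).
#' @param seed RNG seed.
#' @return a `profile_set`: list of `profile_image`s with an `index`
#'   attribute tibble (profile id, state label, drawn geometry).
#' @export
make_fixture_set <- function(counts_per_state, geometry_defaults = list(),
                             seed = 1L) {
  counts_per_state <- as.integer(counts_per_state)
  if (length(counts_per_state) != 7 || any(is.na(counts_per_state)))
    abort("counts_per_state must be 7 integers")
  if (any(counts_per_state < 0)) abort("counts must be >= 0")

  sds <- list(
    "1" = c(gap_c_nm = 0.4, invagination_d_nm = 0.3),
    "2" = c(gap_c_nm = 0.3, droplet_e2_nm = 0.3, droplet_e1_nm = 0.1),
    "3" = c(event_width_a_nm = 1.0, neck_height_g_nm = 1.0),
    "4" = c(event_width_a_nm = 1.5, event_height_b_nm = 1.5,
            pore_width_i_nm = 1.5),
    "5" = c(event_width_a_nm = 1.1, event_height_b_nm = 2.6),
    "6" = c(event_width_a_nm = 2.3, event_height_b_nm = 2.1,
            thickening_factor = 0.05),
    "7" = c(event_width_a_nm = 2.0, event_height_b_nm = 0.4,
            thickening_factor = 0.05))

  set.seed(seed)
  defaults <- .state_geometry_defaults()
  profiles <- list()
  idx <- list()
  for (s in as.character(1:7)) {
    n <- counts_per_state[as.integer(s)]
    if (n == 0) next
    sd_s <- sds[[s]]
    for (k in seq_len(n)) {
      geom <- defaults[[s]]
      for (f in names(sd_s)) {
        geom[[f]] <- rtruncnorm(1, geom[[f]], sd_s[[f]],
                                lo = geom[[f]] - 2 * sd_s[[f]],
                                hi = geom[[f]] + 2 * sd_s[[f]])
      }
      args <- c(list(state_label = s), geom, geometry_defaults,
                list(seed = sample.int(.Machine$integer.max, 1)))
      args <- args[!duplicated(names(args))]
      spec <- do.call(profile_spec, args)
      pr <- render_profile(spec)
      profiles[[length(profiles) + 1L]] <- pr
      idx[[length(idx) + 1L]] <-
        tibble::tibble(profile_id = length(profiles), state = s,
                       !!!geom[lengths(geom) == 1])
    }
  }
  attr(profiles, "index") <- dplyr::bind_rows(idx)
  class(profiles) <- c("profile_set", "list")
  profiles
}

#' @export
print.profile_set <- function(x, ...) {
  states <- vapply(x, function(p) p$truth_label, character(1))
  cat("<profile_set>", length(x), "profiles:",
      paste(names(table(states)), as.integer(table(states)),
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}
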