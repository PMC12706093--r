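#' Pool configuration for SV distance binning
#'
#' Membrane-near SVs are pooled by their distance to the AZ membrane:
#' membrane-proximal up to 6 nm, intermediate 6-12 nm, distal 12-24 nm,
#' with 2-nm histogram bins. Pools are half-open with the upper edge
#' included, so a distance of exactly 6 nm counts as proximal.
#'
#' @param proximal_max_nm,intermediate_max_nm,distal_max_nm pool edges.
#' @param bin_nm histogram bin width; must divide `distal_max_nm`.
#' @return a `pool_config` list.
#' @export
pool_config <- function(proximal_max_nm = 6, intermediate_max_nm = 12,
                        distal_max_nm = 24, bin_nm = 2) {
  if (!(0 < proximal_max_nm && proximal_max_nm < intermediate_max_nm &&
        intermediate_max_nm < distal_max_nm))
    abort("pool edges must satisfy 0 < proximal < intermediate < distal")
  if (abs(distal_max_nm / bin_nm - round(distal_max_nm / bin_nm)) > 1e-9)
    abort("bin_nm must divide distal_max_nm")
  structure(list(proximal_max_nm = proximal_max_nm,
                 intermediate_max_nm = intermediate_max_nm,
                 distal_max_nm = distal_max_nm, bin_nm = bin_nm),
            class = "pool_config")
}

#' Bin SV distances into pools and a 2-nm histogram
#'
#' @param distances numeric vector of SV-to-AZ distances (nm, >= 0).
#' @param cfg a [pool_config()].
#' @return list with `pools` (named counts proximal/intermediate/distal),
#'   `histogram` (tibble bin_lo, bin_hi, count), `n_dropped` (distances
#'   beyond the distal edge, reported and excluded).
#' @export
bin_sv_distances <- function(distances, cfg = pool_config()) {
  if (any(is.na(distances))) abort("distances must not contain NA")
  if (any(distances < 0)) abort("negative distance")
  n_drop <- sum(distances > cfg$distal_max_nm)
  if (n_drop > 0)
    inform(paste0(n_drop, " distances beyond ", cfg$distal_max_nm,
                  " nm dropped"))
  d <- distances[distances <= cfg$distal_max_nm]
  pools <- c(
    proximal = sum(d <= cfg$proximal_max_nm),
    intermediate = sum(d > cfg$proximal_max_nm &
                       d <= cfg$intermediate_max_nm),
    distal = sum(d > cfg$intermediate_max_nm))
  edges <- seq(0, cfg$distal_max_nm, by = cfg$bin_nm)
  counts <- vapply(seq_len(length(edges) - 1), function(i) {
    if (i == 1) sum(d >= edges[i] & d <= edges[i + 1])
    else sum(d > edges[i] & d <= edges[i + 1])
  }, integer(1))
  list(pools = pools,
       histogram = tibble::tibble(bin_lo = edges[-length(edges)],
                                  bin_hi = edges[-1], count = counts),
       n_dropped = n_drop)
}

#' Census of synapse groups, event-state fractions and UVR/MVR
#'
#' Aggregates classified events to the population statistics: per-synapse
#' groups (ongoing fusion / bumps / none via [group_synapse()]), fractions
#' of individual fusion states among all ongoing-fusion events (states 2-6),
#' and uni- vs multivesicular release (MVR: at least two events in states
#' 2-6 at one synapse). Excluded events never enter any count.
#'
#' @param events tibble with columns `synapse_id` and `state` (one row per
#'   classified event; states as characters `"1"`..`"7"`, `"tethered_sv"`,
#'   `"excluded"`).
#' @param synapse_ids optional vector of all synapse ids in the sample,
#'   including synapses without any event (these count toward group "none").
#' @return a `census` list with tibbles `groups` (group, n, fraction),
#'   `synapse_states` (synapse_id, group, synapse_state), `state_fractions`
#'   (state, n, fraction among states 2-6), and `release` (UVR/MVR counts).
#' @export
census_tables <- function(events, synapse_ids = NULL) {
  ev <- dplyr::filter(events, .data$state != "excluded")
  ids <- union(unique(ev$synapse_id), synapse_ids)

  per_syn <- lapply(ids, function(sid) {
    st <- ev$state[ev$synapse_id == sid]
    grp <- group_synapse(st)
    sstate <- if (any(st %in% as.character(1:7)))
      assign_synapse_state(st) else NA_integer_
    n26 <- sum(st %in% as.character(2:6))
    tibble::tibble(synapse_id = sid, group = grp, synapse_state = sstate,
                   n_fusion_events = n26)
  })
  syn <- dplyr::bind_rows(per_syn)

  groups <- tibble::tibble(group = c("ongoing_fusion", "bumps", "none")) |>
    dplyr::left_join(dplyr::count(syn, .data$group), by = "group") |>
    dplyr::mutate(n = ifelse(is.na(.data$n), 0L, .data$n),
                  fraction = if (nrow(syn) > 0) .data$n / nrow(syn) else 0)

  ev26 <- ev$state[ev$state %in% as.character(2:6)]
  state_fractions <- tibble::tibble(state = as.character(2:6)) |>
    dplyr::left_join(
      tibble::tibble(state = ev26) |> dplyr::count(.data$state),
      by = "state") |>
    dplyr::mutate(n = ifelse(is.na(.data$n), 0L, .data$n),
                  fraction = if (length(ev26) > 0) .data$n / length(ev26)
                             else 0)

  fusing <- syn[syn$group == "ongoing_fusion", ]
  release <- tibble::tibble(
    uvr = sum(fusing$n_fusion_events == 1),
    mvr = sum(fusing$n_fusion_events >= 2))

  structure(list(groups = groups, synapse_states = syn,
                 state_fractions = state_fractions, release = release,
                 n_events_26 = length(ev26)),
            class = "census")
}

#' @export
print.census <- function(x, ...) {
  cat("<census>", nrow(x$synapse_states), "synapses,", x$n_events_26,
      "fusion events (states 2-6)\n")
  print(x$groups)
  print(x$state_fractions)
  invisible(x)
}

#' Nearest-neighbor distances among SVs and fusion events
#'
#' For every fusion event and membrane-proximal SV, the minimal 3D Euclidean
#' distance to any other SV of the same synapse is computed (self excluded).
#' Synapses with a single object have no defined neighbor distance (NA,
#' reported). Results are stratified by the interconnector flag.
#'
#' @param objects tibble with columns `synapse_id`, `object_id`, `kind`
#'   ("sv"/"event"), `distance_nm` (to the AZ), `x_nm`, `y_nm`, `z_nm` and
#'   optionally `interconnected`.
#' @param proximal_max_nm distance cut for membrane-proximal SVs (default 6).
#' @return list of tibbles: `per_object` (nn_distance_nm per event/proximal
#'   SV), `per_synapse` (mean nn distance per synapse and kind), `strata`
#'   (summary by interconnected flag for events).
#' @export
nearest_neighbor_analysis <- function(objects, proximal_max_nm = 6) {
  need <- c("synapse_id", "object_id", "kind", "x_nm", "y_nm", "z_nm")
  miss <- setdiff(need, names(objects))
  if (length(miss)) abort(paste0("missing columns: ",
                                 paste(miss, collapse = ", ")))
  res <- objects |>
    dplyr::group_by(.data$synapse_id) |>
    dplyr::group_modify(function(df, key) {
      svs <- df[df$kind == "sv", ]
      target <- df$kind == "event" |
        (df$kind == "sv" & df$distance_nm <= proximal_max_nm)
      nn <- rep(NA_real_, nrow(df))
      for (i in which(target)) {
        others <- svs[svs$object_id != df$object_id[i], ]
        if (nrow(others) == 0) next
        nn[i] <- min(sqrt((others$x_nm - df$x_nm[i])^2 +
                          (others$y_nm - df$y_nm[i])^2 +
                          (others$z_nm - df$z_nm[i])^2))
      }
      df$nn_distance_nm <- nn
      df[target, , drop = FALSE]
    }) |>
    dplyr::ungroup()
  n_undef <- sum(is.na(res$nn_distance_nm))
  if (n_undef > 0)
    inform(paste0(n_undef, " singleton objects without neighbor"))
  per_synapse <- res |>
    dplyr::filter(!is.na(.data$nn_distance_nm)) |>
    dplyr::group_by(.data$synapse_id, .data$kind) |>
    dplyr::summarise(mean_nn_nm = mean(.data$nn_distance_nm),
                     n = dplyr::n(), .groups = "drop")
  strata <- NULL
  if ("interconnected" %in% names(res)) {
    strata <- res |>
      dplyr::filter(.data$kind == "event",
                    !is.na(.data$nn_distance_nm)) |>
      dplyr::group_by(.data$interconnected) |>
      dplyr::summarise(mean_nn_nm = mean(.data$nn_distance_nm),
                       median_nn_nm = median(.data$nn_distance_nm),
                       n = dplyr::n(), .groups = "drop")
  }
  list(per_object = res, per_synapse = per_synapse, strata = strata)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of p values (delegates to
#' [stats::p.adjust()] with `method = "BH"`).
#'
#' @param p_values numeric vector in \[0, 1\].
#' @return adjusted q values, same order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    abort("p values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Theoretical fraction of non-releasing synapses
#'
#' Two-component mixture decomposition of the mean membrane-proximal SV
#' count: synapses without membrane rearrangements are modelled as a mixture
#' of postfusion synapses (proximal SV count as in synapses with ongoing
#' fusion, mean `mu_fusion`) and non-releasing synapses (as in TTX-treated
#' synapses, mean `mu_ttx`). The observed mean `mu_none` then implies a
#' non-releasing fraction (mu_none - mu_fusion) / (mu_ttx - mu_fusion),
#' clipped to \[0, 1\].
#'
#' @param mu_none mean proximal SV count in stimulated synapses without
#'   membrane rearrangements.
#' @param mu_fusion mean in stimulated synapses with ongoing fusion.
#' @param mu_ttx mean in TTX-treated synapses.
#' @return fraction in \[0, 1\].
#' @export
estimate_nonreleasing_fraction <- function(mu_none, mu_fusion, mu_ttx) {
  if (isTRUE(all.equal(mu_ttx, mu_fusion)))
    abort("mu_ttx must differ from mu_fusion (mixture not identifiable)")
  f <- (mu_none - mu_fusion) / (mu_ttx - mu_fusion)
  min(max(f, 0), 1)
}

#' Linear tether-count vs distance trend
#'
#' Ordinary least-squares fit of tether counts against SV-AZ distance, with
#' the Pearson correlation. When the tether counts have zero variance the
#' slope is 0 and the correlation is reported as 0 (convention, noted).
#'
#' @param tether_counts,distances numeric vectors (>= 3 points).
#' @return tibble with slope, intercept, r, n.
#' @export
fit_tether_distance_line <- function(tether_counts, distances) {
  if (length(tether_counts) != length(distances))
    abort("lengths differ")
  if (length(distances) < 3) abort("need at least 3 points")
  if (sd(distances) == 0) abort("zero variance in distances")
  fit <- lm(tether_counts ~ distances)
  r <- if (sd(tether_counts) == 0) {
    inform("zero variance in tether counts; r reported as 0")
    0
  } else cor(distances, tether_counts)
  tibble::tibble(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r = r, n = length(distances))
}

#' Fraction of pixels above an intensity threshold
#'
#' Minimal helper mirroring the fluorescence readout of stimulation:
#' the fraction of values strictly above a threshold, after subtracting a
#' background cutoff (values at or below it are ignored entirely when
#' `background` is given).
#'
#' @param intensities numeric vector or matrix of pixel intensities.
#' @param threshold high-intensity cutoff (strict).
#' @param background optional background level; pixels <= background are
#'   removed from the denominator.
#' @return fraction in \[0, 1\].
#' @export
fraction_above_threshold <- function(intensities, threshold,
                                     background = NULL) {
  v <- as.numeric(intensities)
  if (!is.null(background)) v <- v[v > background]
  if (length(v) == 0) return(0)
  mean(v > threshold)
}

#' Group-comparison convenience wrapper
#'
#' Normality-gated two-group or k-group comparison following the standard
#' policy: Shapiro-Wilk on each group; if all groups are compatible with
#' normality (p > 0.05) use a two-tailed unpaired t test (two groups),
#' otherwise Mann-Whitney (two groups) or Kruskal-Wallis (more). Thin
#' wrapper over the base tests, provided for convenience.
#'
#' @param values numeric vector.
#' @param groups grouping factor.
#' @return tibble with method, statistic, p_value.
#' @export
compare_groups <- function(values, groups) {
  groups <- as.factor(groups)
  k <- nlevels(groups)
  if (k < 2) abort("need at least two groups")
  normal <- all(vapply(split(values, groups), function(v) {
    if (length(v) < 3 || sd(v) == 0) return(FALSE)
    stats::shapiro.test(v)$p.value > 0.05
  }, logical(1)))
  if (k == 2) {
    if (normal) {
      tt <- stats::t.test(values ~ groups)
      tibble::tibble(method = "t", statistic = unname(tt$statistic),
                     p_value = tt$p.value)
    } else {
      wt <- stats::wilcox.test(values ~ groups, exact = FALSE)
      tibble::tibble(method = "mann_whitney",
                     statistic = unname(wt$statistic), p_value = wt$p.value)
    }
  } else {
    kw <- stats::kruskal.test(values, groups)
    tibble::tibble(method = "kruskal_wallis",
                   statistic = unname(kw$statistic), p_value = kw$p.value)
  }
}
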