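half_px <- 1.228 / 2

test_that("noise-free rendering round-trips the generating geometry", {
  m1 <- measure_event(render_profile(profile_spec("1", seed = 1)))
  expect_lt(abs(m1$c_nm - 6.4), half_px)
  expect_lt(abs(m1$d_nm - 2.6), half_px)
  expect_lt(abs(m1$a_nm - 42.5), half_px)

  m2 <- measure_event(render_profile(profile_spec("2", seed = 1)))
  expect_lt(abs(m2$c_nm - 4), half_px)
  expect_lt(abs(m2$e2_nm - 3), half_px)
  expect_lt(abs(m2$e1_nm - 0.7), half_px)
  expect_gt(m2$droplet_ratio, 1.3)

  m3 <- measure_event(render_profile(profile_spec("3", seed = 1)))
  expect_lt(abs(m3$g_nm - 10), half_px)
  expect_gte(m3$f_ratio, 0.6)
  expect_gte(m3$h_ratio, 0.6)

  m4 <- measure_event(render_profile(profile_spec("4", seed = 1)))
  expect_lt(abs(m4$i_nm - 8), half_px)
  expect_lt(abs(m4$a_nm - 30), half_px)
  expect_lt(abs(m4$b_nm - 35), half_px)
  expect_lt(m4$h_ratio, 0.6)
  expect_true(m4$outward_curvature)

  m5 <- measure_event(render_profile(profile_spec("5", seed = 1)))
  expect_lt(abs(m5$b_nm - 48.4), half_px)
  expect_lt(abs(m5$a_nm - 37.4), half_px)
  expect_false(m5$outward_curvature)

  m7 <- measure_event(render_profile(profile_spec("7", seed = 1)))
  expect_lt(abs(m7$b_nm - 7.7), half_px)
})

test_that("requested top-membrane thickening is rendered and measured", {
  m6 <- measure_event(render_profile(profile_spec("6", seed = 1)))
  expect_lt(abs(m6$thickening_ratio - 1.5), 0.05)
  expect_lt(abs(m6$b_nm - 29.6), half_px)
  expect_lt(abs(m6$a_nm - 50.4), half_px)
  # unthickened dilating pore stays near 1
  m5 <- measure_event(render_profile(profile_spec("5", seed = 1)))
  expect_lt(abs(m5$thickening_ratio - 1), 0.1)
})

test_that("degenerate flat-membrane profile renders only the AZ bilayer", {
  pr <- render_profile(profile_spec("none", noise_sigma = 0))
  m <- measure_event(pr)
  expect_true(all(is.na(m[, c("a_nm", "b_nm", "c_nm", "i_nm")])))
  # any vertical scan away from the membrane is constant
  img <- pr$intensity
  top_rows <- img[1:80, ]
  expect_equal(max(top_rows), min(top_rows))
  # AZ traces span the full image width
  expect_equal(min(pr$boundaries$az_outer[, 1]), 0)
  expect_gt(max(pr$boundaries$az_outer[, 1]), (200 - 2) * 1.228)
})

test_that("rendering is deterministic given spec and seed", {
  a <- render_profile(profile_spec("2", noise_sigma = 8, seed = 42))
  b <- render_profile(profile_spec("2", noise_sigma = 8, seed = 42))
  expect_identical(a$intensity, b$intensity)
  expect_identical(a$boundaries, b$boundaries)
  c <- render_profile(profile_spec("2", noise_sigma = 8, seed = 43))
  expect_false(identical(a$intensity, c$intensity))
})

test_that("invalid specs are rejected with the offending field named", {
  expect_error(profile_spec("2", pore_width_i_nm = 5), "pore_width_i_nm")
  expect_error(profile_spec("5", gap_c_nm = 4), "gap_c_nm")
  expect_error(profile_spec("1", gap_c_nm = -2), "gap_c_nm")
  expect_error(profile_spec("4", pore_width_i_nm = 28), "pore_width")
})

test_that("measured gap increases monotonically with generated gap", {
  cs <- c(4, 6.4, 9, 12)
  meas <- vapply(cs, function(cc) {
    measure_event(render_profile(
      profile_spec("tethered_sv", gap_c_nm = cc)))$c_nm
  }, 0)
  expect_true(all(diff(meas) > 0))
  expect_lt(max(abs(meas - cs)), half_px)
})

test_that("fixture sets honour requested counts and draw near the means", {
  fs <- fixture_set_clean()
  expect_length(fs, 86)
  labels <- vapply(fs, function(p) p$truth_label, character(1))
  expect_equal(as.integer(table(factor(labels, levels = as.character(1:7)))),
               event_census_counts)
  expect_equal(sum(labels %in% as.character(2:6)), 55)

  idx <- attr(fs, "index")
  s1 <- idx[idx$state == "1", ]
  expect_true(all(abs(s1$gap_c_nm - 6.4) <= 0.8 + 1e-9))

  expect_length(make_fixture_set(rep(0L, 7)), 0)
  fs3 <- make_fixture_set(c(0, 3, 0, 0, 0, 0, 0), seed = 2)
  expect_length(fs3, 3)
  expect_true(all(vapply(fs3, function(p) p$truth_label, "") == "2"))
  expect_error(make_fixture_set(c(-1, rep(0, 6))), ">= 0")
})

test_that("identical fixture seeds give identical sets", {
  a <- make_fixture_set(c(0, 2, 0, 1, 0, 0, 0), seed = 5)
  b <- make_fixture_set(c(0, 2, 0, 1, 0, 0, 0), seed = 5)
  expect_identical(lapply(a, function(p) p$intensity),
                   lapply(b, function(p) p$intensity))
})

test_that("sampled populations reproduce the group composition exactly", {
  pop <- population_spec(seed = 1)
  tbl <- sample_population(pop)
  ev <- tbl[tbl$kind == "event", c("synapse_id", "state")]
  ids <- paste0("stimulated_", 1:75)
  cen <- census_tables(ev[grepl("^stimulated", ev$synapse_id), ],
                       synapse_ids = ids)
  expect_equal(cen$groups$n, c(39L, 11L, 25L))
  expect_equal(round(100 * cen$groups$fraction, 1), c(52.0, 14.7, 33.3))

  empty <- sample_population(population_spec(
    groups = tibble::tibble(group = "g", n_synapses = 0L,
                            n_ongoing = 0L, n_bumps = 0L)))
  expect_equal(nrow(empty), 0)
})

test_that("noise-free tether counts lie exactly on the configured line", {
  pop <- population_spec(tether_intercept = 5, tether_slope = -0.1,
                         tether_sd = 0, seed = 3)
  tbl <- sample_population(pop)
  svs <- tbl[tbl$kind == "sv", ]
  expect_true(all(svs$tether_count ==
                    pmax(0, round(5 - 0.1 * svs$distance_nm))))
})

test_that("sampled SV distances follow the configured bin distribution", {
  wts <- c(1.2, 1.6, 2.0, 1.4, 1.1, 1, 1, 1, 1, 1, 1, 1)
  pop <- population_spec(
    groups = tibble::tibble(group = "stimulated", n_synapses = 1100L,
                            n_ongoing = 0L, n_bumps = 0L),
    n_state1 = 0L, mean_sv_per_synapse = 10, distance_weights = wts,
    seed = 11)
  d <- sample_population(pop)$distance_nm
  expect_gt(length(d), 1e4)
  d <- d[1:1e4]
  p <- wts / sum(wts)
  cdf <- function(q) {
    vapply(q, function(x) {
      b <- pmin(pmax(x / 2, 0), 12)
      full <- floor(b)
      sum(p[seq_len(full)]) + if (full < 12) p[full + 1] * (b - full) else 0
    }, 0)
  }
  ks <- suppressWarnings(stats::ks.test(d, cdf))
  expect_gt(ks$p.value, 0.01)
})
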