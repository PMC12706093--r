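mk_record <- function(...) {
  base <- tibble::tibble(
    a_nm = NA_real_, b_nm = NA_real_, c_nm = NA_real_, d_nm = NA_real_,
    e1_nm = NA_real_, e2_nm = NA_real_, droplet_ratio = NA_real_,
    f_ratio = NA_real_, g_nm = NA_real_, h_ratio = NA_real_,
    i_nm = NA_real_, j1_deg = NA_real_, outward_curvature = NA,
    k1_nm = NA_real_, k2_nm = NA_real_, thickening_ratio = NA_real_)
  over <- list(...)
  for (f in names(over)) base[[f]] <- over[[f]]
  base
}

test_that("the decision cascade maps prototypical records to their states", {
  expect_equal(classify_event(mk_record(c_nm = 6.4, d_nm = 2.6,
                                        droplet_ratio = 0)), "1")
  expect_equal(classify_event(mk_record(c_nm = 4, droplet_ratio = 1.4,
                                        f_ratio = 0.5)), "2")
  expect_equal(classify_event(mk_record(c_nm = 15, d_nm = 0,
                                        droplet_ratio = 0)), "tethered_sv")
  expect_equal(classify_event(mk_record(f_ratio = 1, h_ratio = 1,
                                        g_nm = 10)), "3")
  expect_equal(classify_event(mk_record(f_ratio = 1, h_ratio = 0.3,
                                        outward_curvature = TRUE,
                                        i_nm = 8)), "4")
  expect_equal(classify_event(mk_record(h_ratio = 0.2,
                                        outward_curvature = FALSE,
                                        thickening_ratio = 1.05,
                                        b_nm = 48)), "5")
  expect_equal(classify_event(mk_record(outward_curvature = FALSE,
                                        thickening_ratio = 1.5,
                                        b_nm = 29.6)), "6")
  expect_equal(classify_event(mk_record(outward_curvature = FALSE,
                                        thickening_ratio = 1.5,
                                        b_nm = 7.7)), "7")
})

test_that("threshold boundaries follow the strict/closed conventions", {
  # droplet strictly > 1.3
  expect_equal(classify_event(mk_record(c_nm = 5, droplet_ratio = 1.31)), "2")
  expect_equal(classify_event(mk_record(c_nm = 5, droplet_ratio = 1.30,
                                        d_nm = 2)), "1")
  # state-1 band inclusive at 4 and 8; invagination floor at 1.2
  expect_equal(classify_event(mk_record(c_nm = 4, d_nm = 1.2,
                                        droplet_ratio = 0)), "1")
  expect_equal(classify_event(mk_record(c_nm = 8, d_nm = 3,
                                        droplet_ratio = 0)), "1")
  expect_equal(classify_event(mk_record(c_nm = 8.01, d_nm = 3,
                                        droplet_ratio = 0)), "tethered_sv")
  expect_equal(classify_event(mk_record(c_nm = 6, d_nm = 1.1,
                                        droplet_ratio = 0)), "tethered_sv")
  # collapsing pore strictly above 10 nm
  expect_equal(classify_event(mk_record(thickening_ratio = 1.5,
                                        outward_curvature = FALSE,
                                        b_nm = 10.01)), "6")
  expect_equal(classify_event(mk_record(thickening_ratio = 1.5,
                                        outward_curvature = FALSE,
                                        b_nm = 10)), "7")
  # thickening strictly > 1.3 separates 5 from 6
  expect_equal(classify_event(mk_record(outward_curvature = FALSE,
                                        thickening_ratio = 1.3,
                                        b_nm = 30)), "5")
})

test_that("exclusion flags remove events before any morphometry is used", {
  m <- mk_record(c_nm = 6.4, d_nm = 2.6, droplet_ratio = 0)
  expect_equal(classify_event(m, exclusion_flags(at_active_zone = FALSE)),
               "excluded")
  expect_equal(classify_event(m, exclusion_flags(clathrin_halo = TRUE)),
               "excluded")
  expect_equal(classify_event(m, exclusion_flags(resolution_ok = FALSE)),
               "excluded")
  # and excluded events never enter census counts
  ev <- tibble::tibble(synapse_id = c("s1", "s1"),
                       state = c("2", "excluded"))
  cen <- census_tables(ev)
  expect_equal(cen$n_events_26, 1L)
})

test_that("contradictory records raise an error", {
  expect_error(classify_event(mk_record(c_nm = 5, h_ratio = 0.5)),
               "contradictory")
})

test_that("synapse state picks the event closest to the open pore", {
  expect_equal(assign_synapse_state(c(2, 2, 5)), 5)
  expect_equal(assign_synapse_state(4), 4)
  expect_equal(assign_synapse_state(c(3, 5)), 5)   # tie toward the higher
  expect_equal(assign_synapse_state(c("1", "7")), 7)
  expect_equal(assign_synapse_state(c("tethered_sv", "2")), 2)
  expect_error(assign_synapse_state(character(0)), "no classified")
  expect_error(assign_synapse_state("tethered_sv"), "no classified")
})

test_that("synapse grouping follows the ongoing-fusion definition", {
  expect_equal(group_synapse(c(7, 7, 2)), "ongoing_fusion")
  expect_equal(group_synapse(integer(0)), "none")
  expect_equal(group_synapse(7), "bumps")
  expect_equal(group_synapse(1), "none")   # state 1 precedes fusion
  expect_equal(group_synapse(c("tethered_sv")), "none")
})

test_that("the classifier recovers all truth labels on noise-free fixtures", {
  cl <- fixture_classified_clean()
  expect_equal(nrow(cl), 86)
  expect_true(all(cl$state == cl$truth))
})

test_that("recovery stays above 95% at 10% contrast noise", {
  cl <- fixture_classified_noisy()
  expect_gte(mean(cl$state == cl$truth), 0.95)
})

test_that("every fixture record maps to exactly one state (total cascade)", {
  m <- fixture_measured_clean()
  states <- vapply(seq_len(nrow(m)), function(i) classify_event(m[i, ]),
                   character(1))
  expect_true(all(states %in% c(as.character(1:7), "tethered_sv")))
  states2 <- vapply(seq_len(nrow(m)), function(i) classify_event(m[i, ]),
                    character(1))
  expect_identical(states, states2)
})
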