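test_that("distance pooling follows the half-open edges and drops > 24 nm", {
  b <- bin_sv_distances(c(2.3, 6.0, 11.9, 24.0))
  expect_equal(unname(b$pools), c(2L, 1L, 1L))
  expect_equal(b$n_dropped, 0L)

  e <- bin_sv_distances(numeric(0))
  expect_equal(unname(e$pools), c(0L, 0L, 0L))

  expect_error(bin_sv_distances(c(3, -1)), "negative")
  expect_message(bin_sv_distances(c(3, 30)), "dropped")
})

test_that("pool counts equal a brute-force recount on random draws", {
  set.seed(7)
  d <- runif(1e4, 0, 24)
  b <- bin_sv_distances(d)
  expect_equal(unname(b$pools),
               c(sum(d <= 6), sum(d > 6 & d <= 12), sum(d > 12 & d <= 24)))
  # histogram conserves counts
  expect_equal(sum(b$histogram$count) + b$n_dropped, length(d))
  brute <- vapply(seq_len(12), function(i) {
    lo <- (i - 1) * 2; hi <- i * 2
    if (i == 1) sum(d >= lo & d <= hi) else sum(d > lo & d <= hi)
  }, integer(1))
  expect_equal(b$histogram$count, brute)
})

test_that("census fractions reproduce the printed compositions", {
  ids <- c(paste0("f", 1:39), paste0("b", 1:11), paste0("n", 1:25))
  ev <- dplyr::bind_rows(
    tibble::tibble(synapse_id = paste0("f", 1:39), state = "2"),
    tibble::tibble(synapse_id = paste0("b", 1:11), state = "7"))
  cen <- census_tables(ev, synapse_ids = ids)
  expect_equal(round(100 * cen$groups$fraction, 1), c(52.0, 14.7, 33.3))
  expect_equal(sum(cen$groups$fraction), 1, tolerance = 1e-9)

  ev2 <- tibble::tibble(synapse_id = seq_len(55),
                        state = rep(as.character(2:6), c(22, 6, 7, 8, 12)))
  sf <- census_tables(ev2)$state_fractions
  expect_equal(round(100 * sf$fraction, 1), c(40.0, 10.9, 12.7, 14.5, 21.8))
  expect_equal(sum(sf$fraction), 1, tolerance = 1e-9)
})

test_that("MVR counts synapses with at least two fusion events", {
  ev <- tibble::tibble(synapse_id = c("a", "a", "b", "c", "c"),
                       state = c("2", "5", "3", "7", "7"))
  cen <- census_tables(ev)
  expect_equal(cen$release$mvr, 1L)    # only synapse a
  expect_equal(cen$release$uvr, 1L)    # synapse b
  # two events where one is a bump is not MVR
  ev2 <- tibble::tibble(synapse_id = "a", state = c("2", "7"))
  expect_equal(census_tables(ev2)$release$mvr, 0L)
})

test_that("nearest neighbors match a brute-force oracle and handle edge cases", {
  two <- tibble::tibble(
    synapse_id = "s", object_id = c("a", "b"), kind = "sv",
    distance_nm = c(2, 3), x_nm = c(0, 3), y_nm = c(0, 4), z_nm = c(0, 0))
  nn <- nearest_neighbor_analysis(two)
  expect_equal(nn$per_object$nn_distance_nm, c(5, 5))

  set.seed(3)
  n <- 50
  tbl <- tibble::tibble(
    synapse_id = "s", object_id = paste0("o", 1:n),
    kind = sample(c("sv", "event"), n, replace = TRUE, prob = c(0.8, 0.2)),
    distance_nm = runif(n, 0, 6),
    x_nm = runif(n, 0, 200), y_nm = runif(n, 0, 200),
    z_nm = runif(n, 0, 30))
  got <- nearest_neighbor_analysis(tbl)$per_object
  for (i in seq_len(nrow(got))) {
    row <- got[i, ]
    svs <- tbl[tbl$kind == "sv" & tbl$object_id != row$object_id, ]
    brute <- min(sqrt((svs$x_nm - row$x_nm)^2 + (svs$y_nm - row$y_nm)^2 +
                      (svs$z_nm - row$z_nm)^2))
    expect_equal(row$nn_distance_nm, brute)
  }

  single <- tibble::tibble(synapse_id = "s", object_id = "a", kind = "event",
                           distance_nm = 0, x_nm = 0, y_nm = 0, z_nm = 0)
  expect_message(r1 <- nearest_neighbor_analysis(single), "singleton")
  expect_true(is.na(r1$per_object$nn_distance_nm))
  expect_error(nearest_neighbor_analysis(single[, 1:3]), "missing columns")
})

test_that("interconnector strata separate the two nn populations", {
  pop <- population_spec(seed = 5)
  tbl <- sample_population(pop)
  nn <- tbl[tbl$kind == "event" & tbl$state %in% as.character(2:6), ]
  m_ic <- mean(nn$nn_distance_nm[nn$interconnected])
  m_no <- mean(nn$nn_distance_nm[!nn$interconnected])
  expect_lt(m_ic, m_no)
})

test_that("BH adjustment matches the step-up rule", {
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(2)
  p <- runif(20)
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  expect_true(all(q <= 1))
  # monotone: sorting by p never decreases q
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("non-releasing fraction implements the mixture decomposition", {
  expect_equal(estimate_nonreleasing_fraction(1.3, 1.3, 3.0), 0)
  expect_equal(estimate_nonreleasing_fraction(3.0, 1.3, 3.0), 1)
  expect_equal(estimate_nonreleasing_fraction(1.9, 1.3, 3.0), 0.6 / 1.7)
  expect_equal(estimate_nonreleasing_fraction(0.5, 1.3, 3.0), 0)  # clipped
  expect_error(estimate_nonreleasing_fraction(1, 2, 2), "differ")
})

test_that("tether-distance line recovers exact and noisy trends", {
  d <- seq(1, 24, length.out = 30)
  f0 <- fit_tether_distance_line(5 - 0.1 * d, d)
  expect_equal(f0$slope, -0.1, tolerance = 1e-12)
  expect_equal(f0$intercept, 5, tolerance = 1e-12)
  expect_equal(f0$r, -1, tolerance = 1e-12)

  set.seed(2)
  y <- 5 - 0.1 * d + rnorm(30, 0, 0.4)
  f1 <- fit_tether_distance_line(y, d)
  X <- cbind(1, d)
  beta <- solve(t(X) %*% X, t(X) %*% y)   # normal equations oracle
  expect_equal(f1$intercept, beta[1], tolerance = 1e-10)
  expect_equal(f1$slope, beta[2], tolerance = 1e-10)

  expect_message(fc <- fit_tether_distance_line(rep(4, 10), 1:10), "zero")
  expect_equal(fc$slope, 0)
  expect_equal(fc$r, 0)
  expect_error(fit_tether_distance_line(1:5, rep(2, 5)), "variance")
})

test_that("fraction-above-threshold helper counts strictly above", {
  x <- c(10, 70, 70.5, 90, 5)
  expect_equal(fraction_above_threshold(x, 70), 2 / 5)
  expect_equal(fraction_above_threshold(x, 70, background = 15), 2 / 3)
  expect_equal(fraction_above_threshold(numeric(0), 70), 0)
})

test_that("group comparison wrapper dispatches on normality and group count", {
  set.seed(9)
  a <- rnorm(30); b <- rnorm(30, 1)
  r1 <- compare_groups(c(a, b), rep(c("x", "y"), each = 30))
  expect_equal(r1$method, "t")
  skew <- rexp(30); skew2 <- rexp(30, 0.5)
  r2 <- compare_groups(c(skew, skew2), rep(c("x", "y"), each = 30))
  expect_equal(r2$method, "mann_whitney")
  r3 <- compare_groups(c(a, b, rnorm(30, 2)),
                       rep(c("x", "y", "z"), each = 30))
  expect_equal(r3$method, "kruskal_wallis")
})
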