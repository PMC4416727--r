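test_that("scenario sigma scaling halves the right axis", {
  expect_equal(scenario_sigmas("spatial", 1), list(sigma_x = 64, sigma_t = 32))
  expect_equal(scenario_sigmas("spatial", 7)$sigma_x, 1)
  expect_equal(scenario_sigmas("spatial", 7)$sigma_t, 32)
  expect_equal(scenario_sigmas("temporal", 3),
               list(sigma_x = 64, sigma_t = 8))
  expect_equal(scenario_sigmas("spatiotemporal", 4),
               list(sigma_x = 8, sigma_t = 4))
  # "none" stays at the weakest values whatever the level
  expect_equal(scenario_sigmas("none", 5), scenario_sigmas("none", 1))
  expect_error(scenario_sigmas("diagonal", 1))
  expect_error(scenario_sigmas("spatial", 0))
  expect_error(scenario_sigmas("spatial", 2, base_sigma_x = -1))
})

test_that("cluster centers are uniform on the lattice", {
  set.seed(101)
  ctr <- sample_cluster_centers(40, 100, 50)
  expect_equal(nrow(ctr), 40)
  expect_true(all(ctr[, "location"] >= 0 & ctr[, "location"] <= 99))
  expect_true(all(ctr[, "year"] >= 1 & ctr[, "year"] <= 50))
  expect_error(sample_cluster_centers(0, 10, 10))
  expect_error(sample_cluster_centers(5, 0, 10))
  # degenerate lattice: the single cell
  expect_equal(unname(sample_cluster_centers(1, 1, 1)), matrix(c(1L, 0L), 1))
  # chi-square goodness of fit on a small lattice
  big <- sample_cluster_centers(20000, 10, 5)
  counts <- table(factor(big[, "location"] * 5 + big[, "year"],
                         levels = as.vector(outer(0:9 * 5, 1:5, "+"))))
  p <- stats::chisq.test(as.vector(counts))$p.value
  expect_gt(p, 0.01)
})

test_that("cluster events are distinct, on-lattice and Gaussian around the mode", {
  set.seed(202)
  ctr <- c(year = 25L, location = 50L)
  for (r in 1:20) {
    ev <- sample_cluster_events(ctr, list(sigma_x = 5, sigma_t = 3), 12)
    expect_equal(nrow(ev), 12)
    expect_equal(anyDuplicated(paste(ev[, 1], ev[, 2])), 0L)
    expect_true(all(ev[, "year"] >= 1 & ev[, "year"] <= 50))
    expect_true(all(ev[, "location"] >= 0 & ev[, "location"] <= 99))
  }
  # delta limit: a point-mass cluster sits on its mode only
  ev0 <- sample_cluster_events(ctr, list(sigma_x = 0, sigma_t = 0), 12)
  expect_equal(unname(ev0), matrix(c(25L, 50L), 1))
  # spatial wrap: a mode at location 0 spills onto both ends of the ring
  evw <- sample_cluster_events(c(year = 25L, location = 0L),
                               list(sigma_x = 2, sigma_t = 2), 200)
  expect_true(all(evw[, "location"] >= 0 & evw[, "location"] <= 99))
  expect_true(any(evw[, "location"] > 90))  # wrapped draws
  # marginal moments: singleton draws, small sigma at the lattice center
  one <- t(replicate(3000, sample_cluster_events(
    ctr, list(sigma_x = 3, sigma_t = 3), 1)[1, ]))
  expect_lt(abs(mean(one[, "location"]) - 50), 3 * 3 / sqrt(3000) * 1.2)
  expect_lt(abs(mean(one[, "year"]) - 25), 3 * 3 / sqrt(3000) * 1.2)
  # sample variance ~ sigma^2 (+ 1/12 discretization) within MC error
  expect_lt(abs(stats::var(one[, "location"]) - 9), 0.75)
  # occupied cells are never drawn
  occ <- matrix(FALSE, 100, 50)
  occ[51, 25] <- TRUE  # the mode itself
  ev <- sample_cluster_events(ctr, list(sigma_x = 1, sigma_t = 1), 8,
                              occupied = occ)
  expect_false(any(ev[, "location"] == 50 & ev[, "year"] == 25))
})

test_that("tiny sigma clusters spill out to nearest cells instead of looping", {
  set.seed(7)
  ev <- sample_cluster_events(c(year = 10L, location = 10L),
                              list(sigma_x = 1e-4, sigma_t = 1e-4), 5,
                              max_iter = 50)
  expect_equal(nrow(ev), 5)
  expect_equal(anyDuplicated(paste(ev[, 1], ev[, 2])), 0L)
  # all chosen cells hug the mode
  expect_true(all(abs(ev[, "year"] - 10) <= 2))
  expect_true(all(pmin(abs(ev[, "location"] - 10),
                       100 - abs(ev[, "location"] - 10)) <= 2))
})

test_that("generated fields are consistent and respect degenerate limits", {
  set.seed(303)
  f <- generate_disaster_field("spatial", 4)
  expect_s3_class(f, "disaster_field")
  expect_equal(realized_event_count(f), sum(f$occupancy))
  expect_equal(realized_event_count(f), nrow(f$events))
  expect_true(all(f$occupancy[cbind(f$events[, "location"] + 1L,
                                    f$events[, "year"])] == 1L))
  # sigma -> 0: all cluster samples collapse onto at most M modes
  f0 <- generate_disaster_field("none", n_total = 500, m_clusters = 40,
                                sigma = list(sigma_x = 0, sigma_t = 0))
  expect_lte(realized_event_count(f0), 40)
  # degenerate configuration: a single cluster draws its own Gaussian count
  # (mean N/M = 1, variance 1), so the realized total is small but random
  f1 <- generate_disaster_field("none", n_total = 1, m_clusters = 1)
  expect_lte(realized_event_count(f1), 6)
  expect_equal(realized_event_count(f1), sum(f1$occupancy))
  expect_error(generate_disaster_field("none", n_total = 5, m_clusters = 10))
})

test_that("identical seeds reproduce fields bit-for-bit", {
  set.seed(42); f1 <- generate_disaster_field("spatiotemporal", 5)
  set.seed(42); f2 <- generate_disaster_field("spatiotemporal", 5)
  expect_identical(f1, f2)
})

test_that("compiled and reference field generators agree statistically", {
  set.seed(11)
  ref <- replicate(100, realized_event_count(generate_disaster_field("none")))
  cpp <- replicate(100, sum(osotua:::cpp_generate_field(100L, 50L, 500, 40L,
                                                        64, 32)))
  # both target ~500 realized events; 40 clusters of variance 1 => sd ~ 6.3
  se <- sqrt(stats::var(ref) / 100 + stats::var(cpp) / 100)
  expect_lt(abs(mean(ref) - mean(cpp)), 4 * se)
  set.seed(12)
  cpp_sp <- replicate(50, sum(osotua:::cpp_generate_field(100L, 50L, 500, 40L,
                                                          1, 32)))
  ref_sp <- replicate(50, realized_event_count(
    generate_disaster_field("spatial", 7)))
  expect_lt(abs(mean(ref_sp) - mean(cpp_sp)),
            4 * sqrt(stats::var(ref_sp) / 50 + stats::var(cpp_sp) / 50))
})

test_that("field export writes occupancy, events and metadata", {
  set.seed(5)
  f <- generate_disaster_field("temporal", 2)
  d <- withr::local_tempdir()
  write_disaster_field(f, d)
  ev <- utils::read.csv(file.path(d, "events.csv"))
  expect_equal(nrow(ev), realized_event_count(f))
  meta <- jsonlite::read_json(file.path(d, "field.json"))
  expect_equal(meta$scenario, "temporal")
  expect_equal(meta$sigma_t, 16)
})
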