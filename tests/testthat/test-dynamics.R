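test_that("growth and loss draws have the stated moments", {
  p <- sim_params()
  expect_equal(annual_growth(0, p), 0)            # absorbing zero
  expect_equal(disaster_loss(0, p), 0)
  set.seed(1)
  g <- annual_growth(rep(1, 1e5), p)              # growth factors
  expect_lt(abs(mean(g) - 1.03), 3 * 0.03 / sqrt(1e5))
  l <- 1 - disaster_loss(rep(1, 1e5), p)          # loss fractions
  expect_lt(abs(mean(l) - 0.30), 3 * 0.10 / sqrt(1e5) * 1.1)
  # loss fractions are clipped to [0, 1] even for wild parameters
  pw <- sim_params(loss_mean = 0.9, loss_sd = 0.8)
  lw <- 1 - disaster_loss(rep(1, 1e4), pw)
  expect_true(all(lw >= 0 & lw <= 1))
})

test_that("the giving rule is all-or-nothing at the threshold boundary", {
  expect_equal(gift_amount(100, 30, 64), 30)  # giver left at 70
  expect_equal(gift_amount(90, 30, 64), 0)    # would leave 60 < 64
  expect_equal(gift_amount(94, 30, 64), 30)   # left exactly at 64: allowed
  expect_equal(gift_amount(c(100, 90, 94), 30, 64), c(30, 0, 30))
})

test_that("requests restore needy herds to exactly the threshold", {
  net <- ring_lattice(5, 2)  # cycle 1-2-3-4-5
  p <- sim_params()
  herd <- c(40, 200, 200, 200, 200)
  set.seed(2)
  out <- process_requests(herd, rep(TRUE, 5), net, p, year = 3L)
  expect_equal(out$herd[1], 64)
  expect_equal(nrow(out$gifts), 1)
  expect_equal(out$gifts$amount, 24)
  expect_equal(out$gifts$year, 3L)
  expect_true(out$gifts$giver %in% c(2, 5))
  expect_equal(sum(out$herd), sum(herd))       # conservation
  # a partner holding exactly the threshold cannot give anything
  out2 <- process_requests(c(40, 64, 64, 64, 64), rep(TRUE, 5), net, p)
  expect_equal(out2$herd[1], 40)
  expect_equal(nrow(out2$gifts), 0)
  # dead nodes are never chosen as partners and never ask
  alive <- c(TRUE, FALSE, TRUE, TRUE, FALSE)
  out3 <- process_requests(c(40, 10, 200, 200, 10), alive, net, p)
  expect_equal(out3$herd[c(2, 5)], c(10, 10))
  if (nrow(out3$gifts) > 0) expect_true(all(out3$gifts$giver == 3))
})

test_that("gifting conserves cattle and leaves herds unchanged or at threshold", {
  p <- sim_params()
  set.seed(3)
  for (r in 1:200) {
    net <- rewire_network(ring_lattice(20, 4), stats::runif(1))
    herd <- stats::runif(20, 0, 150)
    alive <- stats::runif(20) > 0.2
    out <- process_requests(herd, alive, net, p)
    expect_equal(sum(out$herd), sum(herd), tolerance = 1e-12)
    changed <- which(out$herd != herd)
    for (i in changed) {
      if (out$herd[i] > herd[i]) {
        expect_equal(out$herd[i], 64)             # receivers land on 64
      } else {
        expect_gte(out$herd[i], 64)               # givers never drop below
      }
    }
    expect_true(all(out$herd[!alive] == herd[!alive]))  # dead frozen
    if (nrow(out$gifts)) {
      expect_true(all(out$gifts$amount > 0))
      expect_true(all(out$gifts$giver != out$gifts$receiver))
    }
  }
})

test_that("elimination needs two consecutive below-threshold years", {
  p <- sim_params()
  # year n below, year n+1 below -> dead
  s <- update_survival(c(60, 70), c(TRUE, TRUE), c(0L, 0L), p)
  expect_equal(s$below_count, c(1L, 0L))
  expect_equal(s$alive, c(TRUE, TRUE))
  s2 <- update_survival(c(60, 70), s$alive, s$below_count, p)
  expect_equal(s2$alive, c(FALSE, TRUE))
  # a gift restoring the herd to 64 resets the streak (post-gift check)
  s3 <- update_survival(c(64, 64), c(TRUE, TRUE), c(1L, 1L), p)
  expect_equal(s3$below_count, c(0L, 0L))
  expect_equal(s3$alive, c(TRUE, TRUE))
})

test_that("a quiet world compounds growth and everyone survives", {
  f <- empty_field()
  net <- rewire_network(ring_lattice(100, 4), 0.5)
  p <- sim_params(growth_sd = 0)
  for (eng in c("compiled", "reference")) {
    set.seed(4)
    res <- run_simulation(f, net, p, engine = eng)
    expect_equal(res$survival_rate, 1)
    expect_equal(res$effective_disasters, 0L)
    expect_equal(nrow(res$gifts), 0)
    expect_equal(res$herds, rep(70 * 1.03^50, 100), tolerance = 1e-10)
  }
})

test_that("disasters strike by ring position and are counted when effective", {
  # one event at (year 1, location 0): only node 1 is hit
  f <- field_with_events(cbind(year = 1L, location = 0L))
  p <- sim_params(t_years = 1L, growth_sd = 0, loss_sd = 0)
  set.seed(5)
  res <- run_simulation(f, NULL, p, engine = "reference")
  expect_equal(res$effective_disasters, 1L)
  expect_equal(res$herds[1], 70 * 1.03 * 0.7, tolerance = 1e-10)
  expect_equal(res$herds[2], 70 * 1.03, tolerance = 1e-10)
  # the same event aimed at a dead ring position is masked (not effective)
  f2 <- field_with_events(cbind(year = c(1L, 2L, 4L), location = 0L),
                          t_extent = 5L)
  p2 <- sim_params(t_years = 5L, growth_sd = 0, loss_sd = 0)
  set.seed(6)
  res2 <- run_simulation(f2, NULL, p2, engine = "reference")
  # node 1 dies after years 1-2 below threshold; year-4 event hits a corpse
  expect_false(res2$alive[1])
  expect_equal(res2$effective_disasters, 2L)
})

test_that("full runs are seed-deterministic per engine", {
  set.seed(7); f <- generate_disaster_field("none")
  net <- rewire_network(ring_lattice(100, 4), 0.8)
  for (eng in c("compiled", "reference")) {
    set.seed(8); a <- run_simulation(f, net, engine = eng)
    set.seed(8); b <- run_simulation(f, net, engine = eng)
    expect_identical(a, b)
  }
})

test_that("compiled and reference engines agree statistically", {
  p <- sim_params()
  net <- rewire_network(ring_lattice(100, 4), 0.8)
  run_many <- function(eng, n) {
    vapply(seq_len(n), function(i) {
      f <- generate_disaster_field("none")
      r <- run_simulation(f, net, p, engine = eng, collect_gifts = FALSE)
      c(r$survival_rate, r$effective_disasters, sum(r$gifts_per_year))
    }, numeric(3))
  }
  set.seed(9)
  a <- run_many("compiled", 150)
  b <- run_many("reference", 150)
  for (k in 1:3) {
    se <- sqrt(stats::var(a[k, ]) / 150 + stats::var(b[k, ]) / 150)
    expect_lt(abs(mean(a[k, ]) - mean(b[k, ])), 4 * se)
  }
})

test_that("loss-triggered asking is more restrictive than need-based asking", {
  net <- rewire_network(ring_lattice(100, 4), 0.8)
  set.seed(10)
  surv <- sapply(c("need", "loss"), function(tr) {
    mean(replicate(40, {
      f <- generate_disaster_field("none")
      run_simulation(f, net, sim_params(ask_trigger = tr),
                     collect_gifts = FALSE)$survival_rate
    }))
  })
  expect_gt(surv["need"], surv["loss"])
})

test_that("simulation results serialize to CSV and JSON", {
  set.seed(11)
  f <- generate_disaster_field("none")
  res <- run_simulation(f, ring_lattice(100, 4))
  d <- withr::local_tempdir()
  write_sim_result(res, d)
  gifts <- utils::read.csv(file.path(d, "gifts.csv"))
  expect_equal(nrow(gifts), sum(res$gifts_per_year))
  js <- jsonlite::read_json(file.path(d, "result.json"))
  expect_equal(js$survival_rate, res$survival_rate)
})
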