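test_that("veto switch is Bernoulli, seeded, and validated", {
  set.seed(11)
  s <- simulate_veto_switch(1e5, 0.5)
  expect_true(abs(mean(s) - 0.5) < 3 * sqrt(0.25 / 1e5))
  expect_true(all(s %in% c(0L, 1L)))
  set.seed(12); a <- simulate_veto_switch(1000, 0.123)
  set.seed(12); b <- simulate_veto_switch(1000, 0.123)
  expect_identical(a, b)
  expect_error(simulate_veto_switch(10, 0), "0, 1")
  expect_error(simulate_veto_switch(10, 1), "0, 1")
})

test_that("trial sets satisfy the structural invariants", {
  for (mode in c("reversed", "literal")) {
    cfg <- trial_config(line_chain(3), N = 10, M = 4, k = 3, p_switch = 0.4,
                        seed = 21, mode = mode)
    tr <- generate_trials(cfg)
    K <- 5
    expect_equal(dim(tr$positions), c(3, 8, 10))
    for (p in 1:3) {
      expect_equal(sum(tr$labels[p, ] == "left"), 4L)
      expect_equal(sum(tr$labels[p, ] == "right"), 4L)
      for (j in 1:8) {
        path <- unname(tr$positions[p, j, ])
        expect_equal(path[10], if (tr$labels[p, j] == "left") 0L else 4L)
        expect_true(all(path %in% 0:(K - 1)))
        # consecutive positions must be reachable under the chain
        steps <- cbind(path[-10] + 1L, path[-1] + 1L)
        expect_true(all(line_chain(3)$P[steps] > 0))
      }
    }
    # determinism: same config twice gives the identical set
    tr2 <- generate_trials(cfg)
    expect_identical(tr$positions, tr2$positions)
    expect_identical(tr$labels, tr2$labels)
  }
})

test_that("reversed generator reproduces the t-step conditional law", {
  # line n=1, N=3: position at t=-2 given left has law row 0 of P^2
  cfg <- trial_config(line_chain(1), N = 3, M = 5000, k = 1, seed = 31,
                      mode = "reversed")
  tr <- generate_trials(cfg)
  lefts <- as.vector(tr$labels) == "left"
  pmf <- empirical_pmf(tr, 1, 3, lefts)
  expect_lt(tv_dist(pmf, c(0.5, 0.25, 0.25)), 0.05)
})

test_that("literal generator: flash step is boundary + switch-on; one-step law", {
  cfg <- trial_config(line_chain(5), N = 25, M = 2000, k = 1, p_switch = 0.3,
                      seed = 41, mode = "literal")
  tr <- generate_trials(cfg)
  lefts <- as.vector(tr$labels) == "left"
  expect_true(all(tr$positions[1, tr$labels[1, ] == "left", 25] == 0))
  expect_true(all(tr$positions[1, tr$labels[1, ] == "right", 25] == 6))
  # position one step before a left flash follows row 0 of P (time reversal)
  pmf <- empirical_pmf(tr, 24, 7, lefts)
  expect_lt(tv_dist(pmf, c(0.5, 0.5, 0, 0, 0, 0, 0)), 0.05)
  # complete graph: one step before the flash the position is uniform
  cfgc <- trial_config(complete_chain(5), N = 10, M = 1000, k = 1,
                       p_switch = 0.3, seed = 42, mode = "literal")
  trc <- generate_trials(cfgc)
  expect_lt(tv_dist(empirical_pmf(trc, 9, 7), rep(1 / 7, 7)), 0.05)
})

test_that("literal and reversed generators draw from the same trial law", {
  chains <- list(line_chain(5), line_chain(10), complete_chain(5))
  for (ch in chains) {
    K <- nrow(ch$P)
    N <- 25
    lit <- generate_trials(trial_config(ch, N = N, M = 5000, k = 1,
                                        p_switch = 0.3, seed = 51,
                                        mode = "literal"))
    rev <- generate_trials(trial_config(ch, N = N, M = 5000, k = 1,
                                        p_switch = 0.3, seed = 52,
                                        mode = "reversed"))
    lab_l <- as.vector(lit$labels) == "left"
    lab_r <- as.vector(rev$labels) == "left"
    for (ti in seq_len(N)) {
      expect_lt(tv_dist(empirical_pmf(lit, ti, K, lab_l),
                        empirical_pmf(rev, ti, K, lab_r)), 0.05)
    }
  }
})

test_that("position distributions do not depend on the switch probability", {
  pmfs <- lapply(c(0.1, 0.5), function(p) {
    tr <- generate_trials(trial_config(line_chain(5), N = 10, M = 2000, k = 1,
                                       p_switch = p, seed = 61,
                                       mode = "literal"))
    lapply(1:10, function(ti) empirical_pmf(tr, ti, 7,
                                            as.vector(tr$labels) == "left"))
  })
  for (ti in 1:10) expect_lt(tv_dist(pmfs[[1]][[ti]], pmfs[[2]][[ti]]), 0.07)
})

test_that("label-reflection symmetry of the line chain", {
  # reflecting states s -> n+1-s maps the left-trial law onto the right-trial law
  tr <- generate_trials(trial_config(line_chain(5), N = 15, M = 5000, k = 1,
                                     seed = 71, mode = "reversed"))
  lab <- as.vector(tr$labels)
  for (ti in c(1, 5, 10, 14)) {
    pl <- empirical_pmf(tr, ti, 7, lab == "left")
    pr <- empirical_pmf(tr, ti, 7, lab == "right")
    expect_lt(tv_dist(pl, rev(pr)), 0.05)
  }
})

test_that("average position curve: time-locked means split toward the walls", {
  tr <- generate_trials(trial_config(line_chain(1), N = 5, M = 4000, k = 1,
                                     seed = 81, mode = "reversed"))
  avg <- average_position_curve(tr)
  expect_equal(avg$left[5], 0)    # time-locking is exact at t=0
  expect_equal(avg$right[5], 2)
  expect_equal(avg$left[4], 0.5, tolerance = 0.05)  # row 0 of P: (1/2, 1/2, 0)
  # analytic counterpart at every t: sum_s s * P^(|t|)[0, s]
  for (ti in 1:5) {
    expected <- sum((0:2) * t_step_matrix(line_chain(1), 5 - ti)[1, ])
    expect_equal(avg$left[ti], expected, tolerance = 0.08)
  }
  # complete graph: mean position is (n+1)/2 at every t <= -1 for both labels
  trc <- generate_trials(trial_config(complete_chain(5), N = 4, M = 4000, k = 1,
                                      seed = 82, mode = "reversed"))
  avgc <- average_position_curve(trc)
  expect_equal(avgc$left[1:3], rep(3, 3), tolerance = 0.15)
  expect_equal(avgc$right[1:3], rep(3, 3), tolerance = 0.15)
})

test_that("trial sets round-trip through CSV with sidecar", {
  cfg <- trial_config(line_chain(2), N = 6, M = 3, k = 2, seed = 91)
  tr <- generate_trials(cfg)
  tmp <- tempfile(fileext = ".csv")
  write_trials_csv(tr, tmp)
  back <- read_trials_csv(tmp)
  expect_identical(unname(back$positions), unname(tr$positions))
  expect_identical(back$labels, tr$labels)
  expect_equal(back$config$seed, cfg$seed)
  expect_equal(back$config$chain$P, cfg$chain$P)
})

test_that("literal generation errors out when no qualifying flash can be found", {
  expect_error(
    vetowalk:::literal_trial(line_chain(5)$P, target = 0L, N = 10,
                             p_switch = 0.001, burn = 0L, min_events = 50L,
                             max_steps = 2000),
    "exhausted")
  expect_error(trial_config(line_chain(2), N = 1), ">= 2")
  expect_error(trial_config(line_chain(2), M = 1), ">= 2")
  expect_error(trial_config(line_chain(2), p_switch = 1.5), "0, 1")
})
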