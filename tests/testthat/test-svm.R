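test_that("SMO solver attains the optimum of the standard SVM primal", {
  # frozen oracle fixtures: (w, b, objective) from an independent libsvm-type
  # solver on discrete walk-like features, several C values and sizes
  fx <- jsonlite::read_json(svm_fixture_path(), simplifyVector = TRUE)
  grid <- 0:7
  for (i in seq_len(nrow(fx))) {
    x <- fx$x[[i]]; y <- fx$y[[i]]; C <- fx$C[i]
    f <- svm_fit_linear(x, y, C)
    obj <- svm_primal(c(f$w, f$b), x, y, C)
    expect_equal(obj, fx$obj[i], tolerance = 1e-6)
    expect_identical(sign(f$w * grid + f$b + 1e-12),
                     sign(fx$w[i] * grid + fx$b[i] + 1e-12))
  }
  # and against the in-suite multistart primal oracle on fresh random data
  set.seed(101)
  for (rep in 1:10) {
    m <- sample(c(4, 10, 38), 1)
    x <- sample(0:7, m, replace = TRUE)
    y <- sample(c(-1, 1), m, replace = TRUE)
    if (length(unique(y)) == 1) y[1] <- -y[1]
    f <- svm_fit_linear(x, y, 1)
    o <- svm_oracle_fit(x, y, 1)
    expect_lte(svm_primal(c(f$w, f$b), x, y, 1), o$obj + 1e-5)
  }
})

test_that("leave-one-pair-out accuracy: separable, degenerate, and error cases", {
  # perfectly separated scalars classify perfectly
  expect_equal(loo_pair_accuracy(rep(0, 5), rep(6, 5)), 100)
  # all-identical features: deterministic fallback, one of two correct
  expect_equal(loo_pair_accuracy(rep(2, 4), rep(2, 4)), 50)
  expect_error(loo_pair_accuracy(1:3, 1:4), "imbalance")
  expect_error(loo_pair_accuracy(1, 1), "M >= 2")
  expect_error(loo_pair_accuracy(1:3, 4:6, C = -1), "positive")
})

test_that("hand-built 4-trial case matches the independent CV oracle", {
  # left features (0, 1), right features (1, 2) at one time point
  mine <- loo_pair_accuracy(c(0, 1), c(1, 2))
  oracle <- loo_pair_accuracy_oracle(c(0, 1), c(1, 2))
  expect_equal(mine, oracle)
  expect_equal(mine, 50)
  # a few random small cases against the oracle
  set.seed(102)
  for (rep in 1:5) {
    xl <- sample(0:6, 3, replace = TRUE)
    xr <- sample(0:6, 3, replace = TRUE)
    expect_equal(loo_pair_accuracy(xl, xr), loo_pair_accuracy_oracle(xl, xr))
  }
})

test_that("accuracy at t=0 is 100 for every participant on both topologies", {
  for (ch in list(line_chain(5), complete_chain(5))) {
    tr <- generate_trials(trial_config(ch, N = 5, M = 5, k = 4, seed = 111))
    acc <- accuracy_timecourse(tr)
    expect_true(all(acc$per_participant[, 5] == 100))
  }
})

test_that("accuracy time courses: size ordering on the line, chance plateau on the complete graph", {
  acc <- list()
  for (n in c(5, 10)) {
    tr <- generate_trials(trial_config(line_chain(n), N = 40, M = 20, k = 30,
                                       seed = 120 + n))
    acc[[as.character(n)]] <- accuracy_timecourse(tr)
  }
  g5 <- acc[["5"]]$grand_mean; g10 <- acc[["10"]]$grand_mean
  expect_equal(g5[40], 100)
  expect_equal(g10[40], 100)
  # accuracy decreases toward 50 moving backward in time
  expect_lt(mean(g5[1:5]), 60)
  expect_gt(mean(g5[36:39]), 80)
  # the smaller system forgets faster: lower accuracy at matched mid-range t
  expect_lt(mean(g5[26:34]), mean(g10[26:34]))
  # complete graph: chance at every pre-event time
  trc <- generate_trials(trial_config(complete_chain(5), N = 40, M = 20, k = 30,
                                      seed = 131))
  gc <- accuracy_timecourse(trc)$grand_mean
  expect_equal(mean(gc[1:39]), 50, tolerance = 1)
  expect_equal(gc[40], 100)
})

test_that("grand-mean accuracy never beats the Bayes bound by more than 3 SE", {
  for (ch in list(line_chain(5), complete_chain(5))) {
    tr <- generate_trials(trial_config(ch, N = 30, M = 20, k = 30, seed = 141))
    acc <- accuracy_timecourse(tr)
    bayes <- bayes_accuracy_curve(ch, 30)
    for (ti in 1:30) {
      se <- sd(acc$per_participant[, ti]) / sqrt(30)
      expect_lte(acc$grand_mean[ti], bayes$percent[ti] + 3 * se + 1e-9)
    }
  }
})

test_that("Bayes oracle anchors", {
  expect_equal(bayes_accuracy_curve(line_chain(5), 10)$percent[10], 100)
  expect_equal(bayes_accuracy_curve(complete_chain(4), 10)$percent[1:9],
               rep(50, 9))
  # line n=1, t=-1: rows (1/2,1/2,0) vs (0,1/2,1/2) -> 75
  expect_equal(bayes_accuracy_curve(line_chain(1), 2)$percent[1], 75)
})

test_that("accuracy is insensitive to the SVM penalty at a fixed time point", {
  tr <- generate_trials(trial_config(line_chain(5), N = 20, M = 20, k = 10,
                                     seed = 151))
  vals <- sapply(c(0.01, 1, 100), function(C)
    accuracy_timecourse(tr, C = C)$grand_mean[15])
  expect_lte(max(vals) - min(vals), 2.5)  # at most one fold flip in 200
})

test_that("pairing shuffle affects accuracy only within sampling error", {
  tr <- generate_trials(trial_config(line_chain(5), N = 20, M = 20, k = 30,
                                     seed = 161))
  a1 <- accuracy_timecourse(tr, pair_seed = 1)
  a2 <- accuracy_timecourse(tr, pair_seed = 999)
  expect_equal(a1$grand_mean[20], a2$grand_mean[20])  # t=0 exact either way
  se <- apply(a1$per_participant, 2, sd) / sqrt(30)
  expect_true(all(abs(a1$grand_mean - a2$grand_mean) <= 5 * pmax(se, 0.5)))
  expect_lt(mean(abs(a1$grand_mean - a2$grand_mean)), 1.5)
})

test_that("permuted labels drive the grand mean to chance", {
  tr <- generate_trials(trial_config(line_chain(5), N = 20, M = 20, k = 500,
                                     seed = 171))
  set.seed(172)
  for (p in seq_len(500)) tr$labels[p, ] <- sample(tr$labels[p, ])
  g <- accuracy_timecourse(tr)$grand_mean
  expect_true(all(abs(g - 50) <= 2))
})

test_that("class imbalance within a participant is rejected", {
  tr <- generate_trials(trial_config(line_chain(2), N = 4, M = 3, k = 1,
                                     seed = 181))
  tr$labels[1, ] <- c("left", "left", "left", "left", "right", "right")
  expect_error(accuracy_timecourse(tr), "imbalance")
})

test_that("accuracy curves round-trip to CSV", {
  tr <- generate_trials(trial_config(line_chain(2), N = 5, M = 3, k = 2,
                                     seed = 191))
  acc <- accuracy_timecourse(tr)
  tmp <- tempfile(fileext = ".csv")
  write_accuracy_csv(acc, tmp)
  per <- read.csv(tmp)
  grand <- read.csv(sub("\\.csv$", "_grand.csv", tmp))
  expect_equal(nrow(per), 2 * 5)
  expect_equal(grand$accuracy, acc$grand_mean)
  expect_equal(per$accuracy[per$t == 0], acc$per_participant[, 5])
})
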