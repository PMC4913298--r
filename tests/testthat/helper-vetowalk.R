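# shared helpers: distances, empirical pmfs, independent oracles, fixtures

# total-variation distance between two pmfs on the same support
tv_dist <- function(p, q) sum(abs(p - q)) / 2

# empirical pmf of positions at one time index of a trial_set, over states 0..K-1
empirical_pmf <- function(trials, time_index, K, which_trials = NULL) {
  pos <- trials$positions[, , time_index]
  pos <- as.vector(pos)
  if (!is.null(which_trials)) pos <- pos[which_trials]
  as.numeric(table(factor(pos, levels = 0:(K - 1))) / length(pos))
}

# independent primal oracle for the scalar linear SVM: multistart Nelder-Mead
# on the exact (convex) objective 1/2 w^2 + C sum hinge
svm_primal <- function(par, x, y, C) {
  0.5 * par[1]^2 + C * sum(pmax(0, 1 - y * (par[1] * x + par[2])))
}
svm_oracle_fit <- function(x, y, C = 1) {
  starts <- list(c(0, 0), c(1, -1), c(-1, 1), c(2, -3), c(0.5, 0), c(-2, 3))
  best <- NULL
  for (s in starts) {
    o <- stats::optim(s, svm_primal, x = x, y = y, C = C,
                      method = "Nelder-Mead",
                      control = list(maxit = 10000, reltol = 1e-14))
    if (is.null(best) || o$value < best$value) best <- o
  }
  w <- best$par[1]
  # b can be non-unique (flat hinge interval); recover the argmin interval of
  # the piecewise-linear objective in b exactly and take its midpoint, the
  # same convention the dual KKT recovery uses. Breakpoints: b_i = y_i - w x_i;
  # subgradient: active y=-1 hinges push +1, active y=+1 hinges push -1.
  beta <- y - w * x
  bs <- sort(unique(beta))
  slope <- function(b) sum(y == -1 & beta < b) - sum(y == 1 & beta > b)
  mids <- c(bs[1] - 1, (utils::head(bs, -1) + utils::tail(bs, -1)) / 2,
            bs[length(bs)] + 1)
  sl <- vapply(mids, slope, numeric(1))
  zero <- which(sl == 0)
  if (length(zero) > 0) {
    lo <- if (zero[1] == 1) -Inf else bs[zero[1] - 1]
    hi <- if (zero[length(zero)] == length(mids)) Inf else bs[zero[length(zero)]]
    b <- (lo + hi) / 2
  } else {
    b <- bs[which(sl > 0)[1] - 1]
  }
  list(w = w, b = b, obj = svm_primal(c(w, b), x, y, C))
}

# leave-one-pair-out accuracy computed with the primal oracle (independent of
# the SMO code path)
loo_pair_accuracy_oracle <- function(xl, xr, C = 1) {
  M <- length(xl)
  total <- 0
  for (i in seq_len(M)) {
    x <- c(xl[-i], xr[-i])
    y <- c(rep(-1, M - 1), rep(1, M - 1))
    if (max(x) - min(x) < 1e-12) {
      total <- total + 50
      next
    }
    f <- svm_oracle_fit(x, y, C)
    correct <- (f$w * xl[i] + f$b < 0) + (f$w * xr[i] + f$b >= 0)
    total <- total + 50 * correct
  }
  total / M
}

# naive repeated-multiplication matrix power (oracle for t_step_matrix)
matpow_naive <- function(P, t) Reduce(`%*%`, replicate(t, P, simplify = FALSE), diag(nrow(P)))

# a doubly stochastic but non-reversible 3-state "rotor" chain (complex spectrum)
rotor_chain <- function() {
  markov_chain(matrix(c(0.8, 0.2, 0,
                        0, 0.8, 0.2,
                        0.2, 0, 0.8), 3, 3, byrow = TRUE),
               topology = "custom")
}

svm_fixture_path <- function() {
  system.file("extdata", "svm_oracle_fixtures.json", package = "vetowalk")
}
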