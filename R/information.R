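#' Shannon entropy of a probability mass function
#'
#' `-sum p log2 p` with `0 log 0 := 0` (continuity). Base 2 throughout the
#' package: the fair binary time-locked variable at `t = 0` then has entropy
#' exactly 1 bit.
#'
#' @param pmf numeric vector of non-negative masses summing to one
#'   (tolerance 1e-12).
#' @return Entropy in bits.
#' @export
shannon_entropy <- function(pmf) {
  if (!is.numeric(pmf) || any(is.na(pmf)) || any(pmf < -1e-15)) {
    stop("`pmf` must be a numeric vector of non-negative masses", call. = FALSE)
  }
  if (abs(sum(pmf) - 1) > 1e-12) {
    stop("`pmf` must sum to 1 within 1e-12", call. = FALSE)
  }
  p <- pmf[pmf > 0]
  -sum(p * log2(p))
}

#' Distribution of the time-locked position variable
#'
#' The variable `Y_{-t}` is the walker position `t` steps before the event,
#' given that at `t = 0` the walker sits on one of the two boundary states
#' with equal probability:
#' `Pr(Y_{-t} = s) = (P~^(t)[0, s] + P~^(t)[n+1, s]) / 2`,
#' with `P~` the time-reversed chain (equal to the forward chain for both
#' built-in topologies). `direction = "forward"` gives the post-event analogue
#' using the forward matrix; for reversible chains the two coincide.
#'
#' @param chain a [markov_chain()].
#' @param t non-negative integer, number of steps from the event.
#' @param direction `"backward"` (classification, before the event; default)
#'   or `"forward"` (prediction, after it).
#' @return Probability vector over the states.
#' @export
timelocked_distribution <- function(chain, t, direction = c("backward", "forward")) {
  direction <- match.arg(direction)
  ch <- if (direction == "backward") reverse_chain(chain) else chain
  Pt <- t_step_matrix(ch, t)
  K <- nrow(Pt)
  unname((Pt[1, ] + Pt[K, ]) / 2)
}

#' Time-locked mutual information (exact)
#'
#' `I_0(t) = H(Y_{-t}) - H(Y_{-t} | R)` in bits, where `R` in {left, right}
#' is the event identity and
#' `H(Y_{-t} | R) = (H(P~^(t)[0, ]) + H(P~^(t)[n+1, ])) / 2`.
#' Equals 1 bit at `t = 0` (the event pins the position to one of two
#' states) and decays to 0 as `t` grows, at a rate set by the chain's
#' relaxation timescales — asymptotically `I_0(t) ~ C * lambda_1^(2t)` for
#' the line chain.
#'
#' @inheritParams timelocked_distribution
#' @return Mutual information in bits, in `[0, 1]`.
#' @export
timelocked_mi <- function(chain, t, direction = c("backward", "forward")) {
  direction <- match.arg(direction)
  ch <- if (direction == "backward") reverse_chain(chain) else chain
  Pt <- t_step_matrix(ch, t)
  K <- nrow(Pt)
  h_y <- shannon_entropy((Pt[1, ] + Pt[K, ]) / 2)
  h_cond <- (shannon_entropy(Pt[1, ]) + shannon_entropy(Pt[K, ])) / 2
  max(h_y - h_cond, 0)
}

#' Unconstrained mutual information (exact)
#'
#' Without time-locking, the position `X_t` is sampled with no knowledge of
#' the future: the veto switch is independent of the walker, left and right
#' events are equiprobable, so `H(R) = H(R | X_t) = 1` and
#' `I(X_t; R) = 0` identically — the signal carries no predictive
#' information by construction. Returned analytically (the plug-in estimator
#' [empirical_mi()] verifies it on simulations).
#'
#' @param chain a [markov_chain()] built by the drift-free,
#'   independent-veto construction.
#' @param t any integer time (sign irrelevant).
#' @return `0`, exactly.
#' @export
unconstrained_mi <- function(chain, t) {
  stopifnot(inherits(chain, "markov_chain"))
  if (length(t) != 1L || !is.numeric(t) || is.na(t) || t != round(t)) {
    stop("`t` must be an integer", call. = FALSE)
  }
  0
}

#' Plug-in mutual information estimate from paired samples
#'
#' Maximum-likelihood (plug-in) estimator from the empirical joint pmf, in
#' bits. The estimator has a positive small-sample bias of about
#' `(|X| - 1)(|R| - 1) / (2 n ln 2)` bits (Miller-Madow), which
#' `bias_correct = TRUE` subtracts.
#'
#' @param x,r paired observations (any discrete values); `r` is typically
#'   the `"left"`/`"right"` response.
#' @param bias_correct subtract the Miller-Madow bias term?
#' @return Estimated MI in bits (may be slightly negative after correction).
#' @export
empirical_mi <- function(x, r, bias_correct = FALSE) {
  if (length(x) != length(r)) stop("`x` and `r` differ in length", call. = FALSE)
  n <- length(x)
  if (n < 100) stop("need at least 100 paired samples", call. = FALSE)
  if (length(unique(x)) < 1L || length(unique(r)) < 2L) {
    stop("empty classes: `r` must take at least two values", call. = FALSE)
  }
  joint <- table(x, r) / n
  px <- rowSums(joint); pr <- colSums(joint)
  nz <- joint > 0
  mi <- sum(joint[nz] * log2(joint[nz] / outer(px, pr)[nz]))
  if (bias_correct) {
    mi <- mi - (nrow(joint) - 1) * (ncol(joint) - 1) / (2 * n * log(2))
  }
  mi
}

#' Exact mutual-information time course
#'
#' Evaluates the analytic time-locked MI `I_0`, the unconstrained MI `I`
#' (identically zero), and the underlying entropies for `t = 0 .. N-1` steps
#' before the event, reported on the `-t` axis.
#'
#' @param chain a [markov_chain()].
#' @param N number of time points (>= 2).
#' @param direction as in [timelocked_distribution()].
#' @return `data.frame` of class `mi_curve` with columns `t` (0, -1, ...,
#'   `-(N-1)`), `I0_bits`, `I_bits`, `H_bits` (`H(Y_{-t})`), `Hcond_bits`
#'   (`H(Y_{-t}|R)`).
#' @export
mi_timecourse <- function(chain, N, direction = c("backward", "forward")) {
  direction <- match.arg(direction)
  stopifnot(inherits(chain, "markov_chain"))
  if (N < 2 || N != round(N)) stop("`N` must be an integer >= 2", call. = FALSE)
  ch <- if (direction == "backward") reverse_chain(chain) else chain
  K <- nrow(ch$P)
  row_l <- row_r <- numeric(K)
  row_l[1] <- 1; row_r[K] <- 1
  out <- data.frame(t = -(0:(N - 1L)), I0_bits = NA_real_, I_bits = 0,
                    H_bits = NA_real_, Hcond_bits = NA_real_)
  for (i in seq_len(N)) {
    h_y <- shannon_entropy((row_l + row_r) / 2)
    h_c <- (shannon_entropy(row_l) + shannon_entropy(row_r)) / 2
    out$H_bits[i] <- h_y
    out$Hcond_bits[i] <- h_c
    out$I0_bits[i] <- max(h_y - h_c, 0)
    row_l <- as.numeric(row_l %*% ch$P)
    row_r <- as.numeric(row_r %*% ch$P)
  }
  class(out) <- c("mi_curve", "data.frame")
  out
}

#' Write an MI curve as CSV
#'
#' Columns `t`, `I0_bits`, `I_bits`, `H_bits`, `Hcond_bits`.
#'
#' @param curve an `mi_curve` from [mi_timecourse()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_mi_csv <- function(curve, path) {
  stopifnot(inherits(curve, "mi_curve"))
  write.csv(as.data.frame(curve), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
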