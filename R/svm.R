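#' Linear soft-margin SVM on scalar features
#'
#' Standard C-SVM, `min 1/2 w^2 + C * sum hinge`, with unregularised bias,
#' solved in the dual by SMO (the libsvm algorithm specialised to a 1-D
#' linear kernel; no SVM library ships with this R installation). On one
#' scalar feature the fitted model is a learned threshold plus orientation.
#'
#' @param x numeric feature vector.
#' @param y labels, `+1`/`-1` or a factor/character with two levels
#'   (`"right"` maps to `+1`, `"left"` to `-1`).
#' @param C soft-margin penalty (positive; the accuracy pipeline is
#'   insensitive to it over several orders of magnitude on these data).
#' @return List with `w`, `b`, `converged`, `iter`; decision value is
#'   `w * x + b`, classified `"right"` when `>= 0` (ties break to "right" by
#'   fixed convention).
#' @export
svm_fit_linear <- function(x, y, C = 1) {
  if (!is.numeric(C) || length(C) != 1L || C <= 0) {
    stop("`C` must be a positive scalar", call. = FALSE)
  }
  if (is.character(y) || is.factor(y)) {
    y <- ifelse(as.character(y) == "right", 1L, -1L)
  }
  y <- as.integer(y)
  svm_fit_cpp(as.numeric(x), y, C)
}

#' Leave-one-pair-out CV accuracy at one time point
#'
#' `M` folds: in fold `i` the i-th left and i-th right trial form the test
#' pair and a linear SVM is fitted on the remaining `2M - 2` scalars.
#' Training and test sets are therefore always class-balanced. Each fold
#' contributes 0, 50 or 100 according to how many of the two test labels are
#' correct; the mean over folds is returned.
#'
#' Degenerate folds in which every training feature is identical carry no
#' margin information; by contract the classifier then predicts the class of
#' the first training example (deterministic; expected contribution 50 under
#' label symmetry).
#'
#' @param x_left,x_right numeric vectors of length `M`: the walker positions
#'   of the left and right trials at one time point.
#' @param C SVM penalty.
#' @return Accuracy in percent, in `[0, 100]`.
#' @export
loo_pair_accuracy <- function(x_left, x_right, C = 1) {
  if (length(x_left) != length(x_right)) {
    stop("class imbalance: need exactly M left and M right trials", call. = FALSE)
  }
  if (length(x_left) < 2L) stop("need M >= 2 trials per class", call. = FALSE)
  if (!is.numeric(C) || length(C) != 1L || C <= 0) {
    stop("`C` must be a positive scalar", call. = FALSE)
  }
  loo_pair_accuracy_cpp(as.numeric(x_left), as.numeric(x_right), C)
}

#' Time course of cross-validated classification accuracy
#'
#' Applies [loo_pair_accuracy()] independently at every time point and for
#' every participant, then averages over participants (the grand mean): the
#' decoding time course `a_t`. Within each participant the left and right
#' trials are paired by index after a seeded within-class shuffle (any
#' pairing is exchangeable; the shuffle makes that explicit and keeps runs
#' reproducible).
#'
#' @param trials a trial set from [generate_trials()].
#' @param C SVM penalty.
#' @param pair_seed seed for the pairing shuffle; defaults to the trial set's
#'   own seed plus one.
#' @return Object of class `accuracy_curve`: list with `times`
#'   (`-(N-1)...0`), `per_participant` (`k x N` matrix, percent), and
#'   `grand_mean` (length-`N` vector).
#' @export
accuracy_timecourse <- function(trials, C = 1, pair_seed = NULL) {
  stopifnot(inherits(trials, "trial_set"))
  d <- dim(trials$positions)
  k <- d[1]; N <- d[3]
  times <- -(N - 1L):0L
  if (is.null(pair_seed)) {
    pair_seed <- if (!is.null(trials$config)) trials$config$seed + 1L else 1L
  }
  set.seed(pair_seed)
  per <- matrix(NA_real_, k, N)
  for (p in seq_len(k)) {
    il <- which(trials$labels[p, ] == "left")
    ir <- which(trials$labels[p, ] == "right")
    if (length(il) != length(ir)) {
      stop("class imbalance: participant has unequal left/right trial counts",
           call. = FALSE)
    }
    il <- il[sample.int(length(il))]
    ir <- ir[sample.int(length(ir))]
    for (ti in seq_len(N)) {
      per[p, ti] <- loo_pair_accuracy_cpp(
        as.numeric(trials$positions[p, il, ti]),
        as.numeric(trials$positions[p, ir, ti]), C)
    }
  }
  structure(list(times = times, per_participant = per,
                 grand_mean = colMeans(per), C = C),
            class = "accuracy_curve")
}

#' @export
print.accuracy_curve <- function(x, ...) {
  N <- length(x$times)
  cat(sprintf("<accuracy_curve> %d participants x %d time points; a(0) = %.1f%%, a(%d) = %.1f%%\n",
              nrow(x$per_participant), N, x$grand_mean[N], x$times[1],
              x$grand_mean[1]))
  invisible(x)
}

#' Bayes-optimal accuracy time course (analytic oracle)
#'
#' The best achievable accuracy for deciding left vs right from the single
#' scalar `X_{-t}`: `100 * sum_s max(P~^(t)[0,s], P~^(t)[n+1,s]) / 2`, where
#' `P~` is the time-reversed chain. Upper-bounds the expected accuracy of
#' any classifier and serves as a test oracle for the SVM pipeline. Equals
#' 100 at `t = 0` (disjoint supports) and 50 for the complete graph at every
#' `t <= -1` (identical uniform conditionals).
#'
#' @param chain a [markov_chain()].
#' @param N number of time points.
#' @return List with `times` (`-(N-1)...0`) and `percent`.
#' @export
bayes_accuracy_curve <- function(chain, N) {
  stopifnot(inherits(chain, "markov_chain"))
  K <- nrow(chain$P)
  rev <- reverse_chain(chain)
  row_l <- row_r <- numeric(K)
  row_l[1] <- 1; row_r[K] <- 1
  percent <- numeric(N)
  for (t in 0:(N - 1L)) {
    percent[N - t] <- 100 * sum(pmax(row_l, row_r)) / 2
    row_l <- as.numeric(row_l %*% rev$P)
    row_r <- as.numeric(row_r %*% rev$P)
  }
  list(times = -(N - 1L):0L, percent = percent)
}

#' Write an accuracy curve as CSV
#'
#' Long format (`t`, `participant`, `accuracy`) plus a grand-mean file
#' (`<stem>_grand.csv` with columns `t`, `accuracy`), ready for plotting the
#' decoding time course.
#'
#' @param curve an `accuracy_curve`.
#' @param path CSV path for the per-participant table.
#' @return `path`, invisibly.
#' @export
write_accuracy_csv <- function(curve, path) {
  stopifnot(inherits(curve, "accuracy_curve"))
  k <- nrow(curve$per_participant); N <- length(curve$times)
  df <- data.frame(
    t = rep(curve$times, each = k),
    participant = rep(seq_len(k), times = N),
    accuracy = as.vector(curve$per_participant)
  )
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  grand <- data.frame(t = curve$times, accuracy = curve$grand_mean)
  write.csv(grand, sub("\\.csv$", "_grand.csv", path), row.names = FALSE,
            quote = FALSE)
  invisible(path)
}
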