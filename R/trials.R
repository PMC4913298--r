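#' Configuration for the trial generator
#'
#' Describes one simulated experiment: `k` participants, each contributing
#' `M` "left" and `M` "right" trials of `N` time steps, time-locked so the
#' flash (boundary visit with the veto switch on) sits at `t = 0`. The time
#' axis of a trial is `-(N-1), ..., 0` and includes the flash step itself.
#'
#' Defaults follow the reference experimental scale (`k = 500`
#' participants) and a stated-world choice elsewhere (`N = 100` steps,
#' `M = 50` trials per class, `p_switch = 0.001` so the mean gap between
#' power-on events, `1/p_switch = 1000` steps, far exceeds the relaxation
#' time of the default chains — the regime in which consecutive flashes are
#' uncorrelated).
#'
#' @param chain a [markov_chain()].
#' @param N trial length in time steps (>= 2).
#' @param M trials per class per participant (>= 2).
#' @param k number of participants (>= 1).
#' @param p_switch per-step probability that the veto switch is on, in (0,1).
#' @param seed integer master seed; per-participant substreams are derived
#'   from it deterministically.
#' @param mode `"reversed"` (fast reverse-time construction, the production
#'   method) or `"literal"` (long stationary series + veto switch, the
#'   definitional method).
#' @return An object of class `trial_config`.
#' @export
trial_config <- function(chain, N = 100, M = 50, k = 500, p_switch = 0.001,
                         seed = 1L, mode = c("reversed", "literal")) {
  mode <- match.arg(mode)
  stopifnot(inherits(chain, "markov_chain"))
  if (N < 2 || N != round(N)) stop("`N` must be an integer >= 2", call. = FALSE)
  if (M < 2 || M != round(M)) stop("`M` must be an integer >= 2", call. = FALSE)
  if (k < 1 || k != round(k)) stop("`k` must be an integer >= 1", call. = FALSE)
  if (!is.numeric(p_switch) || p_switch <= 0 || p_switch >= 1) {
    stop("`p_switch` must lie strictly inside (0, 1)", call. = FALSE)
  }
  structure(
    list(chain = chain, N = as.integer(N), M = as.integer(M), k = as.integer(k),
         p_switch = p_switch, seed = as.integer(seed), mode = mode),
    class = "trial_config"
  )
}

#' Simulate the veto switch
#'
#' Independent Bernoulli(`p_switch`) draw per time step; an "on" event lasts
#' exactly one step and is independent of the walker. Uses the current R RNG
#' stream, so results are reproducible under `set.seed()`.
#'
#' @param length number of steps (>= 1).
#' @param p_switch on-probability per step, in (0,1).
#' @return Integer vector of 0/1 values.
#' @export
simulate_veto_switch <- function(length, p_switch) {
  if (length < 1 || length != round(length)) {
    stop("`length` must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(p_switch) || p_switch <= 0 || p_switch >= 1) {
    stop("`p_switch` must lie strictly inside (0, 1)", call. = FALSE)
  }
  rbinom(length, 1L, p_switch)
}

# one literal trial: simulate an independent stationary series with its veto
# switch until >= min_events qualifying flashes on `target` exist, pick one
# uniformly, return the N positions ending at (and including) the flash step
literal_trial <- function(P, target, N, p_switch, burn, min_events = 50L,
                          max_steps = 1e7) {
  K <- nrow(P)
  start <- sample.int(K, 1L) - 1L          # uniform = stationary for built-ins
  if (burn > 0L) {
    path <- sim_chain_path_cpp(P, start, burn)
    start <- path[burn]
  }
  pi_target <- 1 / K                        # order-of-magnitude only
  block <- max(10000L, as.integer(ceiling(1.5 * min_events / (p_switch * pi_target))))
  pos <- integer(0)
  sw <- integer(0)
  repeat {
    this_block <- min(block, as.integer(max_steps) - length(pos))
    if (this_block <= 0L) {
      stop(sprintf(
        "literal generation exhausted: fewer than %d qualifying flashes on state %d within %d steps (N=%d, p_switch=%g)",
        min_events, target, as.integer(max_steps), N, p_switch), call. = FALSE)
    }
    new_pos <- sim_chain_path_cpp(P, start, this_block)
    start <- new_pos[this_block]
    pos <- c(pos, new_pos)
    sw <- c(sw, simulate_veto_switch(this_block, p_switch))
    idx <- which(pos == target & sw == 1L)
    idx <- idx[idx >= N]
    if (length(idx) >= min_events) break
  }
  pick <- idx[sample.int(length(idx), 1L)]
  pos[(pick - N + 1L):pick]
}

# one reversed trial: pin t=0 at the boundary, run N-1 steps of the reversed
# chain, report in forward-time order
reversed_trial <- function(P_rev, boundary, N) {
  back <- sim_chain_path_cpp(P_rev, boundary, N - 1L)
  c(rev(back), boundary)
}

#' Generate a time-locked trial set
#'
#' Produces `k` participants x `2M` labelled trials x `N` time points of
#' walker positions, time-locked so the flash is at `t = 0` (position 0 for
#' "left", `n+1` for "right"). Two statistically equivalent constructions are
#' available:
#'
#' * `mode = "literal"`: for each trial an independent stationary series is
#'   simulated together with the veto switch; one qualifying flash (boundary
#'   visit with the switch on) is chosen uniformly at random and the `N`
#'   steps ending at it are stored. This is the definitional procedure; its
#'   cost scales as `1/p_switch`.
#' * `mode = "reversed"`: the trial is built backward from the pinned `t = 0`
#'   boundary state using the time-reversed chain. Because the veto switch is
#'   independent of the walker, conditioning on the flash only pins `X_0`,
#'   so both constructions sample the same trial law.
#'
#' Each participant gets an independent RNG substream derived from the master
#' seed, and exactly `M` trials per class in shuffled order.
#'
#' @param config a [trial_config()].
#' @return An object of class `trial_set`: list with `positions`
#'   (`k x 2M x N` integer array, time dimension named `-(N-1)...0`),
#'   `labels` (`k x 2M` character matrix, `"left"`/`"right"`), and `config`.
#' @export
generate_trials <- function(config) {
  stopifnot(inherits(config, "trial_config"))
  chain <- config$chain
  K <- nrow(chain$P)
  N <- config$N; M <- config$M; k <- config$k
  left_state <- 0L; right_state <- K - 1L

  set.seed(config$seed)
  participant_seeds <- sample.int(.Machine$integer.max - 1L, k)

  if (config$mode == "reversed") {
    P_rev <- reverse_chain(chain)$P
  } else {
    tau1 <- spectral_summary(chain)$relaxation_time
    burn <- if (chain$topology == "custom") as.integer(ceiling(100 * max(tau1, 1))) else 0L
  }

  positions <- array(NA_integer_, dim = c(k, 2L * M, N),
                     dimnames = list(NULL, NULL, as.character(-(N - 1L):0L)))
  labels <- matrix(NA_character_, k, 2L * M)

  for (p in seq_len(k)) {
    set.seed(participant_seeds[p])
    lab <- sample(rep(c("left", "right"), M))
    labels[p, ] <- lab
    for (j in seq_len(2L * M)) {
      target <- if (lab[j] == "left") left_state else right_state
      positions[p, j, ] <- if (config$mode == "reversed") {
        reversed_trial(P_rev, target, N)
      } else {
        literal_trial(chain$P, target, N, config$p_switch, burn)
      }
    }
  }
  structure(list(positions = positions, labels = labels, config = config),
            class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  d <- dim(x$positions)
  cat(sprintf("<trial_set> %d participants x %d trials x %d time points (%s, %s chain, n=%d)\n",
              d[1], d[2], d[3], x$config$mode, x$config$chain$topology,
              x$config$chain$n))
  invisible(x)
}

#' Per-label mean position over time
#'
#' Arithmetic mean of the walker position at each time point, across all
#' trials of each label (participants pooled). As `t` approaches 0 the means
#' split toward the two walls — the time-locked average that mimics an
#' event-related potential despite the absence of predictive signal.
#'
#' @param trials a [trial_set()][generate_trials()].
#' @return `data.frame` with columns `t`, `left`, `right`.
#' @export
average_position_curve <- function(trials) {
  stopifnot(inherits(trials, "trial_set"))
  N <- dim(trials$positions)[3]
  times <- -(N - 1L):0L
  flat_lab <- as.vector(trials$labels)      # participant-major flattening
  out <- data.frame(t = times, left = NA_real_, right = NA_real_)
  for (ti in seq_len(N)) {
    vals <- as.vector(trials$positions[, , ti])
    out$left[ti] <- mean(vals[flat_lab == "left"])
    out$right[ti] <- mean(vals[flat_lab == "right"])
  }
  out
}

#' Read and write trial sets as flat CSV
#'
#' Columns `participant`, `trial`, `label`, `t`, `position`; one row per
#' (trial, time point). A JSON sidecar (`<path>.json`) records the generating
#' configuration for provenance. Round-trips exactly.
#'
#' @param trials a trial set.
#' @param path CSV file path.
#' @return `write_trials_csv()` returns `path` invisibly; `read_trials_csv()`
#'   returns a `trial_set` (with a config stub when no sidecar is present).
#' @export
write_trials_csv <- function(trials, path) {
  stopifnot(inherits(trials, "trial_set"))
  d <- dim(trials$positions)
  k <- d[1]; n_tr <- d[2]; N <- d[3]
  times <- -(N - 1L):0L
  df <- data.frame(
    participant = rep(seq_len(k), each = n_tr * N),
    trial = rep(rep(seq_len(n_tr), each = N), times = k),
    label = rep(as.vector(t(trials$labels)), each = N),
    t = rep(times, times = k * n_tr),
    position = as.vector(aperm(trials$positions, c(3, 2, 1)))
  )
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  cfg <- trials$config
  sidecar <- list(
    topology = cfg$chain$topology, n = cfg$chain$n, N = cfg$N, M = cfg$M,
    k = cfg$k, p_switch = cfg$p_switch, seed = cfg$seed, mode = cfg$mode
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_trials_csv
#' @export
read_trials_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  k <- max(df$participant); n_tr <- max(df$trial); N <- length(unique(df$t))
  positions <- aperm(array(df$position, dim = c(N, n_tr, k)), c(3, 2, 1))
  dimnames(positions) <- list(NULL, NULL, as.character(-(N - 1L):0L))
  labels <- matrix(df$label[seq(1, nrow(df), by = N)], k, n_tr, byrow = TRUE)
  cfg <- NULL
  sc_path <- paste0(path, ".json")
  if (file.exists(sc_path)) {
    sc <- jsonlite::read_json(sc_path, simplifyVector = TRUE)
    chain <- switch(sc$topology,
                    line = line_chain(sc$n),
                    complete = complete_chain(sc$n),
                    NULL)
    if (!is.null(chain)) {
      cfg <- trial_config(chain, N = sc$N, M = sc$M, k = sc$k,
                          p_switch = sc$p_switch, seed = sc$seed, mode = sc$mode)
    }
  }
  structure(list(positions = positions, labels = labels, config = cfg),
            class = "trial_set")
}
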