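#' Discrete-time Markov chain on states 0..n+1
#'
#' Container for the transition matrix of the random-walk decision model.
#' States are indexed `0, 1, ..., n+1`; states `0` and `n+1` are the boundary
#' ("button") states where a flash can occur. Rows must sum to one; for the
#' built-in `line` and `complete` topologies the matrix is doubly stochastic,
#' which forces the uniform stationary distribution.
#'
#' @param transition square numeric matrix of transition probabilities,
#'   row-stochastic; dimension is `n + 2` for `n` interior states.
#' @param topology one of `"line"`, `"complete"`, `"custom"`.
#' @return An object of class `markov_chain` with elements `n` (number of
#'   interior states), `P` (transition matrix with state dimnames), and
#'   `topology`.
#' @seealso [line_chain()], [complete_chain()], [stationary_distribution()]
#' @export
markov_chain <- function(transition, topology = c("custom", "line", "complete")) {
  topology <- match.arg(topology)
  if (!is.matrix(transition) || !is.numeric(transition) ||
      nrow(transition) != ncol(transition) || nrow(transition) < 2) {
    stop("`transition` must be a square numeric matrix of dimension >= 2",
         call. = FALSE)
  }
  if (anyNA(transition) || any(transition < -1e-15) || any(transition > 1 + 1e-15)) {
    stop("transition probabilities must lie in [0, 1]", call. = FALSE)
  }
  rs <- rowSums(transition)
  if (any(abs(rs - 1) > 1e-12)) {
    stop("transition matrix is not row-stochastic (row sums deviate from 1 by more than 1e-12)",
         call. = FALSE)
  }
  if (topology %in% c("line", "complete")) {
    cs <- colSums(transition)
    if (any(abs(cs - 1) > 1e-12)) {
      stop("built-in topologies must be doubly stochastic", call. = FALSE)
    }
  }
  K <- nrow(transition)
  dimnames(transition) <- list(as.character(0:(K - 1)), as.character(0:(K - 1)))
  structure(
    list(n = K - 2L, P = transition, topology = topology),
    class = "markov_chain"
  )
}

#' @export
print.markov_chain <- function(x, ...) {
  cat(sprintf("<markov_chain> topology=%s, n=%d interior states (%d total)\n",
              x$topology, x$n, x$n + 2L))
  invisible(x)
}

check_n <- function(n) {
  if (length(n) != 1L || !is.numeric(n) || is.na(n) || n < 1 || n != round(n)) {
    stop("`n` must be a positive integer", call. = FALSE)
  }
  as.integer(n)
}

#' Random walk on a line with lazy-reflecting boundaries
#'
#' Nearest-neighbour walk on `{0, ..., n+1}`: each interior state moves one
#' step left or right with probability 1/2; each boundary state self-loops
#' with probability 1/2 and steps inward with probability 1/2. The resulting
#' matrix is symmetric (doubly stochastic), so the stationary distribution is
#' uniform, `pi_i = 1/(n+2)`.
#'
#' @param n number of interior states (positive integer).
#' @return A [markov_chain()] with topology `"line"`.
#' @examples
#' line_chain(1)$P
#' @export
line_chain <- function(n) {
  n <- check_n(n)
  K <- n + 2L
  P <- matrix(0, K, K)
  P[1, 1] <- P[1, 2] <- 0.5
  P[K, K] <- P[K, K - 1] <- 0.5
  for (i in seq_len(K - 2L) + 1L) {
    P[i, i - 1L] <- P[i, i + 1L] <- 0.5
  }
  markov_chain(P, topology = "line")
}

#' Random walk on a complete graph
#'
#' Every entry of the transition matrix equals `1/(n+2)`, self-transitions
#' included. One step reaches the stationary (uniform) distribution, so the
#' relaxation time is zero and `P^t = P` for every `t >= 1`.
#'
#' @inheritParams line_chain
#' @return A [markov_chain()] with topology `"complete"`.
#' @export
complete_chain <- function(n) {
  n <- check_n(n)
  K <- n + 2L
  markov_chain(matrix(1 / K, K, K), topology = "complete")
}

#' Stationary distribution of a Markov chain
#'
#' Computed from the left eigenvector for eigenvalue 1 (never by assuming
#' uniformity), so for the built-in chains it doubles as a correctness check
#' of the doubly-stochastic construction.
#'
#' @param chain a [markov_chain()].
#' @param tol tolerance for identifying the unit eigenvalue.
#' @return Numeric vector `pi` with `pi %*% P = pi`, summing to one.
#' @export
stationary_distribution <- function(chain, tol = 1e-10) {
  stopifnot(inherits(chain, "markov_chain"))
  e <- eigen(t(chain$P))
  unit <- which(abs(e$values - 1) < tol)
  if (length(unit) == 0L) {
    stop("no unit eigenvalue found: matrix is not stochastic?", call. = FALSE)
  }
  if (length(unit) > 1L) {
    stop("degenerate chain: multiple unit eigenvalues (stationary state not unique)",
         call. = FALSE)
  }
  v <- Re(e$vectors[, unit])
  v <- v / sum(v)
  if (any(v < -1e-10)) {
    stop("stationary eigenvector has negative mass: chain is not irreducible?",
         call. = FALSE)
  }
  v[v < 0] <- 0
  v / sum(v)
}

#' t-step transition matrix
#'
#' `P^(t)`, the `t`-th matrix power of `P`, computed by repeated squaring.
#' `P^(0)` is the identity. Backward time is handled by [reverse_chain()],
#' not by negative powers.
#'
#' @param chain a [markov_chain()].
#' @param t non-negative integer number of steps.
#' @return `(n+2) x (n+2)` row-stochastic matrix.
#' @export
t_step_matrix <- function(chain, t) {
  stopifnot(inherits(chain, "markov_chain"))
  if (length(t) != 1L || !is.numeric(t) || is.na(t) || t < 0 || t != round(t)) {
    stop("`t` must be a non-negative integer", call. = FALSE)
  }
  t <- as.integer(t)
  K <- nrow(chain$P)
  out <- diag(K)
  base <- chain$P
  while (t > 0L) {
    if (t %% 2L == 1L) out <- out %*% base
    t <- t %/% 2L
    if (t > 0L) base <- base %*% base
  }
  dimnames(out) <- dimnames(chain$P)
  out
}

#' Eigen-spectrum and relaxation timescales
#'
#' Eigenvalues of `P` sorted by descending modulus (`lambda_0 = 1` first) and
#' the associated timescales `tau_i = -1/log|lambda_i|` for `i >= 1`, with the
#' convention `tau = 0` when `lambda = 0` (continuity limit). The relaxation
#' time `tau_1` is the largest of these: the timescale on which the chain
#' forgets its initial condition. For the line chain `tau_1` grows with `n`;
#' for the complete graph it is exactly zero.
#'
#' Complex eigenvalues (possible for custom chains) enter through their
#' modulus, which is what governs geometric convergence.
#'
#' @param chain a [markov_chain()].
#' @param tol tolerance used for the `lambda_0 = 1` check and the zero cutoff.
#' @return An object of class `spectral_summary`: list with `eigenvalues`
#'   (sorted, possibly complex), `timescales` (descending, `tau_1` first),
#'   `relaxation_time` (`tau_1`), and `defective` (logical diagnostic set when
#'   the eigenvector matrix is numerically rank-deficient).
#' @export
spectral_summary <- function(chain, tol = 1e-10) {
  stopifnot(inherits(chain, "markov_chain"))
  e <- eigen(chain$P)
  ord <- order(Mod(e$values), decreasing = TRUE)
  lam <- e$values[ord]
  if (abs(Mod(lam[1]) - 1) > tol) {
    stop("leading eigenvalue is not 1: matrix is not stochastic?", call. = FALSE)
  }
  sub <- Mod(lam[-1])
  if (any(sub >= 1 - 1e-12)) {
    stop("degenerate chain: sub-leading eigenvalue has modulus 1 (stationary state not unique)",
         call. = FALSE)
  }
  taus <- ifelse(sub < tol, 0, -1 / log(sub))
  defective <- FALSE
  if (is.complex(e$vectors) || TRUE) {
    # rank check of the eigenvector matrix; a defective matrix cannot be
    # diagonalised and the spectral decay story only holds approximately
    sv <- svd(e$vectors, nu = 0, nv = 0)$d
    defective <- (sv[length(sv)] / sv[1]) < 1e-10
  }
  structure(
    list(eigenvalues = if (all(Im(lam) == 0)) Re(lam) else lam,
         timescales = taus,
         relaxation_time = taus[1],
         defective = defective),
    class = "spectral_summary"
  )
}

#' @export
print.spectral_summary <- function(x, ...) {
  cat(sprintf("<spectral_summary> %d eigenvalues, relaxation time tau_1 = %.6g%s\n",
              length(x$eigenvalues), x$relaxation_time,
              if (x$defective) " [defective matrix]" else ""))
  invisible(x)
}

#' Time-reversed chain
#'
#' `P^-_{ij} = pi_j P_{ji} / pi_i`, the transition matrix of the process run
#' backward in time at stationarity. For reversible chains (both built-ins)
#' the reversed matrix equals the forward one; in general it differs but
#' shares the stationary distribution. Double reversal returns the original
#' matrix.
#'
#' @param chain a [markov_chain()] with a unique, strictly positive
#'   stationary distribution.
#' @return A [markov_chain()] (topology label preserved).
#' @export
reverse_chain <- function(chain) {
  stopifnot(inherits(chain, "markov_chain"))
  pi <- stationary_distribution(chain)
  if (any(pi <= 0)) {
    stop("time reversal requires strictly positive stationary mass on every state",
         call. = FALSE)
  }
  Prev <- t(chain$P * pi) / pi   # element [i,j] = pi_j P[j,i] / pi_i
  Prev <- Prev / rowSums(Prev)   # remove O(eps) rounding drift
  markov_chain(Prev, topology = chain$topology)
}

# ---- serialization ---------------------------------------------------------

#' Read and write chains as JSON or CSV
#'
#' JSON documents store `n`, `topology_label` and the transition matrix as
#' nested row-major arrays. CSV files are header-free, one row per state, and
#' load as `custom` topology.
#'
#' @param chain a [markov_chain()].
#' @param path file path.
#' @return `write_chain_json()` returns `path` invisibly; the readers return
#'   a [markov_chain()].
#' @export
write_chain_json <- function(chain, path) {
  stopifnot(inherits(chain, "markov_chain"))
  doc <- list(
    n = chain$n,
    topology_label = chain$topology,
    transition = apply(unname(chain$P), 1, function(r) r, simplify = FALSE)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_chain_json
#' @export
read_chain_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  P <- doc$transition
  if (is.list(P)) P <- do.call(rbind, P)
  markov_chain(as.matrix(P), topology = doc$topology_label)
}

#' @rdname write_chain_json
#' @export
read_chain_csv <- function(path) {
  P <- as.matrix(read.csv(path, header = FALSE))
  dimnames(P) <- NULL
  markov_chain(P, topology = "custom")
}
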