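#' Discretized mutation-rate grid
#'
#' Equally spaced mutation-rate classes, inclusive of both endpoints. The
#' default (15 classes on \[0, 0.25\]) is the grid used for immunoglobulin
#' data in discretized (DB) mode.
#'
#' @param k number of classes.
#' @param min_rate,max_rate grid endpoints.
#' @return numeric vector of length `k`.
#' @export
db_rate_grid <- function(k = 15L, min_rate = 0, max_rate = 0.25) {
  if (k < 1L) stop("k must be >= 1")
  if (k == 1L) return(max_rate)
  seq(min_rate, max_rate, length.out = k)
}

#' Chimera HMM configuration
#'
#' @param psi per-column probability of switching to a (chimeric state of a)
#'   different reference.
#' @param mu per-column probability of switching to a different mutation-rate
#'   class of the same reference; must be 0 when only one rate class is used.
#' @param rates strictly increasing mutation-rate classes, each in \[0, 1).
#' @param method "DB" (shared discrete rate grid) or "BW" (per-reference rates
#'   fitted by Baum-Welch; see [fit_bw()]).
#' @param threshold posterior probability at or above which a query is called
#'   chimeric.
#' @param viterbi whether downstream pipelines should compute Viterbi
#'   segmentations for every query rather than only for called chimeras.
#' @param rate_matrix optional N x K matrix of per-reference rates overriding
#'   `rates` (used by the BW mode).
#' @return a `model_config` list.
#' @export
model_config <- function(psi = 1e-4, mu = 1e-3, rates = db_rate_grid(),
                         method = c("DB", "BW"), threshold = 0.95,
                         viterbi = FALSE, rate_matrix = NULL) {
  method <- match.arg(method)
  if (psi < 0 || mu < 0 || psi + mu >= 1)
    stop("require psi >= 0, mu >= 0 and psi + mu < 1")
  rates <- as.numeric(rates)
  if (length(rates) < 1L) stop("need at least one mutation-rate class")
  if (any(rates < 0 | rates >= 1)) stop("rates must lie in [0, 1)")
  if (length(rates) > 1L && any(diff(rates) <= 0))
    stop("rates must be strictly increasing")
  if (length(rates) == 1L && mu != 0)
    stop("mu must be 0 when there is a single rate class")
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  structure(list(psi = psi, mu = mu, rates = rates, method = method,
                 threshold = threshold, viterbi = viterbi,
                 rate_matrix = rate_matrix),
            class = "model_config")
}

#' Build the 2NK state space
#'
#' One state per (reference, rate class, chimeric label). Layout (1-based
#' index i): `i = class*N*K + (r-1)*K + k` with class 0 = non-chimeric (U) and
#' class 1 = chimeric (C), so states 1..NK are U and NK+1..2NK are C.
#'
#' @param msa a `reference_msa`.
#' @param config a `model_config`.
#' @return a `state_space` with per-state vectors `ref`, `rate_class`,
#'   `chimeric`, plus `N`, `K`, `n_states`.
#' @export
build_state_space <- function(msa, config) {
  N <- msa$N
  K <- length(config$rates)
  if (!is.null(config$rate_matrix)) K <- ncol(as.matrix(config$rate_matrix))
  NK <- N * K
  idx <- seq_len(2L * NK)
  structure(list(
    N = N, K = K, n_states = 2L * NK,
    ref = ((idx - 1L) %% NK) %/% K + 1L,
    rate_class = (idx - 1L) %% K + 1L,
    chimeric = (idx - 1L) %/% NK == 1L,
    names = msa$names), class = "state_space")
}

#' @export
print.state_space <- function(x, ...) {
  cat("state_space: N=", x$N, " references x K=", x$K,
      " rate classes x {U,C} = ", x$n_states, " states\n", sep = "")
  invisible(x)
}

#' State index for (reference, rate class, chimeric label)
#' @param space a `state_space`.
#' @param r reference index (1-based).
#' @param k rate class (1-based).
#' @param chimeric logical.
#' @return 1-based state index.
#' @export
state_index <- function(space, r, k, chimeric = FALSE) {
  as.integer(chimeric) * space$N * space$K + (r - 1L) * space$K + k
}

#' States sharing a state's reference and chimeric label (the set R(i))
#' @param space a `state_space`.
#' @param i state index.
#' @return integer vector of K state indices.
#' @export
R_states <- function(space, i) {
  which(space$ref == space$ref[i] & space$chimeric == space$chimeric[i])
}

#' All states of a state's reference, either label (the set R*(j))
#' @param space a `state_space`.
#' @param j state index.
#' @return integer vector of 2K state indices.
#' @export
Rstar_states <- function(space, j) {
  which(space$ref == space$ref[j])
}

#' Switching rate seen by a target state: 0 into U, psi into C
#' @param space a `state_space`.
#' @param j state index (vectorized).
#' @param psi configured switching rate.
#' @return numeric vector.
#' @export
psi_star <- function(space, j, psi) {
  ifelse(space$chimeric[j], psi, 0)
}

#' Per-column emission probability
#'
#' `1 - m` for a matching base, `m/3` for a mismatching base, and 1 when the
#' observation is '-' or N (emission-neutral). A reference gap opposite a
#' query base is scored as a mismatch (`m/3`).
#'
#' @param state_nt reference symbol in \{A,C,G,T,-\}.
#' @param obs observed symbol in \{A,C,G,T,-,N\}.
#' @param m mutation rate in \[0, 1).
#' @return numeric probability (vectorized over the arguments).
#' @export
emission_prob <- function(state_nt, obs, m) {
  n <- max(length(state_nt), length(obs), length(m))
  state_nt <- rep_len(state_nt, n); obs <- rep_len(obs, n); m <- rep_len(m, n)
  if (any(!state_nt %in% c(DNA_BASES4, "-")))
    stop("state_nt must be in {A,C,G,T,-}")
  if (any(!obs %in% c(DNA_BASES4, "-", "N")))
    stop("obs must be in {A,C,G,T,-,N}")
  if (any(m < 0 | m >= 1)) stop("m must be in [0, 1)")
  ifelse(obs %in% c("-", "N"), 1,
         ifelse(obs == state_nt, 1 - m, m / 3))
}

#' Transition probability between two states
#'
#' `1 - psi - mu` for self transitions; `mu/(K-1)` between rate classes of the
#' same reference and chimeric label; `psi/((N-1)K)` into a chimeric state of
#' a different reference; 0 otherwise (in particular, non-chimeric states of a
#' different reference are unreachable, which is what makes the terminal
#' chimeric/non-chimeric split meaningful).
#'
#' @param i,j state indices (vectorized).
#' @param space a `state_space`.
#' @param config a `model_config`.
#' @return numeric probability.
#' @export
transition_prob <- function(i, j, space, config) {
  n <- max(length(i), length(j))
  i <- rep_len(as.integer(i), n); j <- rep_len(as.integer(j), n)
  N <- space$N; K <- space$K
  same_ref <- space$ref[i] == space$ref[j]
  same_cls <- space$chimeric[i] == space$chimeric[j]
  out <- numeric(n)
  # vacuous branches (single reference / single rate class) fold their mass
  # back into the self transition so rows always sum to 1
  out[i == j] <- 1 - (if (N > 1L) config$psi else 0) -
    (if (K > 1L) config$mu else 0)
  w <- i != j & same_ref & same_cls
  if (K > 1L) out[w] <- config$mu / (K - 1L)
  w <- !same_ref & space$chimeric[j]
  if (N > 1L) out[w] <- config$psi / ((N - 1L) * K)
  out
}

#' Forward pass in time linear in the number of states
#'
#' Computes the scaled Forward lattice with the structured-transition
#' rearrangement: per column, only the global sum, the same-class
#' same-reference sums and the both-class same-reference sums are needed, so
#' per-column work is O(NK) instead of O((NK)^2). The posterior probability of
#' chimerism is the chimeric share of the final column.
#'
#' @param q a threaded query (list with `obs`), a character vector/string over
#'   \{A,C,G,T,-,N\}, or an integer code vector.
#' @param msa a `reference_msa`.
#' @param config a `model_config`.
#' @param space optional `state_space` (rebuilt if omitted).
#' @param keep_alpha if `TRUE` the scaled alpha lattice (L x 2NK) is returned,
#'   as needed by [accumulate_stats()].
#' @return a `forward_result`: `log_evidence`, `log_chimeric_mass`,
#'   `posterior`, `scale_factors` (per-column scaling constants whose product
#'   is the likelihood), `n_ops`, and optionally `alpha`.
#' @export
forward_linear <- function(q, msa, config, space = NULL, keep_alpha = FALSE) {
  obs <- as_obs_codes(q, msa$L)
  rm <- rates_matrix(config, msa$N)
  res <- cpp_forward(obs, msa$codes, rm, config$psi, config$mu, keep_alpha)
  structure(res, class = "forward_result")
}

#' @export
print.forward_result <- function(x, ...) {
  cat("forward_result: posterior P(chimera|O) = ",
      format(x$posterior, digits = 6),
      ", log evidence = ", format(x$log_evidence, digits = 8), "\n", sep = "")
  invisible(x)
}

as_obs_codes <- function(q, L) {
  obs <- if (is.list(q)) q$obs else q
  if (is.character(obs)) obs <- encode_obs(obs)
  obs <- as.integer(obs)
  if (length(obs) != L)
    stop("observation has length ", length(obs), " but the MSA has ", L,
         " columns")
  if (any(obs < 0L | obs > 4L)) stop("observation codes must be in 0..4")
  obs
}

#' Dense quadratic Forward pass (oracle)
#'
#' Reference implementation using the full 2NK x 2NK transition matrix and the
#' textbook scaled recursion; O(L (NK)^2). Intended for small instances and as
#' an independent cross-check of [forward_linear()].
#'
#' @inheritParams forward_linear
#' @return a `forward_result` with the same fields as [forward_linear()].
#' @export
forward_quadratic_oracle <- function(q, msa, config, space = NULL) {
  if (is.null(space)) space <- build_state_space(msa, config)
  obs <- as_obs_codes(q, msa$L)
  S <- space$n_states
  NK <- space$N * space$K
  A <- outer(seq_len(S), seq_len(S),
             function(i, j) transition_prob(i, j, space, config))
  rm <- rates_matrix(config, msa$N)
  m_of_state <- rm[cbind(space$ref, space$rate_class)]
  emis_col <- function(t) {
    if (obs[t] == 4L) return(rep(1, S))
    refc <- msa$codes[space$ref, t]
    ifelse(refc == obs[t], 1 - m_of_state, m_of_state / 3)
  }
  pi0 <- c(rep(1 / NK, NK), rep(0, NK))
  a <- pi0 * emis_col(1L)
  cs <- numeric(msa$L)
  cs[1L] <- sum(a)
  if (cs[1L] <= 0) stop("forward pass degenerate: zero total likelihood at column 1")
  a <- a / cs[1L]
  for (t in seq_len(msa$L)[-1L]) {
    a <- as.vector(a %*% A) * emis_col(t)
    cs[t] <- sum(a)
    if (cs[t] <= 0)
      stop("forward pass degenerate: zero total likelihood at column ", t)
    a <- a / cs[t]
  }
  post <- min(max(sum(a[(NK + 1L):S]), 0), 1)
  structure(list(
    log_evidence = sum(log(cs)),
    log_chimeric_mass = if (post > 0) sum(log(cs)) + log(post) else -Inf,
    posterior = post, scale_factors = cs, n_ops = as.numeric(msa$L) * S * S),
    class = "forward_result")
}

# Dense log-space Viterbi oracle; argmax scanned in ascending state order so
# ties resolve to the lowest predecessor index.
viterbi_dense <- function(q, msa, config, space = NULL) {
  if (is.null(space)) space <- build_state_space(msa, config)
  obs <- as_obs_codes(q, msa$L)
  S <- space$n_states
  NK <- space$N * space$K
  A <- outer(seq_len(S), seq_len(S),
             function(i, j) transition_prob(i, j, space, config))
  logA <- log(A)
  rm <- rates_matrix(config, msa$N)
  m_of_state <- rm[cbind(space$ref, space$rate_class)]
  emis_col <- function(t) {
    if (obs[t] == 4L) return(rep(1, S))
    refc <- msa$codes[space$ref, t]
    ifelse(refc == obs[t], 1 - m_of_state, m_of_state / 3)
  }
  d <- log(c(rep(1 / NK, NK), rep(0, NK))) + log(emis_col(1L))
  bp <- matrix(NA_integer_, msa$L, S)
  for (t in seq_len(msa$L)[-1L]) {
    cand <- d + logA                      # cand[i, j]
    best <- apply(cand, 2L, which.max)    # first max = lowest index
    d <- cand[cbind(best, seq_len(S))] + log(emis_col(t))
    bp[t, ] <- best
  }
  end <- which.max(d)
  path <- integer(msa$L)
  path[msa$L] <- end
  for (t in rev(seq_len(msa$L)[-1L])) path[t - 1L] <- bp[t, path[t]]
  list(path = path, log_path_prob = d[end])
}

#' Viterbi segmentation in time linear in the number of states
#'
#' Max-product analogue of [forward_linear()]: per column, per-group maxima
#' (same reference and label over rate classes; best state per reference; best
#' pair of states from distinct references) replace the sums, so the best
#' predecessor of every state is an O(1) lookup. Predecessor ties break toward
#' the lowest state index, making the reported path deterministic inside
#' homology tracts where the switch column is ambiguous.
#'
#' @inheritParams forward_linear
#' @return a `viterbi_result`: `segments` (data.frame of reference,
#'   rate_class, start, end in MSA columns), `breakpoints` (first column of
#'   each new reference), `log_path_prob`, and `path` (1-based state indices).
#' @export
viterbi_linear <- function(q, msa, config, space = NULL) {
  if (is.null(space)) space <- build_state_space(msa, config)
  obs <- as_obs_codes(q, msa$L)
  rm <- rates_matrix(config, msa$N)
  res <- cpp_viterbi(obs, msa$codes, rm, config$psi, config$mu)
  decode_viterbi(res$path, res$log_path_prob, msa, space)
}

decode_viterbi <- function(path, log_path_prob, msa, space) {
  refs <- space$ref[path]
  ks <- space$rate_class[path]
  seg_id <- cumsum(c(1L, as.integer(diff(refs) != 0L | diff(ks) != 0L)))
  starts <- which(!duplicated(seg_id))
  ends <- c(starts[-1L] - 1L, length(path))
  segments <- data.frame(
    reference = msa$names[refs[starts]],
    rate_class = ks[starts],
    start = starts, end = ends,
    stringsAsFactors = FALSE)
  breakpoints <- which(diff(refs) != 0L) + 1L
  structure(list(segments = segments, breakpoints = breakpoints,
                 log_path_prob = log_path_prob, path = path),
            class = "viterbi_result")
}

#' @export
print.viterbi_result <- function(x, ...) {
  cat("viterbi_result: ", nrow(x$segments), " segment(s), ",
      length(x$breakpoints), " reference breakpoint(s)\n", sep = "")
  print(x$segments)
  invisible(x)
}

#' Binary chimera call from a forward result
#'
#' @param result a `forward_result` (or anything with `$posterior`).
#' @param config a `model_config` carrying the threshold.
#' @return `TRUE` iff posterior >= threshold.
#' @export
chimera_call <- function(result, config) {
  result$posterior >= config$threshold
}
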