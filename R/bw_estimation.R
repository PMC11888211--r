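#' Baum-Welch configuration
#'
#' @param init_rate starting mutation rate for every reference.
#' @param max_iter maximum EM iterations.
#' @param tol stop when the total log-likelihood improves by less than this.
#' @param rate_floor,rate_ceiling clamps applied after each M-step.
#' @return a `bw_config` list.
#' @export
bw_config <- function(init_rate = 0.05, max_iter = 10L, tol = 1e-3,
                      rate_floor = 1e-6, rate_ceiling = 0.3) {
  if (init_rate <= 0 || init_rate >= 1) stop("init_rate must be in (0, 1)")
  if (rate_floor >= rate_ceiling) stop("rate_floor must be below rate_ceiling")
  if (max_iter < 1L) stop("max_iter must be >= 1")
  structure(list(init_rate = init_rate, max_iter = as.integer(max_iter),
                 tol = tol, rate_floor = rate_floor,
                 rate_ceiling = rate_ceiling), class = "bw_config")
}

#' Scaled backward pass in time linear in the number of states
#'
#' Uses the transposed form of the structured-transition decomposition
#' (outgoing mass splits into self, same-reference other-rate, and
#' cross-reference-into-chimeric terms) and the forward scale factors, so that
#' `sum_i alpha_t(i) beta_t(i) == 1` at every column.
#'
#' @inheritParams forward_linear
#' @param scale_factors forward scaling constants; computed via
#'   [forward_linear()] if omitted.
#' @return L x 2NK matrix of scaled beta values, with the `forward_result`
#'   used for scaling attached as attribute `forward`.
#' @export
backward_linear <- function(q, msa, config, space = NULL, scale_factors = NULL) {
  obs <- as_obs_codes(q, msa$L)
  rm <- rates_matrix(config, msa$N)
  fwd <- NULL
  if (is.null(scale_factors)) {
    fwd <- forward_linear(obs, msa, config, keep_alpha = TRUE)
    scale_factors <- fwd$scale_factors
  }
  beta <- cpp_backward(obs, msa$codes, rm, config$psi, config$mu, scale_factors)
  attr(beta, "forward") <- fwd
  beta
}

#' Accumulate Baum-Welch sufficient statistics for one query
#'
#' Posterior state occupancies `gamma_t(i)`, proportional to
#' `alpha_t(i) beta_t(i)` and normalized per column, are pooled over the two
#' chimeric labels of each reference. Columns where the observation is '-' or
#' N are emission-neutral and contribute nothing.
#'
#' @param q query (as in [forward_linear()]).
#' @param forward a `forward_result` with `keep_alpha = TRUE`.
#' @param backward the matching scaled beta matrix from [backward_linear()].
#' @param msa a `reference_msa`.
#' @param space a `state_space`.
#' @return a `sufficient_stats` list with per-reference numeric vectors
#'   `mismatches` and `emissions`.
#' @export
accumulate_stats <- function(q, forward, backward, msa, space) {
  if (is.null(forward$alpha))
    stop("forward result must be computed with keep_alpha = TRUE")
  obs <- as_obs_codes(q, msa$L)
  gam <- forward$alpha * backward
  gam <- gam / rowSums(gam)
  mism <- numeric(msa$N)
  emis <- numeric(msa$N)
  informative <- obs != 4L
  for (r in seq_len(msa$N)) {
    idx <- which(space$ref == r)
    g <- rowSums(gam[, idx, drop = FALSE])
    emis[r] <- sum(g[informative])
    mm <- informative & msa$codes[r, ] != obs
    mism[r] <- sum(g[mm])
  }
  structure(list(mismatches = mism, emissions = emis, names = msa$names),
            class = "sufficient_stats")
}

#' M-step: re-estimate per-reference mutation rates
#'
#' `rate_r = mismatches_r / emissions_r`, clamped to
#' \[`rate_floor`, `rate_ceiling`\]; references with no informative emission
#' mass keep their previous rate.
#'
#' @param stats a `sufficient_stats`.
#' @param prev_rates previous per-reference rates.
#' @param bw a `bw_config`.
#' @return numeric vector of per-reference rates.
#' @export
reestimate_rates <- function(stats, prev_rates, bw = bw_config()) {
  rates <- ifelse(stats$emissions > 0,
                  stats$mismatches / pmax(stats$emissions, .Machine$double.eps),
                  prev_rates)
  pmin(pmax(rates, bw$rate_floor), bw$rate_ceiling)
}

#' Fit the Baum-Welch variant (two states per reference)
#'
#' EM over the whole dataset: each E-step runs the scaled forward-backward
#' pass for every query and accumulates per-reference expected mismatch and
#' emission counts; each M-step sets the rates to their ratio. `psi` is a user
#' prior and is never re-estimated; with a single rate class per reference,
#' `mu` is vacuous and fixed at 0. The total log-likelihood is non-decreasing
#' across iterations.
#'
#' @param queries integer code matrix (L x n, as from [thread_queries()]) or a
#'   list of threaded queries.
#' @param msa a `reference_msa`.
#' @param bw a `bw_config`.
#' @param psi per-column reference-switching rate.
#' @return a `bw_fit`: `rates` (per reference), `loglik` (trace, one entry per
#'   E-step), `posteriors` (per query, under the fitted rates), `converged`,
#'   and `iterations`.
#' @export
fit_bw <- function(queries, msa, bw = bw_config(), psi = 1e-4) {
  obs_codes <- as_obs_matrix(queries, msa$L)
  if (ncol(obs_codes) == 0L) stop("empty query list")
  rates <- rep(bw$init_rate, msa$N)
  ll <- numeric(0)
  es <- NULL
  converged <- FALSE
  for (it in seq_len(bw$max_iter)) {
    es <- cpp_bw_estep(obs_codes, msa$codes, rates, psi)
    ll <- c(ll, es$loglik)
    if (it > 1L && ll[it] - ll[it - 1L] < bw$tol) {
      converged <- TRUE
      break
    }
    stats <- structure(list(mismatches = es$mismatches,
                            emissions = es$emissions, names = msa$names),
                       class = "sufficient_stats")
    rates <- reestimate_rates(stats, rates, bw)
  }
  if (!converged) {
    # rates moved after the last recorded E-step: refresh posteriors under them
    es <- cpp_bw_estep(obs_codes, msa$codes, rates, psi)
    ll <- c(ll, es$loglik)
  }
  structure(list(rates = setNames(rates, msa$names), loglik = ll,
                 posteriors = es$posteriors, converged = converged,
                 iterations = length(ll)), class = "bw_fit")
}

#' @export
print.bw_fit <- function(x, ...) {
  cat("bw_fit: ", length(x$rates), " reference rates, ",
      x$iterations, " E-step(s), final log-likelihood ",
      format(tail(x$loglik, 1L), digits = 10),
      if (x$converged) " (converged)" else " (max_iter reached)", "\n",
      sep = "")
  invisible(x)
}

as_obs_matrix <- function(queries, L) {
  if (is.matrix(queries)) {
    storage.mode(queries) <- "integer"
    if (nrow(queries) != L)
      stop("observation matrix has ", nrow(queries), " rows but the MSA has ",
           L, " columns")
    return(queries)
  }
  if (is.list(queries) && !is.null(queries$obs_codes))
    return(as_obs_matrix(queries$obs_codes, L))
  if (is.list(queries)) {
    cols <- lapply(queries, as_obs_codes, L = L)
    return(matrix(unlist(cols), nrow = L))
  }
  stop("queries must be an integer code matrix or a list of threaded queries")
}
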