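#' Configuration for the Bernoulli mixture sampler
#'
#' Collects the prior hyperparameters and MCMC settings of the collapsed
#' Bernoulli mixture model. Per-cluster per-subject success probabilities
#' carry a Beta(`beta_a`, `beta_b`) prior and the mixture weights a
#' symmetric Dirichlet(`gamma`) prior, both integrated out analytically; the
#' number of mixture components K carries either a truncated Poisson(1)
#' prior (default) or a uniform prior on 1..`Kmax`.
#'
#' @param Kmax maximum number of mixture components; defaults to
#'   `min(25, n_items - 1)` at fit time when left `NULL`.
#' @param beta_a,beta_b Beta prior hyperparameters (default 1, 1).
#' @param gamma symmetric Dirichlet concentration on weights (default 1).
#' @param k_prior prior on K: `"poisson"` (truncated Poisson, rate
#'   `poisson_rate`) or `"uniform"`.
#' @param poisson_rate rate of the truncated Poisson prior (default 1).
#' @param n_chains number of Metropolis-coupled chains (default 4);
#'   `n_chains = 1` degrades gracefully to the plain allocation sampler.
#' @param delta temperature spacing; chain c runs at inverse temperature
#'   `1 / (1 + delta * (c - 1))` (default 0.15).
#' @param n_sweeps total sweeps (default 10000).
#' @param burn_in fraction of sweeps discarded (default 0.5).
#' @param thin keep every `thin`-th post-burn-in sweep (default 1).
#' @param seed RNG seed; when `NULL` the current RNG state is used.
#' @param moves move families to run each sweep, any of
#'   `c("gibbs", "m1", "m2", "m3", "ejab")`; all on by default.
#' @return a `mixture_config` list.
#' @export
mixture_config <- function(Kmax = NULL, beta_a = 1, beta_b = 1, gamma = 1,
                           k_prior = c("poisson", "uniform"),
                           poisson_rate = 1,
                           n_chains = 4, delta = 0.15,
                           n_sweeps = 10000, burn_in = 0.5, thin = 1,
                           seed = NULL,
                           moves = c("gibbs", "m1", "m2", "m3", "ejab")) {
  k_prior <- match.arg(k_prior)
  stopifnot(
    is.null(Kmax) || Kmax >= 1,
    beta_a > 0, beta_b > 0, gamma > 0, delta > 0,
    n_chains >= 1, n_sweeps >= 1, burn_in >= 0, burn_in < 1, thin >= 1
  )
  moves <- match.arg(moves, several.ok = TRUE)
  structure(
    list(
      Kmax = Kmax, beta_a = beta_a, beta_b = beta_b, gamma = gamma,
      k_prior = k_prior, poisson_rate = poisson_rate,
      n_chains = as.integer(n_chains), delta = delta,
      n_sweeps = as.integer(n_sweeps), burn_in = burn_in,
      thin = as.integer(thin), seed = seed, moves = moves
    ),
    class = "mixture_config"
  )
}

# log prior mass of K = 1..Kmax
log_k_prior <- function(config, Kmax) {
  if (config$k_prior == "uniform") {
    rep(-log(Kmax), Kmax)
  } else {
    lp <- dpois(seq_len(Kmax), config$poisson_rate, log = TRUE)
    lp - log(sum(exp(lp - max(lp))) ) - max(lp)
  }
}

resolve_kmax <- function(config, n_items) {
  if (!is.null(config$Kmax)) return(as.integer(config$Kmax))
  max(1L, min(25L, n_items - 1L))
}

# coerce clustering input to a complete 0/1 integer matrix, items as rows
as_item_matrix <- function(data) {
  if (inherits(data, "binary_panel")) {
    data <- t(panel_matrix(data))
  }
  data <- as.matrix(data)
  if (anyNA(data)) {
    stop("clustering needs a complete matrix: restrict to responders and active components first")
  }
  if (!all(data %in% c(0, 1))) stop("data must be 0/1")
  storage.mode(data) <- "integer"
  if (is.null(rownames(data))) {
    rownames(data) <- sprintf("item%02d", seq_len(nrow(data)))
  }
  data
}

#' Collapsed log marginal likelihood of one cluster
#'
#' The Beta-Bernoulli collapse: for a cluster of `n_k` items whose
#' per-subject positive counts are `positives`, the log marginal likelihood
#' is `sum_j log B(a + s_j, b + n_k - s_j) - log B(a, b)`, additive over
#' subjects.
#'
#' @param positives per-subject positive counts within the cluster.
#' @param n_k cluster size (number of items).
#' @param beta_a,beta_b Beta prior hyperparameters.
#' @return log marginal likelihood (0 for an empty cluster).
#' @export
log_marginal_cluster <- function(positives, n_k, beta_a = 1, beta_b = 1) {
  stopifnot(all(positives >= 0), all(positives <= n_k))
  if (n_k == 0) return(0)
  sum(lbeta(beta_a + positives, beta_b + n_k - positives) -
    lbeta(beta_a, beta_b))
}

#' Collapsed log prior of an allocation vector
#'
#' Dirichlet mixture weights integrated out:
#' `Gamma(K g) / Gamma(n + K g) * prod_k Gamma(m_k + g) / Gamma(g)`.
#' Summing the exponential over all `K^n` allocations yields 1.
#'
#' @param z allocation vector with labels in `1..K`.
#' @param K number of mixture components (empty labels allowed).
#' @param gamma Dirichlet concentration.
#' @return log prior mass of `z` given `K`.
#' @export
log_allocation_prior <- function(z, K, gamma = 1) {
  stopifnot(all(z >= 1), all(z <= K))
  n <- length(z)
  m <- tabulate(z, nbins = K)
  lgamma(K * gamma) - lgamma(n + K * gamma) +
    sum(lgamma(m + gamma) - lgamma(gamma))
}

#' Collapsed log posterior of an allocation state
#'
#' Up to the shared normalizing constant: cluster marginal likelihoods plus
#' the collapsed allocation prior plus the prior on K. Exactly invariant
#' under permutations of cluster labels.
#'
#' @param z allocation vector over items (rows of `data`).
#' @param K number of mixture components.
#' @param data complete 0/1 matrix, items as rows, subjects as columns
#'   (or a binary panel, which is transposed).
#' @param config a [mixture_config()].
#' @return unnormalized log posterior.
#' @export
log_collapsed_posterior <- function(z, K, data, config = mixture_config()) {
  data <- as_item_matrix(data)
  stopifnot(length(z) == nrow(data))
  Kmax <- max(K, resolve_kmax(config, nrow(data)))
  lpk <- log_k_prior(config, Kmax)
  lik <- sum(vapply(seq_len(K), function(k) {
    rows <- data[z == k, , drop = FALSE]
    log_marginal_cluster(colSums(rows), nrow(rows), config$beta_a, config$beta_b)
  }, numeric(1)))
  lpk[K] + log_allocation_prior(z, K, config$gamma) + lik
}

state_from <- function(z, K, log_post = NA_real_) {
  list(z = as.integer(z), K = as.integer(K), log_post = log_post)
}

moves_mask <- function(moves) {
  c("gibbs", "m1", "m2", "m3", "ejab") %in% moves
}

run_step <- function(state, data, config, moves, beta = 1) {
  data <- as_item_matrix(data)
  Kmax <- resolve_kmax(config, nrow(data))
  Kmax <- max(Kmax, state$K)
  out <- .bmm_step_cpp(
    data, state$z, state$K, Kmax,
    config$beta_a, config$beta_b, config$gamma,
    log_k_prior(config, Kmax), beta, moves_mask(moves)
  )
  state_from(out$z, out$K, out$log_post)
}

#' One full-conditional Gibbs sweep
#'
#' Reallocates every item in turn from its full conditional over the current
#' `1..K` labels (K unchanged). The returned `log_post` is maintained
#' incrementally and agrees with [log_collapsed_posterior()] recomputation.
#'
#' @param state list with `z` (allocation) and `K`.
#' @param data 0/1 item matrix or binary panel.
#' @param config a [mixture_config()].
#' @return updated state list (`z`, `K`, `log_post`).
#' @export
gibbs_sweep <- function(state, data, config = mixture_config()) {
  run_step(state, data, config, "gibbs")
}

#' One round of Metropolis block moves
#'
#' Three fixed-K Metropolis-Hastings moves on the collapsed posterior:
#' a random subset swap between two clusters, a binomial mass reallocation
#' of one cluster into another, and a sequential reshuffle of two clusters
#' from their restricted full conditionals. No-ops when `K < 2`.
#'
#' @inheritParams gibbs_sweep
#' @return updated state list.
#' @export
metropolis_moves <- function(state, data, config = mixture_config()) {
  run_step(state, data, config, c("m1", "m2", "m3"))
}

#' One trans-dimensional eject/absorb move
#'
#' With probability 1/2 ejects a binomial subset of a random cluster into a
#' new mixture component (blocked at `Kmax`), otherwise absorbs the
#' top-labelled component into another (blocked at `K = 1`); accepted by
#' Metropolis-Hastings including the prior on K and proposal terms.
#'
#' @inheritParams gibbs_sweep
#' @return updated state list.
#' @export
eject_absorb <- function(state, data, config = mixture_config()) {
  run_step(state, data, config, "ejab")
}

#' Fit the Bernoulli mixture by Metropolis-coupled MCMC
#'
#' Runs `n_chains` tempered copies of the allocation sampler (inverse
#' temperatures `1 / (1 + delta * (c - 1))`), each executing the full move
#' schedule per sweep (Gibbs sweep, three Metropolis block moves, one
#' eject/absorb), with one adjacent-pair state swap attempted per sweep.
#' Only cold-chain draws are retained. Fully reproducible given
#' `config$seed`.
#'
#' @param data complete 0/1 matrix with the clustered items as rows
#'   (allergen components) and subjects as columns, or a binary panel
#'   (transposed internally; must already be restricted to active
#'   components and responder subjects).
#' @param config a [mixture_config()].
#' @return a `bmm_chain` object: `draws` tibble (`sweep`, `K`, `log_post`),
#'   `z` integer matrix of retained allocations (draws x items),
#'   `item_ids`, `config` (with `Kmax` resolved), and `diagnostics`
#'   (per-move acceptance counts, per-pair swap rates).
#' @export
mc3_run <- function(data, config = mixture_config()) {
  data <- as_item_matrix(data)
  n <- nrow(data)
  Kmax <- resolve_kmax(config, n)
  if (!is.null(config$seed)) set.seed(config$seed)
  betas <- 1 / (1 + config$delta * (seq_len(config$n_chains) - 1))
  n_burn <- floor(config$n_sweeps * config$burn_in)
  res <- .mc3_run_cpp(
    data, Kmax, config$beta_a, config$beta_b, config$gamma,
    log_k_prior(config, Kmax), betas,
    config$n_sweeps, n_burn, config$thin, moves_mask(config$moves)
  )
  z <- res$z
  colnames(z) <- rownames(data)
  config$Kmax <- Kmax
  structure(
    list(
      draws = tibble::tibble(
        sweep = res$sweep, K = res$K, log_post = res$log_post
      ),
      z = z,
      item_ids = rownames(data),
      n_subjects = ncol(data),
      config = config,
      diagnostics = list(
        accept = res$accept,
        swap_attempts = res$swap_attempts,
        swap_accepts = res$swap_accepts,
        betas = betas
      )
    ),
    class = "bmm_chain"
  )
}

#' @export
print.bmm_chain <- function(x, ...) {
  cat(
    "Bernoulli mixture allocation chain:",
    nrow(x$draws), "retained draws,",
    length(x$item_ids), "items x", x$n_subjects, "subjects\n"
  )
  pk <- posterior_over_K(x)
  pk <- pk[pk$prob > 0, ]
  cat("posterior over K:\n")
  print(as.data.frame(pk), row.names = FALSE)
  invisible(x)
}

#' Posterior distribution over the number of clusters
#'
#' Empirical frequencies of K among retained cold-chain draws.
#'
#' @param chain a [mc3_run()] result.
#' @param Kmax upper limit of the support (defaults to the fitted `Kmax`).
#' @return tibble with columns `K` (1..Kmax) and `prob` (sums to 1).
#' @export
posterior_over_K <- function(chain, Kmax = chain$config$Kmax) {
  stopifnot(nrow(chain$draws) > 0)
  tab <- tabulate(chain$draws$K, nbins = Kmax)
  tibble::tibble(K = seq_len(Kmax), prob = tab / sum(tab))
}

#' Modal number of clusters
#'
#' The K with the highest posterior mass; ties resolved towards the smaller
#' K (parsimony).
#'
#' @inheritParams posterior_over_K
#' @return integer K*.
#' @export
modal_K <- function(chain, Kmax = chain$config$Kmax) {
  pk <- posterior_over_K(chain, Kmax)
  as.integer(pk$K[which.max(pk$prob)])
}

#' Exact posterior by exhaustive enumeration (small instances)
#'
#' Test oracle: sums the collapsed unnormalized mass over every allocation
#' `z` in `1..K^n` for each `K <= Kmax`. Refuses instances with more than
#' ten million allocations.
#'
#' @param data 0/1 item matrix or binary panel.
#' @param config a [mixture_config()].
#' @return list with `k_prob` (tibble over K), and allocation-level detail:
#'   `K`, `z` (matrix, one allocation per row), `prob`, `log_mass`.
#' @export
exact_posterior_small <- function(data, config = mixture_config()) {
  data <- as_item_matrix(data)
  n <- nrow(data)
  Kmax <- resolve_kmax(config, n)
  if (Kmax^n > 1e7) {
    stop("instance too large for enumeration: Kmax^n = ", Kmax^n, " > 1e7")
  }
  allocs <- list()
  Ks <- integer(0)
  lm <- numeric(0)
  for (K in seq_len(Kmax)) {
    grid <- as.matrix(expand.grid(rep(list(seq_len(K)), n)))[, n:1, drop = FALSE]
    lmK <- apply(grid, 1, function(z) log_collapsed_posterior(z, K, data, config))
    allocs[[K]] <- grid
    Ks <- c(Ks, rep.int(K, nrow(grid)))
    lm <- c(lm, lmK)
  }
  z <- do.call(rbind, allocs)
  mx <- max(lm)
  w <- exp(lm - mx)
  prob <- w / sum(w)
  k_prob <- tibble::tibble(
    K = seq_len(Kmax),
    prob = vapply(seq_len(Kmax), function(k) sum(prob[Ks == k]), numeric(1))
  )
  list(k_prob = k_prob, K = Ks, z = z, prob = prob, log_mass = lm)
}

#' Cluster the active components of a binary panel
#'
#' Convenience wrapper for the per-age analysis: restricts the panel to its
#' active components and responder subjects, transposes it so components are
#' the clustered items, and runs [mc3_run()].
#'
#' @param panel a binary panel.
#' @param config a [mixture_config()].
#' @param min_positive activity rule (default 3).
#' @return a `bmm_chain` (see [mc3_run()]); the restricted item set is in
#'   `item_ids`.
#' @export
cluster_components <- function(panel, config = mixture_config(),
                               min_positive = 3) {
  active <- active_components(panel, min_positive)
  if (length(active) == 0) stop("no active components at this age")
  resp <- responder_subjects(panel, active)
  vals <- panel_matrix(panel)[resp, active, drop = FALSE]
  mc3_run(t(vals), config)
}
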