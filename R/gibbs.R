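rdirichlet_rows <- function(nrow, shape) {
  g <- matrix(rgamma(nrow * length(shape), rep(shape, each = nrow)), nrow)
  sweep(g, 1, rowSums(g), "/")
}

resolve_priors <- function(priors, K0, Ks) {
  list(alpha_pi = if (is.null(priors$alpha_pi)) 1 / K0 else priors$alpha_pi,
       alpha_lambda = if (is.null(priors$alpha_lambda)) 1 / Ks
                      else priors$alpha_lambda,
       alpha_theta = priors$alpha_theta, nu_a = priors$nu_a,
       nu_b = priors$nu_b)
}

resolve_nu_fixed <- function(nu_fixed, S, p) {
  if (is.null(nu_fixed)) return(NULL)
  if (length(nu_fixed) == 1) return(matrix(as.numeric(nu_fixed), S, p))
  nu_fixed <- as.matrix(nu_fixed)
  stopifnot(nrow(nu_fixed) == S, ncol(nu_fixed) == p)
  nu_fixed
}

# flat layout shared with the C++ kernel (last array margin fastest)
flat0 <- function(a) as.vector(aperm(a, rev(seq_along(dim(a)))))

#' Initialize the Gibbs sampler state
#'
#' Two strategies (see [mcmc_config()]):
#' * `"factorized"`: consumption profiles start at observed item marginals —
#'   every global class at a jittered pooled marginal, each subgroup's first
#'   local class at the subgroup marginal (remaining local classes at prior
#'   draws, with the initial local weights concentrated on that first class)
#'   — `nu = 0.5`, indicators `G ~ Bernoulli(0.5)`, `z` uniform at random,
#'   `c` merged into class 1.
#' * `"random"`: weights and profiles drawn from their priors, `z`/`c` drawn
#'   from those weights, `G` all-global, `nu` from its Beta prior.
#'
#' With `nu_fixed` set, `nu` starts (and stays) frozen.
#'
#' @param data A [consumption_matrix()].
#' @param priors An [rpc_priors()].
#' @param config An [mcmc_config()].
#' @return An `rpc_state` list with fields `pi`, `lam`, `theta0`, `theta1`,
#'   `nu`, `z`, `c`, `G`.
#' @export
init_state <- function(data, priors = rpc_priors(), config = mcmc_config()) {
  K0 <- config$K0_max; Ks <- config$Ks_max
  S <- data$S; p <- data$p; d <- data$d; n <- data$n
  pr <- resolve_priors(priors, K0, Ks)
  nu_fixed <- resolve_nu_fixed(config$nu_fixed, S, p)

  if (identical(config$init %||% "factorized", "factorized")) {
    marg <- function(y) {
      tab <- tabulate(y, d)
      (tab + 0.5) / sum(tab + 0.5)
    }
    theta0 <- array(0, c(K0, p, d))
    theta1 <- array(0, c(S, Ks, p, d))
    for (j in seq_len(p)) {
      m <- marg(data$y[, j])
      for (h in seq_len(K0)) {
        r <- m * exp(stats::rnorm(d, 0, 0.1))
        theta0[h, j, ] <- r / sum(r)
      }
      for (s in seq_len(S)) {
        theta1[s, 1, j, ] <- marg(data$y[data$subgroup == s, j])
        if (Ks > 1) {
          g <- matrix(rgamma((Ks - 1) * d, pr$alpha_theta), Ks - 1, d)
          theta1[s, -1, j, ] <- g / rowSums(g)
        }
      }
    }
    lam <- matrix(if (Ks > 1) 0.1 / (Ks - 1) else 0, S, Ks)
    lam[, 1] <- if (Ks > 1) 0.9 else 1
    state <- list(
      pi = rep(1 / K0, K0), lam = lam, theta0 = theta0, theta1 = theta1,
      nu = if (is.null(nu_fixed)) matrix(0.5, S, p) else nu_fixed,
      z = sample.int(K0, n, replace = TRUE), c = rep(1L, n),
      G = matrix(rbinom(n * p, 1L, 0.5), n, p))
    return(structure(state, class = "rpc_state"))
  }

  pi0 <- drop(rdirichlet_rows(1, rep(pr$alpha_pi, K0)))
  lam <- rdirichlet_rows(S, rep(pr$alpha_lambda, Ks))
  m0 <- rdirichlet_rows(K0 * p, rep(pr$alpha_theta, d))
  theta0 <- array(0, c(K0, p, d))
  for (r in seq_len(d)) theta0[, , r] <- matrix(m0[, r], K0, p)
  m1 <- rdirichlet_rows(S * Ks * p, rep(pr$alpha_theta, d))
  theta1 <- array(0, c(S, Ks, p, d))
  for (r in seq_len(d)) theta1[, , , r] <- array(m1[, r], c(S, Ks, p))
  nu <- if (is.null(nu_fixed)) matrix(rbeta(S * p, pr$nu_a, pr$nu_b), S, p)
        else nu_fixed
  z <- sample.int(K0, n, replace = TRUE, prob = pi0)
  cc <- integer(n)
  for (s in seq_len(S)) {
    idx <- which(data$subgroup == s)
    cc[idx] <- sample.int(Ks, length(idx), replace = TRUE, prob = lam[s, ])
  }
  structure(list(pi = pi0, lam = lam, theta0 = theta0, theta1 = theta1,
                 nu = nu, z = z, c = cc, G = matrix(1L, n, p)),
            class = "rpc_state")
}

call_kernel <- function(data, state, pr, nu_fixed, n_iter, burn_in, thin,
                        store_G, nu_by_item = FALSE) {
  K0 <- length(state$pi); Ks <- ncol(state$lam)
  rpc_gibbs_cpp(
    y = data$y, s = as.integer(data$subgroup),
    K0 = K0, Ks = Ks, d = data$d, S = data$S,
    pi0 = state$pi, lam0 = as.vector(t(state$lam)),
    theta0_0 = flat0(state$theta0), theta1_0 = flat0(state$theta1),
    nu0 = as.vector(t(state$nu)),
    z0 = as.integer(state$z), c0 = as.integer(state$c),
    G0 = state$G,
    alpha_pi = pr$alpha_pi, alpha_lam = pr$alpha_lambda,
    alpha_theta = pr$alpha_theta, a_nu = pr$nu_a, b_nu = pr$nu_b,
    update_nu = is.null(nu_fixed), nu_by_item = nu_by_item,
    n_iter = n_iter, burn_in = burn_in, thin = thin, store_G = store_G)
}

state_from_kernel <- function(fin, S, Ks, K0, p, d, n) {
  structure(list(
    pi = fin$pi,
    lam = t(matrix(fin$lam, Ks, S)),
    theta0 = aperm(array(fin$theta0, c(d, p, K0)), c(3, 2, 1)),
    theta1 = aperm(array(fin$theta1, c(d, p, Ks, S)), c(4, 3, 2, 1)),
    nu = t(matrix(fin$nu, p, S)),
    z = fin$z, c = fin$c, G = fin$G), class = "rpc_state")
}

#' One full-conditional Gibbs sweep
#'
#' Executes a single sweep of the sampler in its fixed update order:
#' (1) global classes `z`, (2) local classes `c`, (3) indicators `G`,
#' (4) global weights `pi`, (5) local weights `lambda`, (6) global profiles
#' `theta0`, (7) local profiles `theta1`, (8) allocation probabilities `nu`
#' (skipped when `config$nu_fixed` is set).  Empty components receive
#' prior-only Dirichlet draws.  Randomness comes from R's RNG: seed with
#' `set.seed()`.
#'
#' @param state An `rpc_state` (see [init_state()]).
#' @param data A [consumption_matrix()].
#' @param priors An [rpc_priors()].
#' @param nu_fixed Optional scalar or `S x p` matrix freezing `nu`.
#' @return The updated `rpc_state`.
#' @export
gibbs_step <- function(state, data, priors = rpc_priors(), nu_fixed = NULL) {
  K0 <- length(state$pi); Ks <- ncol(state$lam)
  pr <- resolve_priors(priors, K0, Ks)
  nu_fixed <- resolve_nu_fixed(nu_fixed, data$S, data$p)
  if (!is.null(nu_fixed)) state$nu <- nu_fixed
  res <- call_kernel(data, state, pr, nu_fixed, n_iter = 1L, burn_in = 0L,
                     thin = 1L, store_G = FALSE)
  state_from_kernel(res$final, data$S, Ks, K0, data$p, data$d, data$n)
}

#' Run the RPC Gibbs sampler
#'
#' Initializes via [init_state()] and runs `config$n_iter` sweeps, retaining
#' every `config$thin`-th draw after `config$burn_in` together with the
#' subject-specific log-likelihood trace.  Fully reproducible given
#' `config$seed`; the caller's RNG state is restored afterwards.
#'
#' @param data A [consumption_matrix()].
#' @param priors An [rpc_priors()].
#' @param config An [mcmc_config()].
#' @return An `rpc_samples` object: retained draws as arrays with the draw
#'   index first (`pi` `M x K0`, `lam` `M x S x Ks`, `theta0` `M x K0 x p x d`,
#'   `theta1` `M x S x Ks x p x d`, `nu` `M x S x p`, `z`/`c` `M x n`, `G`
#'   `M x n x p` when stored), plus `loglik`, `subgroup`, dimensions, `config`
#'   and `priors`.
#' @export
run_mcmc <- function(data, priors = rpc_priors(), config = mcmc_config()) {
  stopifnot(inherits(data, "consumption_matrix"))
  K0 <- config$K0_max; Ks <- config$Ks_max
  S <- data$S; p <- data$p; d <- data$d; n <- data$n
  pr <- resolve_priors(priors, K0, Ks)
  nu_fixed <- resolve_nu_fixed(config$nu_fixed, S, p)
  M <- (config$n_iter - config$burn_in) %/% config$thin
  stopifnot(M >= 1)

  res <- with_local_seed(config$seed, {
    state <- init_state(data, priors, config)
    call_kernel(data, state, pr, nu_fixed, config$n_iter, config$burn_in,
                config$thin, config$store_G,
                nu_by_item = identical(config$nu_index, "item"))
  })
  if (any(!is.finite(res$loglik)))
    stop("non-finite log-likelihood at retained draw ",
         which(!is.finite(res$loglik))[1], call. = FALSE)

  samples <- list(
    pi = res$pi,
    lam = aperm(array(res$lam, c(M, Ks, S)), c(1, 3, 2)),
    theta0 = aperm(array(res$theta0, c(M, d, p, K0)), c(1, 4, 3, 2)),
    theta1 = aperm(array(res$theta1, c(M, d, p, Ks, S)), c(1, 5, 4, 3, 2)),
    nu = aperm(array(res$nu, c(M, p, S)), c(1, 3, 2)),
    z = res$z, c = res$c,
    G = if (config$store_G) aperm(array(res$G, c(M, p, n)), c(1, 3, 2))
        else NULL,
    loglik = as.numeric(res$loglik),
    subgroup = data$subgroup, n = n, p = p, d = d, S = S,
    K0 = K0, Ks = Ks, M = M,
    items = data$items, subgroups = data$subgroups,
    config = config, priors = priors)
  class(samples) <- "rpc_samples"
  samples
}

#' @export
print.rpc_samples <- function(x, ...) {
  cat(sprintf(paste0("rpc_samples: %d retained draws (n_iter %d, burn-in %d,",
                     " thin %d, seed %d)\n"),
              x$M, x$config$n_iter, x$config$burn_in, x$config$thin,
              x$config$seed))
  cat(sprintf("  data: n=%d persons, p=%d items, d=%d levels, S=%d subgroups\n",
              x$n, x$p, x$d, x$S))
  cat(sprintf("  overfitted mixture: K0_max=%d, Ks_max=%d\n", x$K0, x$Ks))
  cat(sprintf("  log-likelihood (last draw): %.2f\n", x$loglik[x$M]))
  invisible(x)
}
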