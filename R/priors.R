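#' Noninformative prior specification for the RPC model
#'
#' Symmetric Dirichlet concentrations for the mixture weights default to
#' `1/K0_max` and `1/Ks_max` (the sparse overfitted-mixture regime, so that
#' redundant components empty out), symmetric Dirichlet 1 for consumption
#' probability rows, and Beta(1, 1) for the global-allocation probabilities.
#'
#' @param alpha_pi Concentration for the global weights; `NULL` = `1/K0_max`.
#' @param alpha_lambda Concentration for local weight rows; `NULL` =
#'   `1/Ks_max`.
#' @param alpha_theta Concentration for consumption probability rows.
#' @param nu_a,nu_b Beta shape parameters for `nu`.
#' @return An `rpc_priors` list.
#' @export
rpc_priors <- function(alpha_pi = NULL, alpha_lambda = NULL, alpha_theta = 1,
                       nu_a = 1, nu_b = 1) {
  for (v in list(alpha_pi, alpha_lambda, alpha_theta, nu_a, nu_b))
    if (!is.null(v) && v <= 0)
      stop("prior hyperparameters must be > 0", call. = FALSE)
  structure(list(alpha_pi = alpha_pi, alpha_lambda = alpha_lambda,
                 alpha_theta = alpha_theta, nu_a = nu_a, nu_b = nu_b),
            class = "rpc_priors")
}

#' MCMC configuration for the RPC Gibbs sampler
#'
#' Defaults overfit the mixture with 30 global and 30 local patterns.  The
#' default chain length is sized for the package's validation experiments
#' (thousands of persons); the full-survey-scale convention of a long chain with
#' half burn-in and thinning is kept.
#'
#' @param K0_max,Ks_max Overfitted numbers of global / local components.
#' @param n_iter Total Gibbs sweeps.
#' @param burn_in Discarded initial sweeps (must be `< n_iter`).
#' @param thin Keep every `thin`-th post-burn-in sweep.
#' @param seed Integer seed controlling initialization and the whole chain.
#' @param nu_fixed Optional: a scalar or `S x p` matrix freezing `nu` at a
#'   known value (the allocation step then never updates it).  Used for the
#'   degenerate latent-class reductions (`nu = 1` or `nu = 0`).
#' @param store_G Retain the full `n x p` indicator draws (needed for the
#'   G-based allocation heatmap).
#' @param nu_index `"subgroup_item"` (default): one allocation probability
#'   `nu[s, j]` per subgroup and item.  `"item"`: a single `nu[j]` shared by
#'   all subgroups.  The shared indexing makes strong localization
#'   identifiable: an item can only be globally allocated if one global
#'   profile row serves every subgroup, whereas per-subgroup probabilities
#'   allow a global class to clone a single subgroup's local pattern at no
#'   likelihood cost.
#' @param init Initialization strategy.  `"factorized"` (default) starts the
#'   consumption profiles at observed item marginals — global classes at
#'   jittered pooled marginals, each subgroup's first local class at the
#'   subgroup marginal with the remaining local classes at prior draws — with
#'   `nu = 0.5`, random indicators, random global labels and merged local
#'   labels.  `"random"` draws everything from the priors with all-global
#'   indicators.  The factorized start lets the shared global structure
#'   crystallize before subgroup-local classes can absorb it; see the package
#'   vignette for the metastable blended mode the random start can settle in.
#' @return An `mcmc_config` list.
#' @export
mcmc_config <- function(K0_max = 30L, Ks_max = 30L, n_iter = 2000L,
                        burn_in = n_iter %/% 2L, thin = 2L, seed = 1L,
                        nu_fixed = NULL, store_G = TRUE,
                        nu_index = c("subgroup_item", "item"),
                        init = c("factorized", "random")) {
  stopifnot(burn_in < n_iter, thin >= 1, K0_max >= 1, Ks_max >= 1)
  structure(list(K0_max = as.integer(K0_max), Ks_max = as.integer(Ks_max),
                 n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = as.integer(seed),
                 nu_fixed = nu_fixed, store_G = isTRUE(store_G),
                 nu_index = match.arg(nu_index), init = match.arg(init)),
            class = "mcmc_config")
}
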