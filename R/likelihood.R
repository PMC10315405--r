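log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

check_params <- function(params, p, d) {
  stopifnot(is.list(params))
  for (f in c("pi", "lam", "theta0", "theta1", "nu"))
    if (is.null(params[[f]])) stop("params$", f, " missing", call. = FALSE)
}

#' Subject-specific conditional log-likelihood of the RPC model
#'
#' Conditional on the global/local indicator row `G_row` (1 = global), the
#' likelihood of one person's consumption vector factorizes into a global
#' mixture over `h` on the globally allocated items and a local mixture over a
#' single local class `l` on the locally allocated items:
#' \deqn{\log\Big[\sum_h \pi_h \prod_{j: G_{ij}=1} \theta_{0}[h,j,y_{ij}]\Big]
#'   + \log\Big[\sum_l \lambda^{(s)}_l \prod_{j: G_{ij}=0}
#'   \theta_{1}[s,l,j,y_{ij}]\Big]}
#' computed stably in log space.  Note the single local class per person: the
#' local product over items sits inside one sum over `l`.
#'
#' @param y_row Integer vector of `p` levels in `1..d`.
#' @param s Subgroup index of the person.
#' @param params List with `pi` (K0), `lam` (S x Ks), `theta0` (K0 x p x d),
#'   `theta1` (S x Ks x p x d), `nu` (S x p).
#' @param G_row Binary vector of length `p`; 1 = item follows the global
#'   process.
#' @return Log-likelihood (scalar).
#' @export
rpc_log_likelihood <- function(y_row, s, params, G_row) {
  p <- length(y_row)
  d <- dim(params$theta0)[3]
  check_params(params, p, d)
  if (any(y_row < 1L | y_row > d))
    stop("consumption level outside 1..", d, call. = FALSE)
  stopifnot(length(G_row) == p, all(G_row %in% c(0L, 1L)))
  K0 <- length(params$pi); Ks <- ncol(params$lam)

  lg <- log(params$pi)
  for (j in which(G_row == 1L))
    lg <- lg + log(params$theta0[, j, y_row[j]])
  ll <- log(params$lam[s, ])
  for (j in which(G_row == 0L))
    ll <- ll + log(params$theta1[s, , j, y_row[j]])
  log_sum_exp(lg) + log_sum_exp(ll)
}

#' Marginal log-likelihood with the allocation indicators integrated out
#'
#' Sums the conditional likelihood over all `2^p` indicator configurations,
#' weighted by `prod_j nu[s,j]^G (1-nu[s,j])^(1-G)`.  This exact enumeration
#' is an oracle for testing (the Gibbs sampler never needs it) and is only
#' supported up to `max_p` items.
#'
#' @inheritParams rpc_log_likelihood
#' @param max_p Enumeration cap (default 12).
#' @return Log-likelihood (scalar).
#' @export
rpc_marginal_log_likelihood <- function(y_row, s, params, max_p = 12L) {
  p <- length(y_row)
  if (p > max_p)
    stop("exact G enumeration is unsupported for p > ", max_p,
         " (oracle-only operation)", call. = FALSE)
  nu <- params$nu[s, ]
  terms <- numeric(2^p)
  for (k in seq_len(2^p)) {
    G <- as.integer(intToBits(k - 1L))[seq_len(p)]
    lw <- sum(log(ifelse(G == 1L, nu, 1 - nu)))
    terms[k] <- if (is.finite(lw))
      lw + rpc_log_likelihood(y_row, s, params, G) else -Inf
  }
  log_sum_exp(terms)
}

#' Full conditional distributions of the Gibbs sampler (single person/item)
#'
#' Reference implementations of the categorical and Bernoulli full
#' conditionals the sampler draws from, exposed for testing and for posterior
#' membership computation:
#' * `z_conditional`: `P(z_i = h) ∝ pi_h prod_{j: G=1} theta0[h,j,y_ij]`
#' * `c_conditional`: `P(c_i = l) ∝ lam[s,l] prod_{j: G=0} theta1[s,l,j,y_ij]`
#' * `g_conditional`: `P(G_ij = 1) = nu th0 / (nu th0 + (1-nu) th1)` with
#'   `th0 = theta0[z_i,j,y_ij]`, `th1 = theta1[s,c_i,j,y_ij]`.
#'
#' @inheritParams rpc_log_likelihood
#' @param z,c_i Current global / local class of the person.
#' @param j Item index (for `g_conditional`).
#' @return A probability vector (`z_`/`c_conditional`) or scalar probability
#'   (`g_conditional`).
#' @export
z_conditional <- function(y_row, params, G_row) {
  lg <- log(params$pi)
  for (j in which(G_row == 1L))
    lg <- lg + log(params$theta0[, j, y_row[j]])
  w <- exp(lg - max(lg))
  w / sum(w)
}

#' @rdname z_conditional
#' @export
c_conditional <- function(y_row, s, params, G_row) {
  ll <- log(params$lam[s, ])
  for (j in which(G_row == 0L))
    ll <- ll + log(params$theta1[s, , j, y_row[j]])
  w <- exp(ll - max(ll))
  w / sum(w)
}

#' @rdname z_conditional
#' @export
g_conditional <- function(y_row, s, params, z, c_i, j) {
  pg <- params$nu[s, j] * params$theta0[z, j, y_row[j]]
  pl <- (1 - params$nu[s, j]) * params$theta1[s, c_i, j, y_row[j]]
  if (pg + pl == 0) 0.5 else pg / (pg + pl)
}
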