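# Independent oracles used across the test suite.  These deliberately avoid
# the package's own computational paths.

# Conditional likelihood by exhaustive enumeration over (h, l): given the
# indicator row G (1 = global), sum pi_h * lam_l * prod_j theta[...] over all
# class pairs.
oracle_loglik <- function(y_row, s, params, G_row) {
  K0 <- length(params$pi)
  Ks <- ncol(params$lam)
  total <- 0
  for (h in seq_len(K0)) for (l in seq_len(Ks)) {
    term <- params$pi[h] * params$lam[s, l]
    for (j in seq_along(y_row)) {
      term <- term * if (G_row[j] == 1L) params$theta0[h, j, y_row[j]]
                     else params$theta1[s, l, j, y_row[j]]
    }
    total <- total + term
  }
  log(total)
}

# Random tiny RPC parameter sets for oracle comparisons.
random_params <- function(p, K0, Ks, S, d) {
  rdir <- function(n, k) {
    g <- matrix(rgamma(n * k, 1), n, k)
    g / rowSums(g)
  }
  theta0 <- array(0, c(K0, p, d))
  for (h in seq_len(K0)) theta0[h, , ] <- rdir(p, d)
  theta1 <- array(0, c(S, Ks, p, d))
  for (s in seq_len(S)) for (l in seq_len(Ks)) theta1[s, l, , ] <- rdir(p, d)
  list(pi = drop(rdir(1, K0)), lam = rdir(S, Ks), theta0 = theta0,
       theta1 = theta1, nu = matrix(runif(S * p), S, p))
}

# Sort-based tertile oracle: type-1 (inverse ECDF) quantiles of the strictly
# positive values computed by explicit sorting and index arithmetic.
oracle_tertiles <- function(x) {
  pos <- sort(x[x > 0])
  m <- length(pos)
  c(pos[ceiling(m / 3)], pos[ceiling(2 * m / 3)])
}

# Enumeration oracle for level assignment under cutpoints (t1, t2).
oracle_level <- function(a, t1, t2) {
  if (a == 0) 1L
  else if (a <= t1) 2L
  else if (a <= t2) 3L
  else 4L
}

# Reference standard latent-class Gibbs sampler (weights alpha_w, profile
# rows alpha_theta), written independently of the package internals.
lcm_gibbs <- function(y, K, alpha_w, alpha_theta, n_iter, burn_in, thin,
                      seed) {
  set.seed(seed)
  n <- nrow(y); p <- ncol(y); d <- max(y)
  rdir <- function(shape) {
    g <- rgamma(length(shape), shape)
    g / sum(g)
  }
  w <- rep(1 / K, K)
  theta <- array(1 / d, c(K, p, d))
  z <- sample.int(K, n, replace = TRUE)
  M <- (n_iter - burn_in) %/% thin
  w_draws <- matrix(0, M, K)
  theta_draws <- array(0, c(M, K, p, d))
  m <- 0
  for (iter in seq_len(n_iter)) {
    # z | w, theta
    logw <- matrix(log(w), n, K, byrow = TRUE)
    for (k in seq_len(K)) {
      lth <- log(matrix(theta[k, , ], p, d))
      logw[, k] <- logw[, k] +
        rowSums(matrix(lth[cbind(rep(seq_len(p), each = n), as.vector(y))],
                       n, p))
    }
    mx <- apply(logw, 1, max)
    pr <- exp(logw - mx)
    pr <- pr / rowSums(pr)
    u <- runif(n)
    cum <- t(apply(pr, 1, cumsum))
    z <- rep(1L, n)
    for (k in seq_len(K - 1)) z <- z + (u > cum[, k])
    # w | z
    w <- rdir(alpha_w + tabulate(z, K))
    # theta | z
    for (k in seq_len(K)) {
      yk <- y[z == k, , drop = FALSE]
      for (j in seq_len(p))
        theta[k, j, ] <- rdir(alpha_theta + tabulate(yk[, j], d))
    }
    if (iter > burn_in && (iter - burn_in) %% thin == 0) {
      m <- m + 1
      w_draws[m, ] <- w
      theta_draws[m, , , ] <- theta
    }
  }
  list(w_mean = colMeans(w_draws),
       theta_mean = apply(theta_draws, c(2, 3, 4), mean))
}

# Align a stack of profile matrices (K x p x d) to a reference stack by
# greedy total-variation matching; returns the permutation old -> new slots.
align_profiles <- function(theta, ref) {
  K <- dim(theta)[1]
  cost <- matrix(0, K, K)
  for (a in seq_len(K)) for (b in seq_len(K))
    cost[a, b] <- sum(abs(theta[a, , ] - ref[b, , ]))
  perm <- integer(K)
  rows <- seq_len(K); cols <- seq_len(K)
  for (k in seq_len(K)) {
    sub <- cost[rows, cols, drop = FALSE]
    ij <- which(sub == min(sub), arr.ind = TRUE)[1, ]
    perm[rows[ij[1]]] <- cols[ij[2]]
    rows <- rows[-ij[1]]; cols <- cols[-ij[2]]
  }
  perm
}
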