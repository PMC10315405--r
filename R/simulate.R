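# Run `expr` under a locally seeded RNG, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Draw one categorical level per row of a row-stochastic matrix `P` (n x d)
# from pre-drawn uniforms, by inverse CDF.
draw_levels <- function(P, u) {
  d <- ncol(P)
  C <- P
  for (r in 2:d) C[, r] <- C[, r - 1] + P[, r]
  lev <- rep(1L, nrow(P))
  for (r in seq_len(d - 1)) lev <- lev + (u > C[, r])
  as.integer(lev)
}

#' Generate a synthetic consumption dataset with known global/local structure
#'
#' Draws data from the generative RPC process defined by a [truth_spec()]:
#' for each person `i` in subgroup `s`, a global class
#' `h ~ Categorical(pi_true)`, a local class `l ~ Categorical(lambda_true[s,])`,
#' per-item indicators `G_ij ~ Bernoulli(nu_true[s, j])` (1 = global), and
#' levels `y_ij` from `theta0_true[h, j, ]` when `G_ij = 1` or
#' `theta1_true[s, l, j, ]` when `G_ij = 0`.  Deterministic given `spec$seed`;
#' the caller's RNG state is left untouched.
#'
#' @param spec A [truth_spec()].
#' @return A list with elements `data` (a [consumption_matrix()]) and `truth`
#'   (list with the latent draws `z`, `c`, `G` and the generating `spec`).
#' @export
generate_dataset <- function(spec) {
  validate_truth_spec(spec)
  S <- length(spec$n_per_subgroup)
  n <- sum(spec$n_per_subgroup); p <- spec$p; d <- spec$d
  subgroup <- rep(seq_len(S), spec$n_per_subgroup)

  with_local_seed(spec$seed, {
    z <- sample.int(spec$true_K0, n, replace = TRUE, prob = spec$pi_true)
    cc <- integer(n)
    for (s in seq_len(S)) {
      idx <- which(subgroup == s)
      cc[idx] <- sample.int(spec$true_Ks, length(idx), replace = TRUE,
                            prob = spec$lambda_true[s, ])
    }
    nu_ij <- spec$nu_true[cbind(rep(subgroup, p), rep(seq_len(p), each = n))]
    G <- matrix(rbinom(n * p, 1L, nu_ij), n, p)
    y <- matrix(0L, n, p)
    for (j in seq_len(p)) {
      P0 <- spec$theta0_true[z, j, , drop = FALSE]
      dim(P0) <- c(n, d)
      # theta1_true[s_i, c_i, j, ] for each person, via flat indexing
      base <- subgroup + S * (cc - 1L) + S * spec$true_Ks * (j - 1L)
      idx <- c(outer(base, S * spec$true_Ks * p * (seq_len(d) - 1L), `+`))
      P1 <- matrix(as.vector(spec$theta1_true)[idx], n, d)
      P <- ifelse(G[, j] == 1L, 1, 0) * P0 + ifelse(G[, j] == 1L, 0, 1) * P1
      y[, j] <- draw_levels(P, runif(n))
    }
    data <- consumption_matrix(y, subgroup, d = d, items = spec$items,
                               subgroups = spec$subgroups)
    list(data = data,
         truth = list(z = z, c = cc, G = G, spec = spec))
  })
}

#' Write / read the latent truth sidecar of a synthetic dataset
#'
#' Structured-text (JSON) persistence of the latent draws and the generating
#' parameters, so a simulated dataset written with [write_consumption()] can
#' be audited and re-scored later.  Arrays are stored with explicit `dim`.
#'
#' @param truth The `truth` element returned by [generate_dataset()].
#' @param path File path (JSON).
#' @export
write_truth <- function(truth, path) {
  spec <- truth$spec
  obj <- list(
    z = truth$z, c = truth$c, G = truth$G,
    spec = list(
      n_per_subgroup = spec$n_per_subgroup, p = spec$p, d = spec$d,
      pi_true = spec$pi_true, lambda_true = spec$lambda_true,
      theta0_true = list(dim = dim(spec$theta0_true),
                         values = as.vector(spec$theta0_true)),
      theta1_true = list(dim = dim(spec$theta1_true),
                         values = as.vector(spec$theta1_true)),
      nu_true = spec$nu_true, seed = spec$seed,
      items = spec$items, subgroups = spec$subgroups))
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  sp <- obj$spec
  spec <- truth_spec(
    sp$n_per_subgroup, sp$p, sp$d, sp$pi_true, sp$lambda_true,
    array(sp$theta0_true$values, sp$theta0_true$dim),
    array(sp$theta1_true$values, sp$theta1_true$dim),
    sp$nu_true, seed = sp$seed,
    items = if (length(sp$items)) sp$items else NULL,
    subgroups = if (length(sp$subgroups)) sp$subgroups else NULL)
  list(z = as.integer(obj$z), c = as.integer(obj$c),
       G = matrix(as.integer(obj$G), nrow = length(obj$z)), spec = spec)
}

#' Closed-form marginal level frequencies of the generative process
#'
#' For each subgroup `s` and item `j`, the marginal probability of each
#' consumption level under a [truth_spec()]:
#' `nu[s,j] * sum_h pi_h theta0[h,j,] + (1-nu[s,j]) * sum_l lambda[s,l] theta1[s,l,j,]`.
#' Used to check empirical frequencies of generated data.
#'
#' @param spec A [truth_spec()].
#' @return An `S x p x d` array of level probabilities.
#' @export
marginal_level_probs <- function(spec) {
  S <- length(spec$n_per_subgroup); p <- spec$p; d <- spec$d
  out <- array(0, c(S, p, d))
  for (s in seq_len(S)) for (j in seq_len(p)) {
    g <- drop(spec$pi_true %*% matrix(spec$theta0_true[, j, ], spec$true_K0, d))
    l <- drop(spec$lambda_true[s, ] %*% matrix(spec$theta1_true[s, , j, ],
                                               spec$true_Ks, d))
    out[s, j, ] <- spec$nu_true[s, j] * g + (1 - spec$nu_true[s, j]) * l
  }
  out
}
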