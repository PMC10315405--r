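# Greedy cost matching: assign each row (draw component) to a distinct column
# (reference slot) by repeatedly taking the smallest remaining cost cell.
greedy_match <- function(cost) {
  A <- nrow(cost)
  perm <- integer(A)
  rows <- seq_len(A); cols <- seq_len(A)
  for (k in seq_len(A)) {
    sub <- cost[rows, cols, drop = FALSE]
    ij <- which(sub == min(sub), arr.ind = TRUE)[1, ]
    perm[rows[ij[1]]] <- cols[ij[2]]
    rows <- rows[-ij[1]]; cols <- cols[-ij[2]]
  }
  perm
}

# Mean total-variation distance between profile stacks flattened to
# A x (p*d): cost[a, b] = mean_j TV(row_aj, row_bj).
tv_cost <- function(X, R, p) {
  A <- nrow(X); B <- nrow(R)
  out <- matrix(0, A, B)
  for (a in seq_len(A)) for (b in seq_len(B))
    out[a, b] <- 0.5 * sum(abs(X[a, ] - R[b, ])) / p
  out
}

# Relabel one family of mixture draws.
#   theta: M x K x p x d, labels: M x n_members (class draws restricted to the
#   members the family applies to), weights: M x K.
# Components with posterior-median occupancy below `threshold` are dropped;
# survivors are relabeled per draw by greedy TV matching of their theta rows
# to the last draw, then ordered by descending mean occupancy.
relabel_family <- function(theta, labels, weights, K, p, d, threshold) {
  M <- dim(theta)[1]
  n_members <- ncol(labels)
  occ <- matrix(0, M, K)
  for (k in seq_len(K)) occ[, k] <- rowMeans(labels == k)
  med_occ <- apply(occ, 2, median)
  keep <- which(med_occ >= threshold)
  A <- length(keep)
  if (A == 0)
    stop("all components fall below the occupancy threshold; ",
         "reduce occupancy_threshold", call. = FALSE)

  flat <- function(m) matrix(theta[m, keep, , ], A, p * d)
  ref <- flat(M)
  theta_rel <- array(0, c(M, A, p, d))
  w_rel <- matrix(0, M, A)
  lab_rel <- matrix(NA_integer_, M, n_members)
  lab_map <- integer(K)
  for (m in seq_len(M)) {
    perm <- if (A == 1) 1L else greedy_match(tv_cost(flat(m), ref, p))
    for (a in seq_len(A)) {
      theta_rel[m, perm[a], , ] <- theta[m, keep[a], , ]
      w_rel[m, perm[a]] <- weights[m, keep[a]]
    }
    lab_map[] <- NA_integer_; lab_map[keep] <- perm
    lab_rel[m, ] <- lab_map[labels[m, ]]
  }
  occ_rel <- matrix(0, M, A)
  for (a in seq_len(A))
    occ_rel[, a] <- rowMeans(!is.na(lab_rel) & lab_rel == a)
  ord <- order(colMeans(occ_rel), decreasing = TRUE)
  inv <- match(seq_len(A), ord)

  theta_rel <- theta_rel[, ord, , , drop = FALSE]
  w_rel <- w_rel[, ord, drop = FALSE]
  lab_rel[] <- inv[lab_rel]
  occ_rel <- occ_rel[, ord, drop = FALSE]

  membership <- matrix(0, n_members, A)
  for (a in seq_len(A)) membership[, a] <- colMeans(lab_rel == a, na.rm = TRUE)
  membership[is.na(membership)] <- 1 / A
  membership <- membership / rowSums(membership)

  theta_mean <- array(0, c(A, p, d))
  for (a in seq_len(A)) {
    tm <- apply(theta_rel[, a, , , drop = FALSE], c(3, 4), mean)
    theta_mean[a, , ] <- tm
  }
  list(n = A, kept = keep, med_occupancy = med_occ,
       occupancy = colMeans(occ_rel), weights_mean = colMeans(w_rel),
       theta_mean = theta_mean, membership = membership, labels = lab_rel)
}

#' Prune empty mixture components and resolve label switching
#'
#' Components whose posterior-median occupancy (fraction of their reference
#' population assigned to them: all `n` persons for global patterns, the
#' subgroup for local ones) falls below `occupancy_threshold` are dropped —
#' the overfitted-mixture analogue of "nonempty patterns remain".  Surviving
#' components are relabeled draw by draw by greedy total-variation matching of
#' their consumption-profile rows to the last retained draw, then ordered by
#' descending mean occupancy.  Posterior means are computed after relabeling.
#'
#' @param samples An `rpc_samples` object from [run_mcmc()].
#' @param occupancy_threshold Minimum posterior-median occupancy (default
#'   0.05).
#' @return An `rpc_pattern_summary` (without modal patterns / heatmap; see
#'   [summarize_rpc()] for the complete summary): `global` and per-subgroup
#'   `local` pattern sets with posterior-mean profiles, occupancies, weights
#'   and per-person membership probabilities, plus the untouched `loglik`
#'   trace.
#' @export
prune_and_relabel <- function(samples, occupancy_threshold = 0.05) {
  stopifnot(inherits(samples, "rpc_samples"), samples$M >= 1)
  p <- samples$p; d <- samples$d
  glob <- relabel_family(samples$theta0, samples$z, samples$pi,
                         samples$K0, p, d, occupancy_threshold)
  loc <- vector("list", samples$S)
  for (s in seq_len(samples$S)) {
    idx <- which(samples$subgroup == s)
    th1_s <- samples$theta1[, s, , , , drop = FALSE]
    dim(th1_s) <- c(samples$M, samples$Ks, p, d)
    lam_s <- samples$lam[, s, , drop = FALSE]
    dim(lam_s) <- c(samples$M, samples$Ks)
    loc[[s]] <- relabel_family(th1_s, samples$c[, idx, drop = FALSE],
                               lam_s, samples$Ks, p, d, occupancy_threshold)
  }
  names(loc) <- samples$subgroups
  structure(list(global = glob, local = loc,
                 occupancy_threshold = occupancy_threshold,
                 loglik = samples$loglik, items = samples$items,
                 subgroups = samples$subgroups, d = d, p = p, S = samples$S),
            class = "rpc_pattern_summary")
}

#' Modal consumption patterns
#'
#' For every retained pattern and food item, the consumption level with the
#' highest posterior-mean probability and that probability.  Ties are broken
#' toward the lower level and flagged.
#'
#' @param summary An `rpc_pattern_summary` from [prune_and_relabel()] or
#'   [summarize_rpc()].
#' @return List with `global` and per-subgroup `local` elements, each holding
#'   `levels` (patterns x items integer matrix), `prob` and `tie` matrices.
#' @export
modal_patterns <- function(summary) {
  stopifnot(inherits(summary, "rpc_pattern_summary"))
  modal_of <- function(theta_mean) {
    K <- dim(theta_mean)[1]; p <- dim(theta_mean)[2]
    levels <- matrix(0L, K, p); prob <- matrix(0, K, p)
    tie <- matrix(FALSE, K, p)
    for (k in seq_len(K)) for (j in seq_len(p)) {
      row <- theta_mean[k, j, ]
      levels[k, j] <- which.max(row)          # first max = lowest level
      prob[k, j] <- max(row)
      tie[k, j] <- sum(row == max(row)) > 1
    }
    colnames(levels) <- colnames(prob) <- colnames(tie) <- summary$items
    list(levels = levels, prob = prob, tie = tie)
  }
  list(global = modal_of(summary$global$theta_mean),
       local = lapply(summary$local, function(l) modal_of(l$theta_mean)))
}

#' Posterior global-allocation heatmap
#'
#' For every item `j` and subgroup `s`, the posterior probability that the
#' item follows the global process: both the empirical indicator version
#' (posterior mean over draws of the fraction of subgroup-`s` persons with
#' `G_ij = 1`) and the posterior mean of `nu[s, j]` are reported; the two
#' agree up to Monte-Carlo error.
#'
#' @param samples An `rpc_samples` with retained `G` draws
#'   (`store_G = TRUE`).
#' @return An `rpc_allocation` list with `G` and `nu` (`p x S` matrices).
#' @export
allocation_heatmap <- function(samples) {
  stopifnot(inherits(samples, "rpc_samples"))
  if (is.null(samples$G))
    stop("G draws were not retained; rerun run_mcmc() with store_G = TRUE",
         call. = FALSE)
  p <- samples$p; S <- samples$S
  Gmat <- matrix(0, p, S); numat <- matrix(0, p, S)
  for (s in seq_len(S)) {
    idx <- which(samples$subgroup == s)
    per_draw <- apply(samples$G[, idx, , drop = FALSE], c(1, 3), mean)
    Gmat[, s] <- colMeans(per_draw)
    numat[, s] <- colMeans(matrix(samples$nu[, s, ], samples$M, p))
  }
  rownames(Gmat) <- rownames(numat) <- samples$items
  colnames(Gmat) <- colnames(numat) <- samples$subgroups
  structure(list(G = Gmat, nu = numat), class = "rpc_allocation")
}

#' Complete posterior pattern summary
#'
#' Convenience wrapper: [prune_and_relabel()] plus [modal_patterns()] plus
#' [allocation_heatmap()] in one object.
#'
#' @inheritParams prune_and_relabel
#' @return The `rpc_pattern_summary` with `modal` and `allocation` fields
#'   filled in.
#' @export
summarize_rpc <- function(samples, occupancy_threshold = 0.05) {
  out <- prune_and_relabel(samples, occupancy_threshold)
  out$modal <- modal_patterns(out)
  out$allocation <- if (!is.null(samples$G)) allocation_heatmap(samples)
                    else NULL
  out
}

#' @export
print.rpc_pattern_summary <- function(x, ...) {
  cat(sprintf("rpc_pattern_summary (occupancy threshold %.2f)\n",
              x$occupancy_threshold))
  cat(sprintf("  global patterns: %d (occupancy: %s)\n", x$global$n,
              paste(sprintf("%.2f", x$global$occupancy), collapse = ", ")))
  for (s in seq_len(x$S))
    cat(sprintf("  local patterns [%s]: %d (occupancy: %s)\n",
                x$subgroups[s], x$local[[s]]$n,
                paste(sprintf("%.2f", x$local[[s]]$occupancy),
                      collapse = ", ")))
  if (!is.null(x$allocation))
    cat(sprintf("  max global-allocation probability: %.3f\n",
                max(x$allocation$G)))
  invisible(x)
}

#' Survey-weighted descriptive summaries
#'
#' Horvitz–Thompson weighted means (for binary flags: weighted proportions)
#' per stratum and overall, with variability from a person-level bootstrap
#' (resampling persons with replacement within stratum).  Design-based
#' stratum/PSU variance estimation is deliberately out of scope; the output
#' labels its `method` accordingly.  Missing values are dropped per variable.
#' Estimates are invariant to rescaling all weights.
#'
#' @param tbl Data frame of numeric / logical variables.
#' @param weights Nonnegative survey weights (pooled-cycle rescaling, e.g.
#'   weight divided by the number of pooled cycles, is assumed done upstream).
#' @param strata Factor or vector defining strata; `NULL` for overall only.
#' @param vars Variables to summarize (default: all columns of `tbl`).
#' @param n_boot Bootstrap replicates (default 200).
#' @param seed Bootstrap seed.
#' @return A data frame with columns `stratum`, `variable`, `estimate`, `se`,
#'   `n`, `method`.
#' @export
weighted_descriptives <- function(tbl, weights, strata = NULL, vars = NULL,
                                  n_boot = 200L, seed = 1L) {
  stopifnot(is.data.frame(tbl), length(weights) == nrow(tbl))
  if (any(weights < 0, na.rm = TRUE))
    stop("survey weights must be nonnegative", call. = FALSE)
  if (is.null(vars)) vars <- names(tbl)
  strata_f <- if (is.null(strata)) NULL else factor(strata)
  groups <- c("overall", levels(strata_f))

  wmean <- function(x, w) {
    ok <- !is.na(x) & !is.na(w)
    if (!any(ok)) return(NA_real_)
    sum(as.numeric(x[ok]) * w[ok]) / sum(w[ok])
  }
  rows <- list()
  with_local_seed(seed, {
    for (g in groups) {
      idx <- if (g == "overall") seq_len(nrow(tbl))
             else which(strata_f == g)
      for (v in vars) {
        x <- tbl[[v]][idx]; w <- weights[idx]
        est <- wmean(x, w)
        boot <- vapply(seq_len(n_boot), function(b) {
          take <- sample.int(length(idx), replace = TRUE)
          wmean(x[take], w[take])
        }, numeric(1))
        rows[[length(rows) + 1L]] <- data.frame(
          stratum = g, variable = v, estimate = est,
          se = stats::sd(boot, na.rm = TRUE), n = sum(!is.na(x)),
          method = "person-bootstrap")
      }
    }
  })
  do.call(rbind, rows)
}
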