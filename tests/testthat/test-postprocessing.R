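# Build a small synthetic rpc_samples object with known structure and
# optional per-draw label permutations (global side), to test pruning and
# relabeling without an MCMC run.
fake_samples <- function(M = 40, permute = TRUE, seed = 1) {
  set.seed(seed)
  K0 <- 4; Ks <- 2; p <- 5; d <- 3; S <- 1; n <- 60
  base <- array(0, c(K0, p, d))
  base[1, , ] <- matrix(c(0.8, 0.1, 0.1), p, d, byrow = TRUE)
  base[2, , ] <- matrix(c(0.1, 0.8, 0.1), p, d, byrow = TRUE)
  base[3, , ] <- matrix(1 / 3, p, d)    # will be pruned (no members)
  base[4, , ] <- matrix(1 / 3, p, d)
  z_base <- rep(c(1L, 2L), c(40, 20))
  theta0 <- array(0, c(M, K0, p, d)); z <- matrix(0L, M, n)
  pi <- matrix(0, M, K0)
  pi_base <- c(2 / 3, 1 / 3, 0, 0)
  for (m in seq_len(M)) {
    # label switching among the occupied components (empties keep their
    # slots, as in a converged overfitted chain)
    perm <- if (permute) c(sample(2L), 3L, 4L) else seq_len(K0)
    # class k of the base sits at slot perm[k]
    theta0[m, perm, , ] <- base + stats::rnorm(length(base), 0, 0.002)
    pi[m, perm] <- pi_base
    z[m, ] <- perm[z_base]
  }
  theta1 <- array(1 / d, c(M, S, Ks, p, d))
  lam <- array(0, c(M, S, Ks)); lam[, 1, 1] <- 1
  cc <- matrix(1L, M, n)
  structure(list(pi = pi, lam = lam, theta0 = theta0, theta1 = theta1,
                 nu = array(0.5, c(M, S, p)), z = z, c = cc,
                 G = array(1L, c(M, n, p)),
                 loglik = stats::rnorm(M), subgroup = rep(1L, n),
                 n = n, p = p, d = d, S = S, K0 = K0, Ks = Ks, M = M,
                 items = paste0("item", 1:p), subgroups = "all",
                 config = NULL, priors = NULL),
            class = "rpc_samples")
}

test_that("pruning drops empty components and relabeling undoes switching", {
  sam <- fake_samples(permute = TRUE)
  summ <- prune_and_relabel(sam, occupancy_threshold = 0.05)
  expect_equal(summ$global$n, 2)
  # slot 1 = highest occupancy = base class 1
  expect_equal(summ$global$occupancy, c(2 / 3, 1 / 3), tolerance = 1e-12)
  expect_lt(max(abs(summ$global$theta_mean[1, , 1] - 0.8)), 0.01)
  expect_lt(max(abs(summ$global$theta_mean[2, , 2] - 0.8)), 0.01)
  # label-switched input gives the same summary as unswitched input
  summ0 <- prune_and_relabel(fake_samples(permute = FALSE),
                             occupancy_threshold = 0.05)
  expect_equal(summ$global$theta_mean, summ0$global$theta_mean,
               tolerance = 0.01)
  # membership rows are distributions and recover the constant assignment
  expect_equal(rowSums(summ$global$membership), rep(1, sam$n))
  expect_true(all(summ$global$membership[1:40, 1] > 0.99))
  expect_true(all(summ$global$membership[41:60, 2] > 0.99))
})

test_that("pruning and relabeling never touch the likelihood trace", {
  sam <- fake_samples()
  summ <- prune_and_relabel(sam, 0.05)
  expect_identical(summ$loglik, sam$loglik)
})

test_that("an over-aggressive occupancy threshold is a clear error", {
  sam <- fake_samples()
  expect_error(prune_and_relabel(sam, occupancy_threshold = 0.9),
               "occupancy_threshold")
})

test_that("modal patterns take the argmax with lower-level tie-breaking", {
  sam <- fake_samples(permute = FALSE)
  summ <- prune_and_relabel(sam, 0.05)
  summ$global$theta_mean[1, 1, ] <- c(0.1, 0.2, 0.7)
  summ$global$theta_mean[1, 2, ] <- c(1 / 3, 1 / 3, 1 / 3)
  mp <- modal_patterns(summ)
  expect_equal(unname(mp$global$levels[1, 1]), 3L)
  expect_equal(unname(mp$global$prob[1, 1]), 0.7)
  expect_equal(unname(mp$global$levels[1, 2]), 1L)  # tie broken to lower level
  expect_true(mp$global$tie[1, 2])
  expect_false(mp$global$tie[1, 1])
  # deterministic and idempotent
  expect_identical(mp, modal_patterns(summ))
})

test_that("allocation heatmap agrees between indicator and nu estimates", {
  sim <- generate_dataset(nhanes_like_spec("tiny", seed = 31))
  cfg <- mcmc_config(K0_max = 5, Ks_max = 5, n_iter = 400, burn_in = 200,
                     thin = 2, seed = 8)
  sam <- run_mcmc(sim$data, rpc_priors(), cfg)
  al <- allocation_heatmap(sam)
  expect_equal(dim(al$G), c(sim$data$p, sim$data$S))
  expect_true(all(al$G >= 0 & al$G <= 1))
  expect_true(all(al$nu >= 0 & al$nu <= 1))
  # G-based and nu-based estimates agree up to Monte-Carlo error
  expect_lt(max(abs(al$G - al$nu)), 0.1)
  # heatmap is invariant to global label permutations of the draws
  sam2 <- sam
  sam2$z <- sam$z[, sim$data$n:1]  # irrelevant field reordering guard
  expect_equal(allocation_heatmap(sam)$G, al$G)
  # refuses when indicators were not stored
  cfg2 <- mcmc_config(K0_max = 5, Ks_max = 5, n_iter = 50, burn_in = 25,
                      thin = 1, seed = 8, store_G = FALSE)
  sam3 <- run_mcmc(sim$data, rpc_priors(), cfg2)
  expect_error(allocation_heatmap(sam3), "store_G")
})

test_that("weighted descriptives reduce to hand arithmetic", {
  tbl <- data.frame(flag = c(1, 0, 1))
  out <- weighted_descriptives(tbl, weights = c(1, 1, 2), n_boot = 50)
  expect_equal(out$estimate[out$stratum == "overall"], 0.75)
  # equal weights collapse to the unweighted mean exactly
  out_eq <- weighted_descriptives(tbl, weights = c(1, 1, 1), n_boot = 50)
  expect_equal(out_eq$estimate[out_eq$stratum == "overall"], 2 / 3)
  # rescaling all weights changes nothing
  out2 <- weighted_descriptives(tbl, weights = c(2, 2, 4), n_boot = 50)
  expect_equal(out$estimate, out2$estimate)
  expect_error(weighted_descriptives(tbl, weights = c(-1, 1, 1)),
               "nonnegative")
})

test_that("weighted descriptives stratify and report bootstrap variability", {
  set.seed(77)
  tbl <- data.frame(flag = rbinom(200, 1, 0.4), x = rnorm(200, 10))
  strata <- rep(c("a", "b"), each = 100)
  w <- runif(200, 0.5, 2)
  out <- weighted_descriptives(tbl, w, strata = strata, n_boot = 100,
                               seed = 3)
  expect_setequal(unique(out$stratum), c("overall", "a", "b"))
  expect_true(all(out$se > 0))
  expect_true(all(out$method == "person-bootstrap"))
  ha <- sum(tbl$flag[1:100] * w[1:100]) / sum(w[1:100])
  expect_equal(out$estimate[out$stratum == "a" & out$variable == "flag"], ha)
})
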