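#' Specify a generative truth for synthetic consumption data
#'
#' Defines every parameter of the generative RPC process: global pattern
#' weights `pi_true`, per-subgroup local weights `lambda_true`, global and
#' local consumption-probability profiles (`theta0_true`, `theta1_true`), and
#' the per-(subgroup, item) probability `nu_true` that an item follows the
#' global process.  [generate_dataset()] draws data from this process and
#' returns the latent truth for recovery testing.
#'
#' @param n_per_subgroup Integer vector of length `S`: persons per subgroup.
#' @param p Number of food items.
#' @param d Number of consumption levels (default 4; level 1 = none).
#' @param pi_true Probability vector of length `true_K0`.
#' @param lambda_true `S x true_Ks` row-stochastic matrix of local weights.
#' @param theta0_true `true_K0 x p x d` array; each `[h, j, ]` row sums to 1.
#' @param theta1_true `S x true_Ks x p x d` array; each `[s, l, j, ]` row sums
#'   to 1.
#' @param nu_true `S x p` matrix in `[0, 1]`: probability that item `j` in
#'   subgroup `s` is globally allocated.
#' @param seed Integer seed making generation deterministic.
#' @param items,subgroups Optional name vectors.
#' @return An object of class `truth_spec`.
#' @export
truth_spec <- function(n_per_subgroup, p, d = 4L, pi_true, lambda_true,
                       theta0_true, theta1_true, nu_true, seed = 1L,
                       items = NULL, subgroups = NULL) {
  spec <- structure(
    list(n_per_subgroup = as.integer(n_per_subgroup), p = as.integer(p),
         d = as.integer(d), true_K0 = length(pi_true),
         true_Ks = ncol(as.matrix(lambda_true)),
         pi_true = as.numeric(pi_true),
         lambda_true = as.matrix(lambda_true),
         theta0_true = theta0_true, theta1_true = theta1_true,
         nu_true = as.matrix(nu_true), seed = as.integer(seed),
         items = items, subgroups = subgroups),
    class = "truth_spec")
  validate_truth_spec(spec)
  spec
}

#' Validate a truth specification
#'
#' Checks dimensions and probability-simplex invariants; errors name the
#' offending field.
#'
#' @param spec A `truth_spec`.
#' @param tol Simplex tolerance.
#' @return `spec`, invisibly.
#' @export
validate_truth_spec <- function(spec, tol = 1e-12) {
  S <- length(spec$n_per_subgroup); p <- spec$p; d <- spec$d
  K0 <- spec$true_K0; Ks <- spec$true_Ks
  fail <- function(field, why)
    stop(sprintf("invalid truth_spec field '%s': %s", field, why), call. = FALSE)
  if (any(spec$n_per_subgroup <= 0L)) fail("n_per_subgroup", "counts must be positive")
  chk_simplex <- function(x, field) {
    if (any(x < 0 | x > 1)) fail(field, "entries outside [0, 1]")
    if (abs(sum(x) - 1) > tol) fail(field, sprintf("sums to %.15g, not 1", sum(x)))
  }
  chk_simplex(spec$pi_true, "pi_true")
  if (!identical(dim(spec$lambda_true), c(S, Ks)) && !all(dim(spec$lambda_true) == c(S, Ks)))
    fail("lambda_true", sprintf("expected %d x %d matrix", S, Ks))
  for (s in seq_len(S)) chk_simplex(spec$lambda_true[s, ], "lambda_true")
  if (!all(dim(spec$theta0_true) == c(K0, p, d)))
    fail("theta0_true", sprintf("expected %d x %d x %d array", K0, p, d))
  for (h in seq_len(K0)) for (j in seq_len(p))
    chk_simplex(spec$theta0_true[h, j, ], "theta0_true")
  if (!all(dim(spec$theta1_true) == c(S, Ks, p, d)))
    fail("theta1_true", sprintf("expected %d x %d x %d x %d array", S, Ks, p, d))
  for (s in seq_len(S)) for (l in seq_len(Ks)) for (j in seq_len(p))
    chk_simplex(spec$theta1_true[s, l, j, ], "theta1_true")
  if (!all(dim(spec$nu_true) == c(S, p)))
    fail("nu_true", sprintf("expected %d x %d matrix", S, p))
  if (any(spec$nu_true < 0 | spec$nu_true > 1)) fail("nu_true", "entries outside [0, 1]")
  invisible(spec)
}

# One consumption-probability row: `modal_prob` at the modal level; if
# `none_prob` is given (and the mode is not level 1), level 1 takes that mass
# and the rest is split over the remaining levels — the zero-inflation device
# for episodically consumed items.
profile_row <- function(modal, modal_prob, d = 4L, none_prob = NULL) {
  row <- numeric(d)
  row[modal] <- modal_prob
  others <- setdiff(seq_len(d), modal)
  if (!is.null(none_prob) && modal != 1L) {
    row[1L] <- none_prob
    rest <- setdiff(others, 1L)
    row[rest] <- (1 - modal_prob - none_prob) / length(rest)
  } else {
    row[others] <- (1 - modal_prob) / length(others)
  }
  row
}

# Deterministic profile arrays used by the presets: class h's modal level for
# item j cycles through the d levels with a per-class phase shift.  Distinct
# phases (mod d) give profiles that disagree on every item's modal level.
build_theta0 <- function(K0, p, d, modal_prob, none_prob = NULL,
                         phase = seq_len(K0)) {
  th <- array(0, c(K0, p, d))
  for (h in seq_len(K0)) for (j in seq_len(p)) {
    modal <- 1L + (j + phase[h]) %% d
    th[h, j, ] <- profile_row(modal, modal_prob, d,
                              if (j %% 3L == 0L) none_prob else NULL)
  }
  th
}

build_theta1 <- function(S, Ks, p, d, modal_prob, none_prob = NULL,
                         phase = outer(seq_len(S), seq_len(Ks),
                                       function(s, l) s + 2L * l),
                         flip = rep(FALSE, S)) {
  if (length(modal_prob) == 1L) modal_prob <- rep(modal_prob, S)
  th <- array(0, c(S, Ks, p, d))
  for (s in seq_len(S)) for (l in seq_len(Ks)) for (j in seq_len(p)) {
    jj <- if (flip[s]) -j else j
    modal <- 1L + (jj + phase[s, l]) %% d
    th[s, l, j, ] <- profile_row(modal, modal_prob[s], d,
                                 if ((j + s) %% 3L == 0L) none_prob else NULL)
  }
  th
}

#' NHANES-like preset truth specifications
#'
#' A small registry of generative regimes mirroring the study population the
#' package targets (5 race/ethnicity subgroups, 28 food-group items, 4
#' consumption levels, zero inflation on episodically consumed items):
#'
#' * `"study_scale"` — 2917 persons in subgroups of 526/386/999/805/201, 28
#'   items, 3 weakly separated global patterns, one dominant local pattern per
#'   subgroup, and all-local allocation (`nu_true` between 0.04 and 0.12).
#' * `"all_local"` — the same regime at half the sample size; the default
#'   fixture for the all-local recovery experiment.
#' * `"tiny"` — 150 persons, 6 items, 3 subgroups; a smoke-test fixture that
#'   runs the full pipeline in seconds.
#' * `"well_separated"` — 2 subgroups of 500, 28 items, 2 strongly separated
#'   global patterns and 1 local pattern per subgroup, `nu_true = 0.5`
#'   everywhere; the parameter-recovery benchmark.
#' * `"all_global"` — a single population of 800 persons, 8 items,
#'   `nu_true = 1`: data from a plain latent class model on the global
#'   profiles (the degenerate reduction fixture).
#' * `"local_lcm"` — one subgroup of 800 persons, 8 items, `nu_true = 0`:
#'   a plain latent class model on the local profiles.
#'
#' @param preset Preset name (see above).
#' @param size_factor Multiplier on the preset's subgroup sizes (each subgroup
#'   kept at a minimum of 25 persons).
#' @param seed Seed stored in the returned spec.
#' @return A [truth_spec()].
#' @export
nhanes_like_spec <- function(preset = c("study_scale", "all_local", "tiny",
                                        "well_separated", "all_global",
                                        "local_lcm"),
                             size_factor = NULL, seed = 1L) {
  presets <- c("study_scale", "all_local", "tiny", "well_separated",
               "all_global", "local_lcm")
  if (!is.character(preset) || !preset[1] %in% presets)
    stop("unknown preset '", preset[1], "'; available presets: ",
         paste(presets, collapse = ", "), call. = FALSE)
  preset <- preset[1]
  scale_n <- function(n, f) pmax(25L, as.integer(round(n * f)))

  if (preset %in% c("study_scale", "all_local")) {
    if (is.null(size_factor)) size_factor <- if (preset == "all_local") 0.5 else 1
    S <- 5L; p <- 28L; d <- 4L
    n <- scale_n(c(526L, 386L, 999L, 805L, 201L), size_factor)
    pi_true <- c(0.40, 0.35, 0.25)
    lambda_true <- matrix(1, S, 1)
    theta0_true <- build_theta0(3L, p, d, modal_prob = 0.35, none_prob = 0.30)
    # every subgroup pair must differ on every item (different modal level,
    # or clearly different modal mass) so that allocation is identifiable
    theta1_true <- build_theta1(S, 1L, p, d,
                                modal_prob = c(0.55, 0.65, 0.60, 0.70, 0.80),
                                none_prob = 0.15,
                                flip = c(FALSE, FALSE, FALSE, FALSE, TRUE))
    nu_true <- matrix(rep(0.04 + 0.08 * (seq_len(p) - 1) / (p - 1), each = S), S, p)
    subgroups <- c("Mexican", "OtherHispanic", "NHWhite", "NHBlack", "NHAsian")
  } else if (preset == "tiny") {
    if (is.null(size_factor)) size_factor <- 1
    S <- 3L; p <- 6L; d <- 4L
    n <- scale_n(c(50L, 50L, 50L), size_factor)
    pi_true <- c(0.6, 0.4)
    lambda_true <- matrix(1, S, 1)
    theta0_true <- build_theta0(2L, p, d, modal_prob = 0.7)
    theta1_true <- build_theta1(S, 1L, p, d, modal_prob = 0.7)
    nu_true <- matrix(0.5, S, p)
    subgroups <- NULL
  } else if (preset == "well_separated") {
    if (is.null(size_factor)) size_factor <- 1
    S <- 2L; p <- 28L; d <- 4L
    n <- scale_n(c(500L, 500L), size_factor)
    pi_true <- c(0.5, 0.5)
    lambda_true <- matrix(1, S, 1)
    theta0_true <- build_theta0(2L, p, d, modal_prob = 0.99, phase = c(1L, 2L))
    theta1_true <- build_theta1(S, 1L, p, d, modal_prob = 0.99,
                                phase = matrix(c(3L, 4L), S, 1))
    nu_true <- matrix(0.5, S, p)
    subgroups <- NULL
  } else if (preset == "all_global") {
    if (is.null(size_factor)) size_factor <- 1
    S <- 1L; p <- 8L; d <- 4L
    n <- scale_n(800L, size_factor)
    pi_true <- c(0.5, 0.3, 0.2)
    lambda_true <- matrix(1, S, 1)
    theta0_true <- build_theta0(3L, p, d, modal_prob = 0.8)
    theta1_true <- build_theta1(S, 1L, p, d, modal_prob = 0.8)
    nu_true <- matrix(1, S, p)
    subgroups <- NULL
  } else { # local_lcm
    if (is.null(size_factor)) size_factor <- 1
    S <- 1L; p <- 8L; d <- 4L
    n <- scale_n(800L, size_factor)
    pi_true <- 1
    lambda_true <- matrix(c(0.5, 0.3, 0.2), S, 3, byrow = TRUE)
    theta0_true <- build_theta0(1L, p, d, modal_prob = 0.8)
    theta1_true <- build_theta1(S, 3L, p, d, modal_prob = 0.8,
                                phase = matrix(1:3, S, 3))
    nu_true <- matrix(0, S, p)
    subgroups <- NULL
  }
  truth_spec(n, p, d, pi_true, lambda_true, theta0_true, theta1_true,
             nu_true, seed = seed, subgroups = subgroups)
}
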