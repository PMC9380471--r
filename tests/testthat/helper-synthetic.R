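# Shared fixtures and small oracles for the test suite. Datasets are
# generated in code and cached per session.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, fn) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- fn()
  .fixture_env[[name]]
}

# a small labelled dataset with several perturbations and two gemgroups
small_dataset <- function() fixture("small", function() {
  cfg <- sim_config(seed = 7, n_perturbations = 6,
                    cells_per_gemgroup = 300)
  generate_dataset(cfg)
})

# normalization chain on a dataset that already carries truth labels
norm_chain <- function(ds, deg_threshold = 8) {
  um <- ds$expression %||% ds$experiment
  ctl <- unique(ds$truth$cells$perturbation[ds$truth$cells$is_control])
  factors <- compute_depth_factors(um, ctl)
  model <- fit_normalization(um, ctl, factors)
  list(um = um, controls = ctl, factors = factors, model = model,
       z = z_transform(um, model))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# all-control dataset for null calibration
null_dataset <- function() fixture("null", function() {
  cfg <- sim_config(seed = 21, n_perturbations = 0, frac_controls = 1,
                    n_control_constructs = 4, cells_per_gemgroup = 400)
  generate_expression(cfg)
})

# adjusted Rand index between two labelings
ari <- function(a, b) {
  t <- table(a, b)
  sij <- sum(choose(t, 2))
  si <- sum(choose(rowSums(t), 2))
  sj <- sum(choose(colSums(t), 2))
  N <- choose(sum(t), 2)
  (sij - si * sj / N) / ((si + sj) / 2 - si * sj / N)
}

# brute-force O(n^2) energy-distance oracle
energy_oracle <- function(X, Y) {
  if (is.vector(X)) X <- matrix(X, ncol = 1)
  if (is.vector(Y)) Y <- matrix(Y, ncol = 1)
  s <- 0
  for (i in seq_len(nrow(X))) for (j in seq_len(nrow(Y)))
    s <- s + sqrt(sum((X[i, ] - Y[j, ])^2))
  a <- 0
  for (i in seq_len(nrow(X))) for (j in seq_len(nrow(X)))
    a <- a + sqrt(sum((X[i, ] - X[j, ])^2))
  b <- 0
  for (i in seq_len(nrow(Y))) for (j in seq_len(nrow(Y)))
    b <- b + sqrt(sum((Y[i, ] - Y[j, ])^2))
  2 * s / (nrow(X) * nrow(Y)) - a / nrow(X)^2 - b / nrow(Y)^2
}

# three correlated perturbation modules with noise, rows = profiles
module_profiles <- function(n_per = 6, n_genes = 40, sep = 2, seed = 5) {
  set.seed(seed)
  sig <- matrix(rnorm(3 * n_genes, sd = sep), 3)
  P <- do.call(rbind, lapply(1:3, function(m)
    sig[rep(m, n_per), ] + matrix(rnorm(n_per * n_genes), n_per)))
  rownames(P) <- sprintf("pert_%02d", seq_len(3 * n_per))
  list(profile = P, truth = rep(1:3, each = n_per))
}
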