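# Shared fixtures, built in code. The default-scale simulation and pipeline
# run are computed once per session and cached, since several files probe
# different aspects of the same run.

fixture_env <- new.env(parent = emptyenv())

# small two-condition dataset with 3 planted modules; fast enough for unit
# tests of every stage
small_config <- function(seed = 11, ...) {
  args <- list(n_genes = 240, module_sizes = rep(60L, 3L),
               n_samples_per_condition = c(30L, 30L),
               n_dw_genes = 4L, n_de_genes = 8L, n_dv_genes = 8L,
               trait_driver_modules = c(pack_years = 1L,
                                        drinks_per_day = 2L),
               seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(synthetic_config, args)
}

small_sim <- function() {
  if (is.null(fixture_env$small)) fixture_env$small <-
      generate_dataset(small_config())
  fixture_env$small
}

default_sim <- function() {
  if (is.null(fixture_env$default)) fixture_env$default <-
      generate_dataset(synthetic_config(seed = 1))
  fixture_env$default
}

small_run <- function() {
  if (is.null(fixture_env$small_run)) {
    sim <- small_sim()
    fixture_env$small_run <- run_pipeline(
      sim$data, pipeline_config(min_module_size = 20, n_perm = 60,
                                seed = 11),
      out_dir = file.path(tempdir(), "diffwire-small-run"))
  }
  fixture_env$small_run
}

default_run <- function() {
  if (is.null(fixture_env$run)) {
    sim <- default_sim()
    fixture_env$run <- run_pipeline(
      sim$data, pipeline_config(seed = 1),
      out_dir = file.path(tempdir(), "diffwire-default-run"))
  }
  fixture_env$run
}

# deterministic random expression_dataset (no structure)
noise_dataset <- function(n_genes = 20, n1 = 10, n2 = 10, seed = 42) {
  set.seed(seed)
  vals <- matrix(abs(rnorm(n_genes * (n1 + n2), mean = 50, sd = 10)),
                 n_genes,
                 dimnames = list(sprintf("g%02d", 1:n_genes),
                                 sprintf("s%02d", 1:(n1 + n2))))
  expression_dataset(vals, rep(c("a", "b"), c(n1, n2)))
}

# random symmetric adjacency in [0,1] with unit diagonal
random_adjacency <- function(n, seed) {
  set.seed(seed)
  a <- matrix(runif(n * n), n)
  a <- (a + t(a)) / 2
  diag(a) <- 1
  dimnames(a) <- list(sprintf("g%02d", 1:n), sprintf("g%02d", 1:n))
  a
}

# block-structured similarity matrix: within-block value wv, between bv
block_similarity <- function(sizes, wv = 0.8, bv = 0.05) {
  n <- sum(sizes)
  s <- matrix(bv, n, n)
  at <- 1L
  for (sz in sizes) {
    idx <- at:(at + sz - 1L)
    s[idx, idx] <- wv
    at <- at + sz
  }
  diag(s) <- 1
  dimnames(s) <- list(sprintf("g%03d", 1:n), sprintf("g%03d", 1:n))
  s
}

expect_symmetric <- function(m, tol = 1e-10) {
  expect_lt(max(abs(m - t(m))), tol)
}
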