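test_that("search_config enforces its invariants", {
  expect_s3_class(search_config(), "glv_search_config")
  expect_error(search_config(n_restarts = 0))
  expect_error(search_config(step_contract = 1))
  expect_error(search_config(step_tol = 0.5, step_init = 0.2))
  expect_error(search_config(sparsity_weight = -1))
})

test_that("sample_initial_matrix is deterministic and correctly bounded", {
  set.seed(5); A1 <- sample_initial_matrix(4, 0.7)
  set.seed(5); A2 <- sample_initial_matrix(4, 0.7)
  expect_identical(A1, A2)
  set.seed(6)
  draws <- replicate(1000, sample_initial_matrix(3, 1))
  diags <- apply(draws, 3, diag)
  expect_true(all(diags <= 0 & diags >= -1))
  offs <- apply(draws, 3, function(A) A[row(A) != col(A)])
  expect_true(all(abs(offs) <= 1))
  # uniform moment check: mean of off-diagonals within 3 SE of 0
  se <- sqrt(1 / 3) / sqrt(length(offs))
  expect_lt(abs(mean(offs)), 3 * se)
})

test_that("objective reproduces elementary penalty cases", {
  cfg0 <- search_config(sparsity_weight = 0, stability_margin = 0)
  # stable 1-D interaction: no penalty at all
  expect_equal(glv_objective(matrix(-1, 1, 1), 1, cfg0), 0)
  # unstable: squared hinge on the spectral abscissa
  expect_equal(glv_objective(matrix(1, 1, 1), 1, cfg0), 1)
  # sparsity decomposition for a stable matrix
  A <- matrix(c(-1, 0.2, -0.3, -1), 2)
  cfgl <- search_config(sparsity_weight = 0.1, stability_margin = 0)
  expect_equal(glv_objective(A, c(1, 1), cfgl),
               glv_objective(A, c(1, 1), cfg0) + 0.1 * 0.5)
})

test_that("R and compiled objectives agree on random matrices", {
  set.seed(41)
  spec <- make_scenario("three_taxon",
                        overrides = list(n_subjects = 3, weeks = 3:8))
  ds <- generate_dataset(spec)
  rel <- relative_abundance(aggregate_taxa(ds$table, "phylum"))
  obs <- subject_trajectories(rel, ds$meta, spec$group)
  cfg <- search_config()
  y_bar <- spec$y_bar_true
  obsn <- glvnet:::normalize_observations(obs, 3, cfg$noise_cv,
                                          cfg$read_depth)
  for (rep in 1:10) {
    A <- sample_initial_matrix(3, 0.6)
    fr <- glv_objective(A, y_bar, cfg, obs)
    res <- glvnet:::compass_search_glv(
      A, y_bar, rep(0.05, 3), obsn, cfg$fit_weight, cfg$stability_margin,
      cfg$sparsity_weight, cfg$diag_constraint,
      # step_tol > step_init: searches nothing, returns f(A0)
      step_init = 1e-8, step_contract = 0.5, step_tol = 1,
      max_iters = 1)
    expect_equal(res$value, fr, tolerance = 1e-10)
  }
})

test_that("direct_search solves a separable quadratic", {
  cfg <- search_config(step_init = 1, step_tol = 1e-5, max_iters = 5000,
                       diag_constraint = FALSE)
  f <- function(A) (A[1, 1] - 3)^2
  res <- direct_search(f, matrix(0, 1, 1), cfg)
  expect_lt(abs(res$A[1, 1] - 3), 1e-4)
  expect_true(all(diff(res$trace) <= 0))
})

test_that("direct_search makes progress on the Rosenbrock function", {
  rosen <- function(A) (1 - A[1, 1])^2 + 100 * (A[1, 2] - A[1, 1]^2)^2
  A0 <- matrix(c(-1.2, 1), 1, 2)
  cfg <- search_config(step_init = 0.5, step_tol = 1e-6,
                       max_iters = 50000, diag_constraint = FALSE)
  res <- direct_search(rosen, A0, cfg)
  expect_lt(res$value, rosen(A0))
  expect_true(all(diff(res$trace) <= 0))
  expect_lt(res$value, 1e-2)
})

test_that("direct_search terminates on a constant objective", {
  cfg <- search_config(max_iters = 1000)
  res <- direct_search(function(A) 1, matrix(0, 2, 2), cfg)
  expect_identical(res$A, matrix(0, 2, 2))
  expect_equal(res$value, 1)
})

test_that("direct_search rejects non-finite polls but keeps going", {
  f <- function(A) {
    if (A[1, 1] < -2) return(NaN)
    (A[1, 1] + 1.9)^2
  }
  cfg <- search_config(step_init = 0.5, step_tol = 1e-4,
                       max_iters = 2000, diag_constraint = FALSE)
  res <- direct_search(f, matrix(0, 1, 1), cfg)
  expect_lt(abs(res$A[1, 1] + 1.9), 1e-3)
  expect_error(direct_search(function(A) NaN, matrix(0, 1, 1), cfg),
               "finite")
})

test_that("R and compiled compass searches find the same minimizer", {
  spec <- make_scenario("three_taxon",
                        overrides = list(n_subjects = 2, weeks = 3:7))
  ds <- generate_dataset(spec)
  rel <- relative_abundance(aggregate_taxa(ds$table, "phylum"))
  eq <- estimate_equilibrium(rel, ds$meta, spec$group, window = c(5, 7))
  obs <- subject_trajectories(rel, ds$meta, spec$group)
  cfg <- search_config(n_restarts = 2, max_iters = 800, seed = 3,
                       subsample_fraction = 1)
  ens_c <- infer_ensemble(eq, cfg, observations = obs, engine = "cpp")
  ens_r <- infer_ensemble(eq, cfg, observations = obs, engine = "r")
  for (k in seq_along(ens_c$solutions)) {
    expect_equal(ens_c$solutions[[k]]$A, ens_r$solutions[[k]]$A,
                 tolerance = 1e-6)
    expect_equal(ens_c$solutions[[k]]$objective,
                 ens_r$solutions[[k]]$objective, tolerance = 1e-8)
  }
})

test_that("l1_gauge maps to the sparsest column representative", {
  A <- matrix(c(-1, 0, 0.4, 0,
                0.5, -1, 0, 0,
                0, 0, -1, 0,
                0, 0, 0, -1), 4, 4, byrow = TRUE)
  # shifting a column by a constant is undone by the gauge
  Ashift <- A
  Ashift[, 2] <- Ashift[, 2] + 0.3
  g <- l1_gauge(Ashift)
  expect_equal(g[, 2][-2], A[, 2][-2], tolerance = 1e-12)
  # a matrix already in sparse gauge is a fixed point
  expect_equal(l1_gauge(A)[-1, 1], A[-1, 1])
})
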