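test_that("presets encode the designed treatment contrast and are stable", {
  ctl <- make_scenario("control")
  vnc <- make_scenario("vancomycin")
  # shared facilitation of Verrucomicrobia by Bacteroidetes
  expect_gt(ctl$A_true["Verrucomicrobia", "Bacteroidetes"], 0)
  expect_gt(vnc$A_true["Verrucomicrobia", "Bacteroidetes"], 0)
  # the Proteobacteria hub exists only without treatment
  hub_targets <- c("Actinobacteria", "Bacteroidetes", "Verrucomicrobia")
  expect_true(all(ctl$A_true[hub_targets, "Proteobacteria"] != 0))
  expect_true(all(vnc$A_true[hub_targets, "Proteobacteria"] == 0))
  expect_true(all(vnc$A_true[, "Proteobacteria"][-5] == 0))
  # Firmicutes facilitate Verrucomicrobia only under treatment
  expect_identical(ctl$A_true["Verrucomicrobia", "Firmicutes"], 0)
  expect_gt(vnc$A_true["Verrucomicrobia", "Firmicutes"], 0)
  # both pass the stability check at construction (invariant) — and the
  # constructor rejects destabilized overrides, naming the abscissa
  expect_error(
    make_scenario("control",
                  overrides = list(A_true = {
                    A <- ctl$A_true; diag(A) <- 0.5; A
                  })),
    "spectral abscissa")
})

test_that("every sample column sums exactly to the sequencing depth", {
  spec <- make_scenario("three_taxon",
                        overrides = list(n_subjects = 3, depth = 5000))
  ds <- generate_dataset(spec)
  expect_true(all(colSums(ds$table$values) == 5000))
  expect_equal(length(ds$table$samples),
               3 * length(spec$weeks))
  expect_identical(ds$meta$sample, ds$table$samples)
})

test_that("generation is deterministic under the scenario seed", {
  spec <- make_scenario("three_taxon", overrides = list(n_subjects = 2))
  d1 <- generate_dataset(spec)
  d2 <- generate_dataset(spec)
  expect_identical(d1$table$values, d2$table$values)
  expect_identical(as.data.frame(d1$meta), as.data.frame(d2$meta))
  d3 <- generate_dataset(make_scenario("three_taxon",
                                       overrides = list(n_subjects = 2,
                                                        seed = 99L)))
  expect_false(identical(d1$table$values, d3$table$values))
})

test_that("the noiseless deep-sequencing limit approaches the equilibrium", {
  spec <- make_scenario("control",
                        overrides = list(process_noise = 0, start_noise = 0,
                                         depth = 1e7, n_subjects = 2))
  ds <- generate_dataset(spec)
  rel <- relative_abundance(aggregate_taxa(ds$table, "phylum"))
  late <- ds$meta$week >= 14
  late_states <- rel$values[, late, drop = FALSE]
  err <- abs(sweep(late_states, 1, spec$y_bar_true))
  expect_lt(max(err), 0.01)
})

test_that("custom scenarios require the core fields", {
  expect_error(make_scenario("custom"), "overrides")
  sp <- make_scenario("custom", overrides = list(
    taxa = c("A", "B"), A_true = diag(c(-1, -1)),
    y_bar_true = c(0.5, 0.5), y0 = c(0.4, 0.6)))
  expect_equal(unname(sp$r_true), c(0.5, 0.5))
  expect_s3_class(sp, "glv_scenario")
})

test_that("true_network lists exactly the nonzero off-diagonal influences", {
  spec <- make_scenario("three_taxon")
  net <- true_network(spec)
  expect_equal(nrow(net$edges), 3)
  key <- paste(net$edges$source, net$edges$target)
  expect_setequal(key, c("Firmicutes Bacteroidetes",
                         "Proteobacteria Firmicutes",
                         "Bacteroidetes Proteobacteria"))
  expect_true(all(net$edges$support == 1))
})

test_that("equilibrium estimates sharpen with depth and cohort size", {
  lo <- make_scenario("three_taxon",
                      overrides = list(depth = 1e3, n_subjects = 4))
  hi <- make_scenario("three_taxon",
                      overrides = list(depth = 1e5, n_subjects = 16))
  err <- function(spec) {
    ds <- generate_dataset(spec)
    rel <- relative_abundance(aggregate_taxa(ds$table, "phylum"))
    eq <- estimate_equilibrium(rel, ds$meta, spec$group,
                               window = c(11, 15))
    mean(abs(eq$y_bar - spec$y_bar_true) / spec$y_bar_true)
  }
  expect_lt(err(hi), err(lo))
})

test_that("subject trajectories carry ordered weeks and positive weights", {
  spec <- make_scenario("three_taxon", overrides = list(n_subjects = 3))
  ds <- generate_dataset(spec)
  rel <- relative_abundance(aggregate_taxa(ds$table, "phylum"))
  obs <- subject_trajectories(rel, ds$meta, spec$group)
  expect_length(obs, 3)
  for (ob in obs) {
    expect_identical(ob$times, as.numeric(spec$weeks))
    expect_true(all(diff(ob$times) > 0))
    expect_true(all(ob$weights > 0))
    expect_equal(dim(ob$states), dim(ob$weights))
    expect_equal(unname(rowSums(ob$states)), rep(1, nrow(ob$states)),
                 tolerance = 1e-8)
  }
})
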