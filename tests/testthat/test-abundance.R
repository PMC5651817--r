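make_tiny_table <- function() {
  abundance_table(matrix(c(3, 1, 0, 2, 6, 2), 3, 2),
                  taxa = c("k__Bacteria;p__Firmicutes;o__Clostridiales",
                           "k__Bacteria;p__Firmicutes;o__Lactobacillales",
                           "k__Bacteria;p__Bacteroidetes;o__Bacteroidales"),
                  samples = c("s1", "s2"))
}

test_that("abundance tables validate and TSV round-trips exactly", {
  tab <- make_tiny_table()
  p <- withr::local_tempfile(fileext = ".tsv")
  write_abundance(tab, p)
  tab2 <- read_abundance(p)
  expect_identical(tab2$taxa, tab$taxa)
  expect_identical(tab2$samples, tab$samples)
  expect_equal(tab2$values, tab$values)
  expect_false(tab2$is_relative)

  expect_error(abundance_table(matrix(-1, 1, 1), "t", "s"), "negative")
  expect_error(abundance_table(matrix(1, 2, 1), c("t", "t"), "s"),
               "unique")
  expect_error(abundance_table(matrix(1, 1, 2), "t", c("s", "s")),
               "unique")
})

test_that("read_abundance reports malformed input precisely", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("taxonomy\ts1\ts2", "t1\t1\t2", "t2\t3\tno"), p)
  expect_error(read_abundance(p), "row 3.*s2")
  writeLines(c("taxonomy\ts1\ts2", "t1\t1"), p)
  expect_error(read_abundance(p), "fields")
})

test_that("an all-zero sample column is kept and floored downstream", {
  tab <- abundance_table(matrix(c(3, 1, 0, 0), 2, 2),
                         taxa = c("a", "b"), samples = c("s1", "s2"))
  rel <- relative_abundance(tab)
  expect_true(all(rel$values > 0))
  expect_equal(colSums(rel$values), c(s1 = 1, s2 = 1))
  expect_error(relative_abundance(tab, floor = 0), "all zeros")
})

test_that("aggregation sums ranks, pools unlabeled, conserves column sums", {
  tab <- make_tiny_table()
  ph <- aggregate_taxa(tab, "phylum")
  expect_identical(ph$taxa, c("Bacteroidetes", "Firmicutes"))
  expect_equal(unname(ph$values["Firmicutes", ]), c(4, 8))
  expect_equal(colSums(ph$values), colSums(tab$values))

  tab2 <- abundance_table(matrix(c(1, 5), 2, 1),
                          taxa = c("k__Bacteria;p__;o__", "k__Bacteria"),
                          samples = "s1")
  ph2 <- aggregate_taxa(tab2, "phylum")
  expect_identical(ph2$taxa, "unclassified")
  expect_error(aggregate_taxa(tab, "banana"))
})

test_that("the seven phyla aggregate to seven named rows", {
  spec <- make_scenario("control", overrides = list(n_subjects = 1))
  ds <- generate_dataset(spec)
  ph <- aggregate_taxa(ds$table, "phylum")
  expect_identical(ph$taxa,
                   c("Actinobacteria", "Bacteroidetes", "Cyanobacteria",
                     "Firmicutes", "Proteobacteria", "Tenericutes",
                     "Verrucomicrobia"))
})

test_that("aggregation and the relative transform commute", {
  set.seed(51)
  values <- matrix(stats::rpois(8 * 5, 40) + 1, 8, 5)
  lineages <- sprintf("k__Bacteria;p__P%d;o__O%d", rep(1:4, each = 2), 1:8)
  tab <- abundance_table(values, lineages, paste0("s", 1:5))
  a <- relative_abundance(aggregate_taxa(tab, "phylum"), floor = 0)
  b <- aggregate_taxa(relative_abundance(tab, floor = 0), "phylum")
  expect_equal(a$values, b$values, tolerance = 1e-12)
})

test_that("relative_abundance produces unit columns on random tables", {
  set.seed(52)
  values <- matrix(stats::rpois(30, 10), 6, 5)
  tab <- abundance_table(values, paste0("t", 1:6), paste0("s", 1:5))
  rel <- relative_abundance(tab)
  expect_true(all(abs(colSums(rel$values) - 1) < 1e-12))
  expect_equal(unname(relative_abundance(
    abundance_table(matrix(c(3, 1), 2, 1), c("a", "b"), "s"))$values[, 1]),
    c(0.75, 0.25))
})

test_that("metadata validates and round-trips", {
  meta <- sample_metadata(c("s1", "s2"), c("m1", "m1"), c(3, 4), "ctl")
  p <- withr::local_tempfile(fileext = ".tsv")
  write_metadata(meta, p)
  meta2 <- read_metadata(p)
  expect_equal(as.data.frame(meta2), as.data.frame(meta))
  expect_error(sample_metadata(c("s1", "s1"), c("a", "b"), 1:2, "g"),
               "unique")
})

test_that("estimate_equilibrium averages the window and honors selection", {
  vals <- cbind(c(0.2, 0.8), c(0.4, 0.6), c(0.9, 0.1))
  tab <- abundance_table(vals, c("a", "b"), c("s1", "s2", "s3"),
                         is_relative = TRUE)
  meta <- sample_metadata(c("s1", "s2", "s3"), c("m1", "m2", "m3"),
                          c(10, 11, 2), c("ctl", "ctl", "ctl"))
  eq <- estimate_equilibrium(tab, meta, "ctl", window = c(9, 15))
  expect_equal(unname(eq$y_bar), c(0.3, 0.7))
  # out-of-window samples are a no-op
  eq_all <- estimate_equilibrium(tab, meta, "ctl", window = c(9, 20))
  expect_equal(eq$y_bar, eq_all$y_bar)
  expect_error(estimate_equilibrium(tab, meta, "ctl", window = c(1, 2)),
               ">= 2 samples")
  counts <- abundance_table(matrix(1:4, 2, 2), c("a", "b"), c("s1", "s2"))
  expect_error(estimate_equilibrium(counts, meta, "ctl"), "relative")
})

test_that("estimate_equilibrium is invariant to sample order", {
  spec <- make_scenario("three_taxon", overrides = list(n_subjects = 3))
  ds <- generate_dataset(spec)
  rel <- relative_abundance(aggregate_taxa(ds$table, "phylum"))
  eq1 <- estimate_equilibrium(rel, ds$meta, spec$group, window = c(11, 15))
  set.seed(61)
  perm <- sample(length(rel$samples))
  rel2 <- abundance_table(rel$values[, perm], rel$taxa,
                          rel$samples[perm], is_relative = TRUE)
  eq2 <- estimate_equilibrium(rel2, ds$meta, spec$group,
                              window = c(11, 15))
  expect_equal(eq1$y_bar, eq2$y_bar)
})

test_that("BIOM-JSON tables can be read", {
  skip_if_not_installed("biomformat")
  tab <- make_tiny_table()
  # build a minimal BIOM v1 (JSON) document by hand
  doc <- list(
    id = "test", format = "Biological Observation Matrix 1.0.0",
    format_url = "http://biom-format.org",
    type = "OTU table", generated_by = "glvnet-test",
    date = "2026-01-01T00:00:00",
    matrix_type = "dense", matrix_element_type = "int",
    shape = c(3L, 2L),
    rows = lapply(tab$taxa, function(t) list(id = t, metadata = NULL)),
    columns = lapply(tab$samples,
                     function(s) list(id = s, metadata = NULL)),
    data = unname(split(unname(tab$values), seq_len(3)))
  )
  p <- withr::local_tempfile(fileext = ".biom")
  jsonlite::write_json(doc, p, auto_unbox = TRUE, digits = NA)
  tab2 <- read_abundance(p, format = "biom-json")
  expect_setequal(tab2$taxa, tab$taxa)
  expect_equal(tab2$values[tab$taxa, tab$samples], tab$values)
})
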