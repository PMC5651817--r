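fake_ensemble <- function(mats, taxa = NULL) {
  n <- nrow(mats[[1]])
  if (is.null(taxa)) taxa <- paste0("t", seq_len(n))
  sols <- lapply(seq_along(mats), function(k) {
    A <- mats[[k]]
    dimnames(A) <- list(taxa, taxa)
    list(A = A, r = rep(0, n), objective = 0, spectral_abscissa = -1,
         residual_max = 0, accepted = TRUE, restart = k)
  })
  structure(list(solutions = sols, y_bar = rep(1 / n, n), taxa = taxa,
                 config = search_config()), class = "glv_ensemble")
}

test_that("a unanimous ensemble yields the corresponding edge", {
  A <- matrix(c(-1, 0.5, 0, -1), 2)  # a_21 = +0.5: taxon 1 influences 2
  ens <- fake_ensemble(list(A, A, A))
  net <- consensus_network(ens)
  expect_equal(nrow(net$edges), 1)
  expect_identical(net$edges$source, "t1")
  expect_identical(net$edges$target, "t2")
  expect_equal(net$edges$sign, 1)
  expect_equal(net$edges$weight, 0.5)
  expect_equal(net$edges$support, 1)
  # self-limitation reported separately, never as an edge
  expect_equal(net$self_limitation$median_a_ii, c(-1, -1))
})

test_that("edges below the support or strength threshold are excluded", {
  Apos <- matrix(c(-1, 0.5, 0, -1), 2)
  Aneg <- matrix(c(-1, -0.5, 0, -1), 2)
  ens <- fake_ensemble(list(Apos, Apos, Aneg, Aneg))
  net <- consensus_network(ens, sign_support = 0.9)
  expect_equal(nrow(net$edges), 0)
  weak <- matrix(c(-1, 0.03, 0, -1), 2)
  expect_equal(nrow(consensus_network(fake_ensemble(list(weak)))$edges), 0)
  empty <- fake_ensemble(list(Apos))
  empty$solutions[[1]]$accepted <- FALSE
  expect_error(consensus_network(empty), "no accepted")
})

test_that("edge lists and GraphML round-trip the signed graph", {
  A <- matrix(c(-1, 0.4, -0.2, 0, -1, 0, 0.3, 0, -1), 3, byrow = TRUE)
  ens <- fake_ensemble(list(A), taxa = c("Alpha", "Beta", "Gamma"))
  net <- consensus_network(ens)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_edgelist_tsv(net, p)
  net2 <- read_edgelist_tsv(p, nodes = net$nodes)
  expect_equal(net2$edges$source, net$edges$source)
  expect_equal(net2$edges$sign, net$edges$sign)
  expect_equal(net2$edges$weight, net$edges$weight, tolerance = 1e-6)

  g <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(net, g)
  net3 <- read_graphml(g)
  expect_setequal(net3$nodes, net$nodes)
  expect_equal(net3$edges[, c("source", "target", "sign")],
               net$edges[, c("source", "target", "sign")])
  expect_equal(net3$edges$weight, net$edges$weight, tolerance = 1e-6)
})

test_that("compare_networks partitions edge changes exhaustively", {
  mk <- function(edges) signed_network(c("a", "b", "c"), edges)
  e <- function(...) data.frame(..., stringsAsFactors = FALSE)
  n1 <- mk(e(source = c("a", "b", "c"), target = c("b", "c", "a"),
             sign = c(1, -1, 1), weight = c(0.5, 0.4, 0.3),
             support = 1))
  # identical networks: every diff list empty
  d0 <- compare_networks(n1, n1)
  expect_equal(nrow(d0$edges_only_in_first), 0)
  expect_equal(nrow(d0$edges_only_in_second), 0)
  expect_equal(nrow(d0$sign_flips), 0)
  expect_equal(nrow(d0$weight_changes), 0)
  expect_equal(nrow(d0$unchanged), 3)

  n2 <- mk(e(source = c("a", "b"), target = c("b", "c"),
             sign = c(-1, -1), weight = c(0.5, 0.4 + 1e-9),
             support = 1))
  d <- compare_networks(n1, n2)
  expect_equal(nrow(d$edges_only_in_first), 1)   # c -> a lost
  expect_equal(nrow(d$edges_only_in_second), 0)
  expect_equal(nrow(d$sign_flips), 1)            # a -> b flipped
  expect_equal(nrow(d$weight_changes), 0)        # below tolerance
  n3 <- mk(e(source = "a", target = "b", sign = 1, weight = 0.9,
             support = 1))
  d2 <- compare_networks(n1, n3)
  expect_equal(nrow(d2$weight_changes), 1)
  expect_error(compare_networks(n1, signed_network("a",
    e(source = character(), target = character(), sign = numeric(),
      weight = numeric(), support = numeric()))), "node sets differ")
})

test_that("preset ground-truth networks diff exactly as designed", {
  ctl <- true_network(make_scenario("control"))
  vnc <- true_network(make_scenario("vancomycin"))
  d <- compare_networks(ctl, vnc)
  lost <- paste(d$edges_only_in_first$source, d$edges_only_in_first$target,
                sep = "->")
  gained <- paste(d$edges_only_in_second$source,
                  d$edges_only_in_second$target, sep = "->")
  expect_setequal(lost, c("Proteobacteria->Actinobacteria",
                          "Proteobacteria->Bacteroidetes",
                          "Proteobacteria->Verrucomicrobia",
                          "Bacteroidetes->Proteobacteria"))
  expect_identical(gained, "Firmicutes->Verrucomicrobia")
  expect_equal(nrow(d$sign_flips), 0)
})

test_that("diff reports write a readable summary", {
  ctl <- true_network(make_scenario("control"))
  vnc <- true_network(make_scenario("vancomycin"))
  d <- compare_networks(ctl, vnc)
  p <- withr::local_tempfile(fileext = ".txt")
  write_diff_report(d, p)
  txt <- readLines(p)
  expect_true(any(grepl("Firmicutes -> Verrucomicrobia", txt)))
})
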