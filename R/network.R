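#' Construct a signed directed network
#'
#' @param nodes Character vector of taxon labels.
#' @param edges Data frame with columns `source`, `target`,
#'   `sign` (+1/-1), `weight` (>= 0), `support` (in `[0, 1]`).
#' @param self_limitation Optional data frame of per-taxon diagonal
#'   interaction strengths (reported separately from the graph, which
#'   carries inter-taxon influence only).
#' @return A `signed_network`.
#' @export
signed_network <- function(nodes, edges, self_limitation = NULL) {
  need <- c("source", "target", "sign", "weight", "support")
  if (!all(need %in% names(edges))) {
    stop("edges must have columns ", paste(need, collapse = ", "))
  }
  bad <- !(edges$source %in% nodes) | !(edges$target %in% nodes)
  if (any(bad)) stop("edge endpoints must be in the node set")
  if (any(edges$source == edges$target)) {
    stop("consensus edges must not contain self-loops")
  }
  if (any(!edges$sign %in% c(-1, 1)) || any(edges$weight < 0) ||
      any(edges$support < 0 | edges$support > 1)) {
    stop("invalid edge attributes")
  }
  rownames(edges) <- NULL
  structure(list(nodes = as.character(nodes), edges = edges,
                 self_limitation = self_limitation),
            class = "signed_network")
}

#' @export
print.signed_network <- function(x, ...) {
  cat(sprintf("signed network: %d nodes, %d edges (%d positive, %d negative)\n",
              length(x$nodes), nrow(x$edges), sum(x$edges$sign > 0),
              sum(x$edges$sign < 0)))
  if (nrow(x$edges)) {
    ord <- order(-x$edges$weight)
    df <- x$edges[ord, ]
    apply(df, 1, function(e) {
      cat(sprintf("  %s -> %s  %s%.3f (support %.2f)\n", e[["source"]],
                  e[["target"]], if (as.numeric(e[["sign"]]) > 0) "+" else "-",
                  as.numeric(e[["weight"]]), as.numeric(e[["support"]])))
    })
  }
  invisible(x)
}

#' Distill a solution ensemble into a consensus signed network
#'
#' For every ordered taxon pair `j -> i` (the influence of taxon `j` on
#' taxon `i`, entry `a_ij` of the interaction matrix), the edge is included
#' when the median of `a_ij` over accepted solutions has magnitude at least
#' `strength_floor` and the fraction of accepted solutions agreeing with
#' the median's sign is at least `sign_support`. Edge weight is the
#' absolute median, sign the median's sign, support the agreement
#' fraction. Diagonal entries (self-limitation) are summarized separately
#' and never appear as graph edges.
#'
#' @param ensemble A `glv_ensemble` with at least one accepted solution.
#' @param sign_support Minimum sign-agreement fraction (default 0.8).
#' @param strength_floor Minimum absolute median interaction strength
#'   (default 0.05).
#' @return A `signed_network`.
#' @export
consensus_network <- function(ensemble, sign_support = 0.8,
                              strength_floor = 0.05) {
  sols <- accepted_solutions(ensemble)
  if (length(sols) == 0) stop("ensemble has no accepted solutions")
  taxa <- ensemble$taxa
  n <- length(taxa)
  stack <- vapply(sols, function(s) unname(s$A), matrix(0, n, n))
  edges <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      vals <- stack[i, j, ]
      med <- stats::median(vals)
      if (abs(med) < strength_floor) next
      support <- mean(sign(vals) == sign(med))
      if (support < sign_support) next
      edges[[length(edges) + 1]] <- data.frame(
        source = taxa[j], target = taxa[i], sign = sign(med),
        weight = abs(med), support = support, stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(source = character(), target = character(),
               sign = numeric(), weight = numeric(), support = numeric(),
               stringsAsFactors = FALSE)
  edges <- edges[order(edges$source, edges$target), , drop = FALSE]
  selfd <- data.frame(
    taxon = taxa,
    median_a_ii = vapply(seq_len(n),
                         function(i) stats::median(stack[i, i, ]),
                         numeric(1)),
    stringsAsFactors = FALSE)
  signed_network(taxa, edges, self_limitation = selfd)
}

#' Write a signed network as an edge-list TSV
#'
#' Columns: source, target, sign, weight, support. Self-limitation terms,
#' if present, go to a companion `*_self_limitation.tsv` file.
#'
#' @param network A `signed_network`.
#' @param path Output TSV path.
#' @export
write_edgelist_tsv <- function(network, path) {
  df <- network$edges
  df$sign <- ifelse(df$sign > 0, "+", "-")
  df$weight <- sprintf("%.6f", df$weight)
  df$support <- sprintf("%.4f", df$support)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(network$self_limitation)) {
    sp <- sub("\\.tsv$", "_self_limitation.tsv", path)
    sl <- network$self_limitation
    sl$median_a_ii <- sprintf("%.6f", sl$median_a_ii)
    utils::write.table(sl, sp, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a signed network from an edge-list TSV
#' @param path TSV written by [write_edgelist_tsv()].
#' @param nodes Optional full node set (isolated nodes are not
#'   recoverable from the edge list alone).
#' @export
read_edgelist_tsv <- function(path, nodes = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(sign = "character"))
  df$sign <- ifelse(df$sign == "+", 1, -1)
  df$weight <- as.numeric(df$weight)
  df$support <- as.numeric(df$support)
  if (is.null(nodes)) nodes <- sort(unique(c(df$source, df$target)))
  signed_network(nodes, df)
}

#' Export a signed network to GraphML
#'
#' Nodes carry a `name` attribute; edges carry `sign`, `weight` and
#' `support`. The file re-imports (with [read_graphml()]) to an isomorphic
#' signed graph.
#'
#' @param network A `signed_network`.
#' @param path Output `.graphml` path.
#' @export
write_graphml <- function(network, path) {
  g <- igraph::graph_from_data_frame(
    network$edges[, c("source", "target", "sign", "weight", "support")],
    directed = TRUE,
    vertices = data.frame(name = network$nodes))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Import a signed network from GraphML written by [write_graphml()]
#' @param path `.graphml` path.
#' @export
read_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  el <- igraph::as_data_frame(g, what = "edges")
  names(el)[1:2] <- c("source", "target")
  el <- el[order(el$source, el$target), , drop = FALSE]
  signed_network(igraph::V(g)$name, el)
}

edge_key <- function(edges) paste(edges$source, edges$target, sep = " -> ")

#' Compare two signed networks over the same node set
#'
#' Classifies every edge key present in either network into exactly one of:
#' present only in the first, present only in the second, present in both
#' with opposite signs (`sign_flips`), present in both with the same sign
#' but a weight change above `weight_tol` (`weight_changes`), or unchanged.
#'
#' @param n1,n2 `signed_network`s with identical node sets.
#' @param weight_tol Weight changes at or below this are not reported.
#' @return A `network_diff` with data frames `edges_only_in_first`,
#'   `edges_only_in_second`, `sign_flips`, `weight_changes`, `unchanged`.
#' @export
compare_networks <- function(n1, n2, weight_tol = 1e-6) {
  if (!setequal(n1$nodes, n2$nodes)) {
    stop("node sets differ: ",
         paste(c(setdiff(n1$nodes, n2$nodes), setdiff(n2$nodes, n1$nodes)),
               collapse = ", "))
  }
  k1 <- edge_key(n1$edges); k2 <- edge_key(n2$edges)
  e1 <- n1$edges; e2 <- n2$edges
  only1 <- e1[!(k1 %in% k2), , drop = FALSE]
  only2 <- e2[!(k2 %in% k1), , drop = FALSE]
  common <- intersect(k1, k2)
  i1 <- match(common, k1); i2 <- match(common, k2)
  flips <- e1$sign[i1] != e2$sign[i2]
  dw <- abs(e1$weight[i1] - e2$weight[i2])
  changed <- !flips & dw > weight_tol
  both <- data.frame(
    source = e1$source[i1], target = e1$target[i1],
    sign_first = e1$sign[i1], sign_second = e2$sign[i2],
    weight_first = e1$weight[i1], weight_second = e2$weight[i2],
    stringsAsFactors = FALSE)
  out <- list(edges_only_in_first = only1,
              edges_only_in_second = only2,
              sign_flips = both[flips, , drop = FALSE],
              weight_changes = both[changed, , drop = FALSE],
              unchanged = both[!flips & !changed, , drop = FALSE])
  out <- lapply(out, function(d) { rownames(d) <- NULL; d })
  structure(out, class = "network_diff")
}

#' @export
print.network_diff <- function(x, ...) {
  cat(sprintf(paste0(
    "network diff: %d only in first, %d only in second, ",
    "%d sign flips, %d weight changes, %d unchanged\n"),
    nrow(x$edges_only_in_first), nrow(x$edges_only_in_second),
    nrow(x$sign_flips), nrow(x$weight_changes), nrow(x$unchanged)))
  show <- function(label, d) {
    if (nrow(d)) {
      cat(" ", label, ":\n", sep = "")
      for (k in seq_len(nrow(d))) {
        cat(sprintf("    %s -> %s\n", d$source[k], d$target[k]))
      }
    }
  }
  show("only in first", x$edges_only_in_first)
  show("only in second", x$edges_only_in_second)
  show("sign flips", x$sign_flips)
  invisible(x)
}

#' Write a network diff as a plain-text report
#' @param diff A `network_diff`.
#' @param path Output path.
#' @export
write_diff_report <- function(diff, path) {
  fmt <- function(d) {
    if (!nrow(d)) return("  (none)")
    paste0("  ", d$source, " -> ", d$target, collapse = "\n")
  }
  txt <- c(
    "edges only in first:", fmt(diff$edges_only_in_first),
    "edges only in second:", fmt(diff$edges_only_in_second),
    "sign flips:", fmt(diff$sign_flips),
    "weight changes:", fmt(diff$weight_changes),
    "unchanged:", fmt(diff$unchanged))
  writeLines(txt, path)
  invisible(path)
}
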