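#!/usr/bin/env Rscript
# Stage 4: consensus networks, ground-truth scoring, and the treatment
# contrast.
#
# Each ensemble is distilled into a signed consensus network (edge kept
# when >= 80% of accepted solutions agree on the sign of its median
# strength, and the median is at least 0.05). The consensus networks are
# exported as edge lists and GraphML, scored against the known
# ground-truth networks, and the control and vancomycin networks are
# compared edge by edge.

library(glvnet)

nets <- list()
for (name in c("control", "vancomycin", "three_taxon")) {
  ens <- read_ensemble_json(file.path("results",
                                      paste0(name, "_ensemble.json")))
  net <- consensus_network(ens)
  nets[[name]] <- net
  cat("\n==", name, "consensus ==\n")
  print(net)
  write_edgelist_tsv(net, file.path("results", paste0(name, "_edges.tsv")))
  write_graphml(net, file.path("results", paste0(name, "_network.graphml")))

  truth <- true_network(make_scenario(name))
  tr <- truth$edges[truth$edges$weight >= 0.1, , drop = FALSE]
  hits <- vapply(seq_len(nrow(tr)), function(k) {
    any(net$edges$source == tr$source[k] &
          net$edges$target == tr$target[k] &
          net$edges$sign == tr$sign[k])
  }, logical(1))
  cat(sprintf("sign recovery: %d/%d strong true edges%s\n",
              sum(hits), nrow(tr),
              if (all(hits)) "" else paste0(" (missing: ",
                paste(tr$source[!hits], "->", tr$target[!hits],
                      collapse = ", "), ")")))
}

cat("\n== control vs vancomycin ==\n")
d <- compare_networks(nets$control, nets$vancomycin)
print(d)
write_diff_report(d, "results/diff_control_vs_vancomycin.txt")

hub <- c("Proteobacteria->Actinobacteria", "Proteobacteria->Bacteroidetes",
         "Proteobacteria->Verrucomicrobia")
lost <- paste(d$edges_only_in_first$source, d$edges_only_in_first$target,
              sep = "->")
gained <- paste(d$edges_only_in_second$source,
                d$edges_only_in_second$target, sep = "->")
cat(sprintf("\nProteobacteria hub edges lost under treatment: %d/3\n",
            sum(hub %in% lost)))
cat(sprintf("Firmicutes->Verrucomicrobia gained under treatment: %s\n",
            "Firmicutes->Verrucomicrobia" %in% gained))
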