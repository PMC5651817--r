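# Shared full-scale recovery runs (the expensive part of the suite).
# Computed lazily once per session and reused across test files.

recovery_cache <- new.env(parent = emptyenv())

recovery_run <- function(name) {
  if (!is.null(recovery_cache[[name]])) return(recovery_cache[[name]])
  spec <- make_scenario(name)
  ds <- generate_dataset(spec)
  rel <- relative_abundance(aggregate_taxa(ds$table, "phylum"))
  eq <- estimate_equilibrium(rel, ds$meta, spec$group, window = c(11, 15))
  obs <- subject_trajectories(rel, ds$meta, spec$group)
  ens <- infer_ensemble(eq, search_config(n_restarts = 200),
                        observations = obs)
  out <- list(spec = spec, equilibrium = eq,
              ensemble = ens, network = consensus_network(ens))
  recovery_cache[[name]] <- out
  out
}

# fraction of ground-truth edges (with |a_ij| >= 2 * strength_floor)
# whose sign the consensus network reproduces
sign_recovery_rate <- function(network, spec, strength_floor = 0.05) {
  tr <- true_network(spec)$edges
  tr <- tr[tr$weight >= 2 * strength_floor, , drop = FALSE]
  hits <- vapply(seq_len(nrow(tr)), function(k) {
    any(network$edges$source == tr$source[k] &
          network$edges$target == tr$target[k] &
          network$edges$sign == tr$sign[k])
  }, logical(1))
  mean(hits)
}
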