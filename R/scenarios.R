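phyla7 <- c("Actinobacteria", "Bacteroidetes", "Cyanobacteria",
            "Firmicutes", "Proteobacteria", "Tenericutes",
            "Verrucomicrobia")

# order-level lineages the generator emits, so phylum aggregation is
# exercised end-to-end; fractions split each phylum among its orders
order_splits <- list(
  Actinobacteria  = c("o__Bifidobacteriales" = 1),
  Bacteroidetes   = c("o__Bacteroidales" = 1),
  Cyanobacteria   = c("o__YS2" = 1),
  Firmicutes      = c("o__Clostridiales" = 0.7, "o__Lactobacillales" = 0.3),
  Proteobacteria  = c("o__Enterobacteriales" = 0.6,
                      "o__Desulfovibrionales" = 0.4),
  Tenericutes     = c("o__Anaeroplasmatales" = 1),
  Verrucomicrobia = c("o__Verrucomicrobiales" = 1)
)

edge_list_to_matrix <- function(taxa, diagonal, edges) {
  n <- length(taxa)
  A <- matrix(0, n, n, dimnames = list(taxa, taxa))
  diag(A) <- diagonal
  for (e in edges) {
    # e = (source j, target i, a_ij): influence of source on target
    A[e[[2]], e[[1]]] <- e[[3]]
  }
  A
}

scenario_defaults <- function(name) {
  # Preset design notes. Weekly compositional data identify an interaction
  # only when its source taxon's abundance actually varies across samples,
  # and the window-mean equilibrium estimate is only trustworthy for taxa
  # whose own relaxation rate (ybar_i |a_ii|, per week) lets them settle
  # within the sampled horizon. The presets therefore (i) put the large
  # developmental transients on the abundant, fast-relaxing phyla, (ii)
  # start slow rare phyla close to their steady level, and (iii) place
  # edges so that every interaction's source is a phylum with a real
  # transient (plus subject-to-subject scatter from start_noise).
  if (name == "three_taxon") {
    taxa <- c("Bacteroidetes", "Firmicutes", "Proteobacteria")
    A <- edge_list_to_matrix(
      taxa, diagonal = c(-1.0, -0.9, -1.5),
      edges = list(
        list("Firmicutes", "Bacteroidetes", 0.5),
        list("Proteobacteria", "Firmicutes", -0.45),
        list("Bacteroidetes", "Proteobacteria", 0.4)
      ))
    y_bar <- c(Bacteroidetes = 0.40, Firmicutes = 0.40,
               Proteobacteria = 0.20)
    # starting composition solved (noiseless flow) so that the week-11..15
    # window mean of each taxon matches its equilibrium
    y0 <- c(Bacteroidetes = 0.28, Firmicutes = 0.44,
            Proteobacteria = 0.28)
    group <- "three_taxon"
  } else if (name == "control") {
    taxa <- phyla7
    # untreated community: Proteobacteria act as an interaction hub with
    # Actinobacteria, Bacteroidetes and Verrucomicrobia; Bacteroidetes
    # facilitate Verrucomicrobia
    A <- edge_list_to_matrix(
      taxa,
      diagonal = c(-1.5, -1.5, -1.2, -0.6, -1.5, -1.3, -1.4),
      edges = list(
        list("Bacteroidetes", "Verrucomicrobia", 0.6),    # shared edge
        list("Firmicutes", "Bacteroidetes", -0.5),        # shared edge
        list("Proteobacteria", "Actinobacteria", 0.5),    # hub, control only
        list("Proteobacteria", "Bacteroidetes", -0.5),    # hub, control only
        list("Proteobacteria", "Verrucomicrobia", -0.45), # hub, control only
        list("Bacteroidetes", "Proteobacteria", -0.45)    # hub, control only
      ))
    y_bar <- c(Actinobacteria = 0.09, Bacteroidetes = 0.26,
               Cyanobacteria = 0.03, Firmicutes = 0.30,
               Proteobacteria = 0.15, Tenericutes = 0.05,
               Verrucomicrobia = 0.12)
    # week-3 gut: milk-adapted Firmicutes dominant, Bacteroidetes still
    # expanding; remaining starts solved (noiseless flow) so the
    # week-11..15 window mean of every taxon matches its equilibrium
    y0 <- c(Actinobacteria = 0.0702, Bacteroidetes = 0.16,
            Cyanobacteria = 0.03, Firmicutes = 0.2553,
            Proteobacteria = 0.21, Tenericutes = 0.05,
            Verrucomicrobia = 0.2244)
    group <- "control"
  } else if (name == "vancomycin") {
    taxa <- phyla7
    # treated community: the Proteobacteria hub edges are gone; a
    # Firmicutes -> Verrucomicrobia facilitation appears
    A <- edge_list_to_matrix(
      taxa,
      diagonal = c(-1.5, -1.5, -1.2, -0.6, -1.5, -1.3, -1.4),
      edges = list(
        list("Bacteroidetes", "Verrucomicrobia", 0.6),  # shared edge
        list("Firmicutes", "Bacteroidetes", -0.5),      # shared edge
        list("Firmicutes", "Verrucomicrobia", 0.6)      # treated only
      ))
    y_bar <- c(Actinobacteria = 0.06, Bacteroidetes = 0.10,
               Cyanobacteria = 0.03, Firmicutes = 0.20,
               Proteobacteria = 0.25, Tenericutes = 0.11,
               Verrucomicrobia = 0.25)
    # post-treatment state: Firmicutes suppressed, Proteobacteria and
    # Verrucomicrobia expanded; starts solved as in the control preset
    y0 <- c(Actinobacteria = 0.0516, Bacteroidetes = 0.0523,
            Cyanobacteria = 0.03, Firmicutes = 0.13,
            Proteobacteria = 0.1038, Tenericutes = 0.11,
            Verrucomicrobia = 0.5223)
    group <- "vancomycin"
  } else {
    stop(sprintf("unknown scenario '%s'", name))
  }
  list(name = name, group = group, taxa = taxa, A_true = A,
       y_bar_true = y_bar, y0 = y0,
       weeks = 3:15, n_subjects = 12, depth = 10000,
       process_noise = 0.1, start_noise = 0.5, seed = 20260101L)
}

#' Build a ground-truth scenario for synthetic data generation
#'
#' A scenario fixes everything the forward model needs: the taxon set, a
#' ground-truth interaction matrix `A_true` (stability-verified together
#' with the target composition `y_bar_true`), implied growth rates
#' `r_true = -A_true y_bar_true`, an immature starting composition, the
#' weekly sampling grid, cohort size, sequencing depth, and noise levels.
#' Presets:
#' \describe{
#'   \item{`control`}{7-phylum untreated community. Proteobacteria form an
#'     interaction hub with Actinobacteria, Bacteroidetes and
#'     Verrucomicrobia; Bacteroidetes positively influence
#'     Verrucomicrobia.}
#'   \item{`vancomycin`}{same 7 phyla, treated community: the shared edges
#'     remain, every Proteobacteria hub edge is removed, and a positive
#'     Firmicutes -> Verrucomicrobia influence appears.}
#'   \item{`three_taxon`}{small 3-taxon community for quick demonstrations
#'     and recovery checks.}
#'   \item{`custom`}{all fields from `overrides`.}
#' }
#'
#' @param name Preset name.
#' @param overrides Named list of fields replacing preset values (e.g.
#'   `list(depth = 1e5, n_subjects = 4)`).
#' @return A `glv_scenario` list; construction fails (naming the spectral
#'   abscissa) if `(A_true, y_bar_true)` is not asymptotically stable.
#' @export
make_scenario <- function(name = c("control", "vancomycin", "three_taxon",
                                   "custom"),
                          overrides = list()) {
  name <- match.arg(name)
  spec <- if (name == "custom") {
    need <- c("taxa", "A_true", "y_bar_true", "y0")
    if (!all(need %in% names(overrides))) {
      stop("custom scenario needs overrides: ",
           paste(setdiff(need, names(overrides)), collapse = ", "))
    }
    utils::modifyList(
      list(name = "custom", group = "custom", weeks = 3:15, n_subjects = 12,
           depth = 10000, process_noise = 0.1, start_noise = 0.5,
           seed = 20260101L),
      overrides)
  } else {
    utils::modifyList(scenario_defaults(name), overrides)
  }
  n <- length(spec$taxa)
  spec$A_true <- as.matrix(spec$A_true)
  stopifnot(all(dim(spec$A_true) == n), length(spec$y_bar_true) == n,
            length(spec$y0) == n, spec$depth >= 1, spec$n_subjects >= 1)
  if (any(spec$y_bar_true <= 0)) stop("y_bar_true must be interior (> 0)")
  spec$r_true <- growth_rates_for_equilibrium(spec$A_true, spec$y_bar_true)
  model <- community_model(spec$taxa, spec$r_true, spec$A_true)
  rep <- assess_stability(model, spec$y_bar_true, margin = 1e-6)
  if (!rep$stable) {
    stop(sprintf(
      "scenario '%s' is not asymptotically stable: spectral abscissa %g",
      spec$name, rep$spectral_abscissa))
  }
  structure(spec, class = "glv_scenario")
}

#' @export
print.glv_scenario <- function(x, ...) {
  cat(sprintf(
    "gLV scenario '%s': %d taxa, weeks %g-%g, %d subjects, depth %g\n",
    x$name, length(x$taxa), min(x$weeks), max(x$weeks), x$n_subjects,
    x$depth))
  invisible(x)
}

#' The ground-truth community model of a scenario
#' @param spec A `glv_scenario`.
#' @return A [community_model()] with `A_true` and `r_true`.
#' @export
scenario_model <- function(spec) {
  community_model(spec$taxa, spec$r_true, spec$A_true)
}

#' Ground-truth signed network of a scenario
#'
#' Off-diagonal nonzero entries of `A_true` as a `signed_network`, for
#' comparing inferred consensus networks against the truth.
#'
#' @param spec A `glv_scenario`.
#' @return A `signed_network` with support 1 on every true edge.
#' @export
true_network <- function(spec) {
  A <- spec$A_true
  idx <- which(A != 0 & row(A) != col(A), arr.ind = TRUE)
  edges <- data.frame(
    source = spec$taxa[idx[, "col"]],
    target = spec$taxa[idx[, "row"]],
    sign = ifelse(A[idx] > 0, 1, -1),
    weight = abs(A[idx]),
    support = 1,
    stringsAsFactors = FALSE)
  edges <- edges[order(edges$source, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  signed_network(spec$taxa, edges)
}

#' Generate a synthetic longitudinal sequencing dataset
#'
#' Forward model per subject: the starting composition is perturbed by
#' subject-level lognormal noise (`start_noise`) and renormalized, the gLV
#' dynamics are integrated over the weekly grid, each weekly composition is
#' perturbed by per-taxon lognormal process noise (`process_noise`) and
#' renormalized, phylum proportions are split across representative
#' order-level lineages, and read counts are drawn once per sample from a
#' multinomial at the configured depth. Sample columns therefore sum
#' exactly to `depth`, and the whole dataset is deterministic given
#' `spec$seed`.
#'
#' @param spec A `glv_scenario` from [make_scenario()].
#' @return List with `table` (an order-level counts `abundance_table`) and
#'   `meta` (the matching `sample_metadata`).
#' @export
generate_dataset <- function(spec) {
  model <- scenario_model(spec)
  n <- length(spec$taxa)
  splits <- lapply(spec$taxa, function(ph) {
    s <- order_splits[[ph]]
    if (is.null(s)) s <- stats::setNames(1, "o__")
    s
  })
  lineages <- unlist(lapply(seq_len(n), function(i) {
    sprintf("k__Bacteria;p__%s;c__;%s", spec$taxa[i], names(splits[[i]]))
  }))
  with_preserved_rng(spec$seed, {
    cols <- list(); meta_rows <- list()
    for (s in seq_len(spec$n_subjects)) {
      # mean-one lognormal multipliers, so noise does not shift means
      y0 <- spec$y0 *
        exp(stats::rnorm(n, 0, spec$start_noise) - spec$start_noise^2 / 2)
      y0 <- y0 / sum(y0)
      traj <- simulate_glv(model, y0, spec$weeks)
      for (w in seq_along(spec$weeks)) {
        p <- traj$states[w, ]
        if (spec$process_noise > 0) {
          p <- p * exp(stats::rnorm(n, 0, spec$process_noise) -
                         spec$process_noise^2 / 2)
        }
        p <- pmax(p, 0)
        p <- p / sum(p)
        # expand phylum proportions to order-level lineages
        p_lineage <- unlist(lapply(seq_len(n), function(i) {
          p[i] * unname(splits[[i]])
        }))
        counts <- as.numeric(stats::rmultinom(1, spec$depth, p_lineage))
        id <- sprintf("%s_m%02d_w%02d", spec$group, s, spec$weeks[w])
        cols[[id]] <- counts
        meta_rows[[id]] <- data.frame(
          sample = id, subject = sprintf("%s_m%02d", spec$group, s),
          week = spec$weeks[w], group = spec$group,
          stringsAsFactors = FALSE)
      }
    }
    values <- do.call(cbind, cols)
    meta <- do.call(rbind, meta_rows)
    list(table = abundance_table(values, lineages, names(cols)),
         meta = sample_metadata(meta$sample, meta$subject, meta$week,
                                meta$group))
  })
}

#' Per-subject observed trajectories from an abundance table
#'
#' Extracts, for each subject of a group, the weekly relative-abundance
#' path as a trajectory usable by the inference objective's misfit term.
#' The table should already be aggregated to the modeling rank and
#' relative. Each trajectory carries inverse-variance weights for the
#' log-scale residuals, `1 / (noise_cv^2 + 1 / (read_depth * p))`,
#' evaluated at the per-week group mean composition — an exogenous
#' variance estimate, so that weighting is not correlated with the
#' individual measurement errors it standardizes.
#'
#' @param table A relative `abundance_table`.
#' @param meta Matching `sample_metadata`.
#' @param group Group label to select.
#' @param noise_cv Assumed coefficient of variation of multiplicative
#'   abundance noise (for the weights).
#' @param read_depth Assumed reads per sample (for the counting-noise part
#'   of the weights).
#' @return Named list (one per subject) of `list(times, states, weights)`.
#' @export
subject_trajectories <- function(table, meta, group, noise_cv = 0.1,
                                 read_depth = 1e4) {
  if (!table$is_relative) stop("table must be relative")
  m <- meta[match(table$samples, meta$sample), ]
  keep <- which(m$group == group)
  if (length(keep) == 0) stop(sprintf("no samples in group '%s'", group))
  weeks <- sort(unique(m$week[keep]))
  group_mean <- vapply(weeks, function(w) {
    rowMeans(table$values[, keep[m$week[keep] == w], drop = FALSE])
  }, numeric(length(table$taxa)))
  wmat <- t(1 / (noise_cv^2 + 1 / (read_depth * group_mean) + 1e-10))
  out <- list()
  for (subj in unique(m$subject[keep])) {
    idx <- keep[m$subject[keep] == subj]
    idx <- idx[order(m$week[idx])]
    out[[subj]] <- list(times = m$week[idx],
                        states = t(table$values[, idx, drop = FALSE]),
                        weights = wmat[match(m$week[idx], weeks), ,
                                       drop = FALSE])
  }
  out
}
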