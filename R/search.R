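#' Configuration for the repeated Monte-Carlo direct search
#'
#' Bundles every tunable of the inverse problem: how many random restarts to
#' run, how initial interaction matrices are sampled, the compass-search
#' step-size schedule, the stability margin, the penalty weights of the
#' scalar objective, and the RNG seed.
#'
#' @param n_restarts Number of Monte Carlo starting points (>= 1).
#' @param init_scale Half-width of the uniform distribution used to sample
#'   entries of the initial interaction matrix.
#' @param step_init Initial compass-search step size.
#' @param step_contract Step contraction factor in (0, 1) applied when no
#'   poll improves.
#' @param step_tol Terminal step size; the search stops once the step falls
#'   below it.
#' @param max_iters Cap on accepted moves plus contractions per restart.
#' @param stability_margin Required margin on the spectral abscissa; a
#'   solution is admissible only when `max Re(lambda) < -stability_margin`.
#' @param sparsity_weight L1 penalty coefficient on off-diagonal entries
#'   of `A` (>= 0).
#' @param fit_weight Weight of the trajectory-misfit term (per-observation
#'   mean squared error) when observed trajectories are supplied.
#' @param diag_constraint If `TRUE`, diagonal entries `a_ii` are constrained
#'   to be <= 0 (self-limitation) during the search.
#' @param accept_tol Maximum admissible objective value for a solution to be
#'   accepted into the consensus set. The default `NULL` uses a relative
#'   rule: 1.25 times the best objective found among stable solutions. Set
#'   to `Inf` to accept every stable solution.
#' @param subsample_fraction Fraction of observed trajectories (subjects)
#'   used by each restart's fit. With values below 1 the Monte Carlo
#'   restarts double as a stability-selection loop: each restart sees a
#'   different random subset of subjects, so interactions driven by the
#'   noise of particular samples lose sign agreement across the ensemble
#'   while real interactions keep it. Set to 1 to fit every restart on the
#'   full data.
#' @param noise_cv Assumed per-taxon coefficient of variation of the
#'   multiplicative (biological/technical) abundance noise; together with
#'   `read_depth` it sets the variance model
#'   `Var(p) = p^2 noise_cv^2 + p / read_depth` used to weight trajectory
#'   residuals.
#' @param read_depth Assumed sequencing reads per sample for the
#'   counting-noise part of the variance model.
#' @param seed Integer RNG seed controlling the restart sampling.
#' @return A `glv_search_config` list.
#' @export
search_config <- function(n_restarts = 50, init_scale = 1,
                          step_init = 0.2, step_contract = 0.5,
                          step_tol = 1e-3, max_iters = 2000,
                          stability_margin = 1e-6, sparsity_weight = 0.005,
                          fit_weight = 1, diag_constraint = TRUE,
                          accept_tol = NULL, subsample_fraction = 0.8,
                          noise_cv = 0.1, read_depth = 1e4, seed = 1L) {
  stopifnot(n_restarts >= 1, step_contract > 0, step_contract < 1,
            step_tol > 0, step_tol < step_init, sparsity_weight >= 0,
            fit_weight >= 0, stability_margin >= 0, init_scale > 0,
            max_iters >= 1, noise_cv >= 0, read_depth > 0,
            subsample_fraction > 0, subsample_fraction <= 1)
  structure(list(n_restarts = as.integer(n_restarts),
                 init_scale = init_scale, step_init = step_init,
                 step_contract = step_contract, step_tol = step_tol,
                 max_iters = as.integer(max_iters),
                 stability_margin = stability_margin,
                 sparsity_weight = sparsity_weight,
                 fit_weight = fit_weight,
                 diag_constraint = isTRUE(diag_constraint),
                 accept_tol = if (is.null(accept_tol)) NA_real_ else accept_tol,
                 subsample_fraction = subsample_fraction,
                 noise_cv = noise_cv, read_depth = read_depth,
                 seed = as.integer(seed)),
            class = "glv_search_config")
}

#' Sample a random initial interaction matrix
#'
#' Off-diagonal entries are i.i.d. uniform on `[-init_scale, +init_scale]`;
#' diagonal entries are uniform on `[-init_scale, 0]`. The nonpositive
#' diagonal biases starts toward self-limiting communities — without it,
#' randomly sampled matrices are almost never Hurwitz-stable as `n` grows.
#' Draws come from R's current RNG stream; seed it (or use
#' [infer_ensemble()], which seeds it from the config) for reproducibility.
#'
#' @param n Community size.
#' @param init_scale Sampling half-width.
#' @return An `n x n` numeric matrix.
#' @export
sample_initial_matrix <- function(n, init_scale = 1) {
  stopifnot(n >= 1)
  A <- matrix(stats::runif(n * n, -init_scale, init_scale), n, n)
  diag(A) <- stats::runif(n, -init_scale, 0)
  A
}

normalize_observations <- function(observations, n, noise_cv = 0.1,
                                   read_depth = 1e4) {
  if (is.null(observations)) return(NULL)
  if (inherits(observations, "glv_trajectory")) {
    observations <- list(observations)
  }
  if (!is.list(observations)) stop("observations must be trajectories")
  lapply(observations, function(ob) {
    times <- as.numeric(ob$times)
    states <- as.matrix(ob$states)
    if (ncol(states) != n) {
      stop(sprintf("observed trajectory has %d taxa, expected %d",
                   ncol(states), n))
    }
    if (length(times) != nrow(states) || any(diff(times) <= 0)) {
      stop("observed trajectory needs strictly increasing times matching rows")
    }
    states <- unname(states)
    if (any(states <= 0)) {
      stop("observed compositions must be strictly positive ",
           "(apply a detection floor first)")
    }
    weights <- if (is.null(ob$weights)) {
      # inverse-variance weights on the log scale: multiplicative noise
      # (common cv) plus counting noise (relative sd 1/sqrt(depth * p))
      1 / (noise_cv^2 + 1 / (read_depth * states) + 1e-10)
    } else {
      unname(as.matrix(ob$weights))
    }
    lst <- log(states)
    list(times = times, states = states,
         clr = lst - rowMeans(lst), weights = weights)
  })
}

# Fixed-step RK4 used inside the objective: deterministic, cheap, and
# identical (up to rounding) to the compiled hot path. Each trajectory is
# forecast from its first observed state through its full horizon (callers
# control disturbance accumulation by segmenting long series). Predictions
# are compared in centered-log-ratio (clr) space: sequencing observations
# are compositional with multiplicative noise, and clr residuals both
# respect that noise model and cancel the common-mode error that
# per-sample renormalization spreads across taxa. Returns NULL on
# divergence so the caller can reject the poll.
rk4_fit_sse <- function(A, r, ob, dt = 0.5, overflow = 1e6, y0 = NULL) {
  y <- if (is.null(y0)) ob$states[1, ] else y0
  sse <- 0
  rhs <- function(y) y * (r + A %*% y)
  for (k in 2:length(ob$times)) {
    t0 <- ob$times[k - 1]; t1 <- ob$times[k]
    nstep <- max(1L, ceiling((t1 - t0) / dt))
    h <- (t1 - t0) / nstep
    for (s in seq_len(nstep)) {
      k1 <- rhs(y)
      k2 <- rhs(y + h / 2 * k1)
      k3 <- rhs(y + h / 2 * k2)
      k4 <- rhs(y + h * k3)
      y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      if (!all(is.finite(y)) || max(abs(y)) > overflow) return(NULL)
    }
    if (any(y <= 1e-12)) return(NULL)
    ly <- log(y)
    d <- (ly - mean(ly)) - ob$clr[k, ]
    sse <- sse + sum(ob$weights[k, ] * d * d)
  }
  sse
}

#' Scalar objective of the inverse problem (reference implementation)
#'
#' The growth rates are eliminated analytically as `r = -A y_bar`, so the
#' equilibrium residual is identically zero and the merit function reduces
#' to a squared hinge on the spectral abscissa of the stability matrix, an
#' optional L1 sparsity penalty on off-diagonal interactions, and — when
#' observed trajectories are supplied — the inverse-variance-weighted mean
#' squared misfit between the compositions predicted by gLV forward
#' simulation and the observed ones:
#' \deqn{f(A) = w_{fit}\,\mathrm{WMSE}(A) +
#'   \max(0, \alpha(J) + m)^2 + w_{sp} \sum_{i \ne j} |a_{ij}|}
#' where `alpha(J)` is the spectral abscissa of
#' `diag(r + A y_bar) + diag(y_bar) A` and `m` the stability margin.
#' Without observations the objective depends on the data only through
#' `y_bar` (the stability-constrained feasibility problem); with them it
#' additionally selects matrices whose transient dynamics reproduce the
#' measured time series. This R implementation is the readable reference;
#' [infer_ensemble()] uses a compiled implementation of the same function.
#'
#' @param A Candidate interaction matrix.
#' @param y_bar Strictly positive equilibrium composition.
#' @param config A [search_config()].
#' @param observations Optional trajectory or list of trajectories (each
#'   with `times` and a `times x n` `states` matrix) to fit.
#' @return Scalar objective value (`Inf` if the forward simulation
#'   diverges).
#' @export
glv_objective <- function(A, y_bar, config = search_config(),
                          observations = NULL, y_bar_se_rel = NULL) {
  A <- as.matrix(A)
  y_bar <- as.numeric(y_bar)
  n <- length(y_bar)
  if (any(y_bar <= 0)) stop("y_bar must be strictly positive")
  obs <- normalize_observations(observations, n, config$noise_cv,
                                config$read_depth)
  S <- if (is.null(obs)) 0L else length(obs)
  if (ncol(A) != n || !nrow(A) %in% c(n, n + 1L, n + 1L + S)) {
    stop(sprintf("A must have %d columns and %d, %d or %d rows",
                 n, n, n + 1L, n + 1L + S))
  }
  eq_pen <- 0
  refine <- nrow(A) > n
  latent_starts <- nrow(A) == n + 1L + S && S > 0
  v <- NULL
  if (refine) {
    # row n+1: log-scale refinement of the equilibrium within its
    # sampling uncertainty; rows n+2..n+1+S: per-trajectory log-scale
    # deviations of the latent initial state from its noisy observation —
    # all penalized by their squared standardized deviations
    u <- A[n + 1L, ]
    se <- if (is.null(y_bar_se_rel)) rep(0.05, n) else y_bar_se_rel
    if (latent_starts) v <- A[(n + 2L):(n + 1L + S), , drop = FALSE]
    y_bar <- y_bar * exp(u)
    eq_pen <- sum((u / se)^2)
    A <- A[seq_len(n), , drop = FALSE]
  }
  r <- as.numeric(-A %*% y_bar)
  J <- diag(as.numeric(r + A %*% y_bar), nrow = n) + y_bar * A
  sa <- max(Re(eigen(J, only.values = TRUE)$values))
  hinge <- max(0, sa + config$stability_margin)
  off <- A[row(A) != col(A)]
  obj <- hinge^2 + config$sparsity_weight * sum(abs(off))
  if (!is.null(obs) && config$fit_weight > 0) {
    sse <- eq_pen
    nobs <- if (refine) n else 0
    for (s_idx in seq_len(S)) {
      ob <- obs[[s_idx]]
      y0 <- NULL
      if (latent_starts) {
        vs <- v[s_idx, ]
        y0 <- ob$states[1, ] * exp(vs)
        # start measurement variance on the log scale is the inverse of
        # the (log-scale) observation weight at the first time point
        sse <- sse + sum(vs^2 * ob$weights[1, ])
        nobs <- nobs + n
      }
      s <- rk4_fit_sse(A, r, ob, y0 = y0)
      if (is.null(s)) return(Inf)
      sse <- sse + s
      nobs <- nobs + (length(ob$times) - 1) * n
    }
    obj <- obj + config$fit_weight * sse / nobs
  }
  obj
}

#' Compass (coordinate pattern) direct search over matrix entries
#'
#' Derivative-free minimization of a scalar function of an `n x n` matrix.
#' Entries are polled cyclically in row-major order, `+step` before
#' `-step`; the first improving poll is accepted, and polling continues
#' with the next coordinate. When a full cycle over all coordinates yields
#' no improvement the step contracts by `step_contract`. The search stops
#' when the step falls below `step_tol` or after `max_iters` accepted
#' moves plus contractions. Non-finite objective values reject the poll
#' and the search continues.
#'
#' @param f Scalar objective taking a matrix.
#' @param A0 Starting matrix; `f(A0)` must be finite.
#' @param config A [search_config()] (only the step schedule,
#'   `max_iters` and `diag_constraint` fields are used).
#' @return List with the minimizer `A`, its `value`, the iteration count
#'   `iters`, and `trace` — the objective after every iteration
#'   (monotonically nonincreasing).
#' @export
direct_search <- function(f, A0, config = search_config()) {
  A <- as.matrix(A0)
  n1 <- nrow(A); n2 <- ncol(A)
  fx <- f(A)
  if (!is.finite(fx)) stop("objective must be finite at the starting point")
  step <- config$step_init
  iters <- 0L
  trace <- numeric(0)
  coords <- cbind(rep(seq_len(n1), each = n2), rep(seq_len(n2), n1))
  ncoord <- nrow(coords)
  cidx <- 1L
  since_improve <- 0L
  while (step >= config$step_tol && iters < config$max_iters) {
    i <- coords[cidx, 1]; j <- coords[cidx, 2]
    moved <- FALSE
    for (delta in c(step, -step)) {
      cand_val <- A[i, j] + delta
      if (config$diag_constraint && i == j && cand_val > 0) next
      Ac <- A
      Ac[i, j] <- cand_val
      fc <- f(Ac)
      if (is.finite(fc) && fc < fx) {
        A <- Ac
        fx <- fc
        moved <- TRUE
        break
      }
    }
    cidx <- if (cidx == ncoord) 1L else cidx + 1L
    if (moved) {
      since_improve <- 0L
      iters <- iters + 1L
      trace <- c(trace, fx)
    } else {
      since_improve <- since_improve + 1L
      if (since_improve == ncoord) {
        step <- step * config$step_contract
        since_improve <- 0L
        iters <- iters + 1L
        trace <- c(trace, fx)
      }
    }
  }
  list(A = A, value = fx, iters = iters, trace = trace)
}

# Shrink off-diagonal entries until the objective is finite (the forward
# simulation of a wildly unstable start can blow up; weak interactions
# cannot).
dampen_start <- function(A0, fobj, max_halvings = 60L) {
  f0 <- fobj(A0)
  k <- 0L
  while (!is.finite(f0) && k < max_halvings) {
    off <- row(A0) != col(A0)
    A0[off] <- A0[off] * 0.5
    f0 <- fobj(A0)
    k <- k + 1L
  }
  if (!is.finite(f0)) stop("could not find a finite starting objective")
  A0
}

#' L1-minimizing compositional gauge of an interaction matrix
#'
#' Compositional (relative-abundance) trajectories determine the
#' interaction matrix only up to adding a constant to each column: shifting
#' column `j` by `c_j` (together with the implied growth rates) changes
#' every taxon's per-capita growth by the same amount and so leaves every
#' predicted composition unchanged. This function maps a matrix to the
#' representative of its gauge class whose off-diagonal columns have
#' minimal L1 norm — the sparsest interpretation of the same compositional
#' dynamics — by subtracting each column's off-diagonal median.
#'
#' @param A Interaction matrix.
#' @return The gauge-normalized matrix.
#' @export
l1_gauge <- function(A) {
  A <- as.matrix(A)
  for (j in seq_len(ncol(A))) {
    A[, j] <- A[, j] - stats::median(A[-j, j])
  }
  A
}

with_preserved_rng <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Infer an ensemble of admissible interaction matrices
#'
#' Solves the stability-constrained inverse problem by repeated
#' Monte-Carlo-sampled direct search: for each restart an initial
#' interaction matrix is drawn with [sample_initial_matrix()], the penalized
#' objective ([glv_objective()]) is minimized by compass search, growth
#' rates are recovered as `r = -A y_bar`, and the solution is marked
#' accepted when (i) its stability penalty is exactly zero, i.e. the
#' spectral abscissa lies below `-stability_margin`, (ii) its equilibrium
#' residual max-norm is below `1e-8`, and (iii) its objective does not
#' exceed `accept_tol`. The problem is nonconvex and deliberately
#' multi-solution: the ensemble, not any single matrix, is the inferential
#' object, and is distilled by [consensus_network()].
#'
#' @param y_bar Strictly positive equilibrium composition (may be an
#'   `equilibrium_state` from [estimate_equilibrium()]).
#' @param config A [search_config()].
#' @param observations Optional trajectory or list of trajectories fitted by
#'   the objective's misfit term (e.g. per-subject weekly abundance paths).
#'   When present, the equilibrium is refined jointly with `A` within the
#'   sampling uncertainty of its estimate (the refined value is recorded
#'   per solution); without observations `y_bar` is held fixed.
#' @param taxa Optional taxon labels (taken from `y_bar` if named).
#' @param y_bar_se_rel Relative standard errors of the equilibrium
#'   estimate (taken from an `equilibrium_state`, default 0.05), which set
#'   the scale of the joint refinement penalty.
#' @param engine `"cpp"` (default, compiled) or `"r"` (pure-R reference;
#'   identical algorithm, useful for cross-checking).
#' @return A `glv_ensemble`: list of per-restart solutions (each with `A`,
#'   `r`, `objective`, `spectral_abscissa`, `residual_max`, `accepted`,
#'   `restart`), plus `y_bar`, `taxa` and `config`.
#' @export
infer_ensemble <- function(y_bar, config = search_config(),
                           observations = NULL, taxa = NULL,
                           y_bar_se_rel = NULL,
                           engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  if (inherits(y_bar, "equilibrium_state")) {
    if (is.null(taxa)) taxa <- y_bar$taxa
    if (is.null(y_bar_se_rel)) y_bar_se_rel <- y_bar$y_bar_se_rel
    y_bar <- y_bar$y_bar
  }
  if (is.null(taxa)) {
    taxa <- if (!is.null(names(y_bar))) names(y_bar)
            else paste0("taxon", seq_along(y_bar))
  }
  y_bar <- as.numeric(y_bar)
  n <- length(y_bar)
  if (any(y_bar <= 0)) stop("y_bar must be strictly positive")
  obs <- normalize_observations(observations, n, config$noise_cv,
                                config$read_depth)
  # with observations the equilibrium is refined jointly with A, within
  # the sampling uncertainty of its estimate (search over an extra row of
  # log-scale deviations); without observations ybar is fixed
  refine <- !is.null(obs)
  se <- if (is.null(y_bar_se_rel)) rep(0.05, n)
        else pmax(as.numeric(y_bar_se_rel), 1e-3)
  fobj <- function(A) glv_objective(A, y_bar, config, obs, se)

  nsub <- if (is.null(obs)) 0L else length(obs)
  use_subsample <- nsub >= 3 && config$subsample_fraction < 1
  keep_n <- if (use_subsample) {
    max(2L, as.integer(round(config$subsample_fraction * nsub)))
  } else nsub

  solutions <- with_preserved_rng(config$seed, {
    lapply(seq_len(config$n_restarts), function(k) {
      A0 <- sample_initial_matrix(n, config$init_scale)
      if (config$diag_constraint) diag(A0) <- pmin(diag(A0), 0)
      # each restart fits a random subset of subjects (stability
      # selection); acceptance and reported objectives use the full data
      obs_k <- if (use_subsample) obs[sort(sample.int(nsub, keep_n))]
               else obs
      # search space: A, plus (with data) the equilibrium refinement row
      # and one latent-initial-state row per fitted trajectory
      if (refine) {
        A0 <- rbind(A0, matrix(0, 1L + length(obs_k), n))
      }
      fobj_k <- function(A) glv_objective(A, y_bar, config, obs_k, se)
      A0 <- dampen_start(A0, if (is.null(obs)) fobj else fobj_k)
      res <- if (engine == "cpp") {
        compass_search_glv(A0, y_bar, se,
                           if (is.null(obs)) list() else obs_k,
                           config$fit_weight, config$stability_margin,
                           config$sparsity_weight, config$diag_constraint,
                           config$step_init, config$step_contract,
                           config$step_tol, config$max_iters)
      } else {
        direct_search(if (is.null(obs)) fobj else fobj_k, A0, config)
      }
      Aext <- res$A
      u <- if (refine) Aext[n + 1L, ] else rep(0, n)
      A <- Aext[seq_len(n), , drop = FALSE]
      y_bar_k <- y_bar * exp(u)
      objective <- if (is.null(obs) || !use_subsample) res$value
                   else fobj(rbind(A, u))
      if (!is.null(obs)) {
        # report each solution in its sparse compositional gauge (the fit
        # cannot distinguish gauge-equivalent matrices); keep the search
        # result unchanged if the gauge representative loses stability
        Ag <- l1_gauge(A)
        fg <- fobj(if (refine) rbind(Ag, u) else Ag)
        sag <- spectral_abscissa(y_bar_k * Ag)
        if (is.finite(fg) && sag < -config$stability_margin) {
          A <- Ag
          objective <- fg
        }
      }
      dimnames(A) <- list(taxa, taxa)
      r <- growth_rates_for_equilibrium(A, y_bar_k)
      model <- community_model(taxa, r, A)
      rep <- assess_stability(model, y_bar_k, config$stability_margin)
      resid <- max(abs(equilibrium_residual(model, y_bar_k)))
      list(A = A, r = r, y_bar = stats::setNames(y_bar_k, taxa),
           objective = objective,
           spectral_abscissa = rep$spectral_abscissa,
           residual_max = resid,
           accepted = rep$stable && resid < 1e-8,
           restart = k)
    })
  })

  # acceptance on objective value: absolute cap, or (default) within 25% of
  # the best stable solution found — keeps consensus on the global basin
  stable_obj <- vapply(solutions,
                       function(s) if (s$accepted) s$objective else Inf,
                       numeric(1))
  tol <- config$accept_tol
  if (is.na(tol)) {
    # without data the problem is pure feasibility: every stable solution
    # is admissible; with data, keep solutions near the best fit
    tol <- if (is.null(obs) || all(is.infinite(stable_obj))) Inf
           else 1.25 * min(stable_obj) + 1e-12
  }
  solutions <- lapply(solutions, function(s) {
    s$accepted <- s$accepted && s$objective <= tol
    s
  })

  if (!any(vapply(solutions, `[[`, logical(1), "accepted"))) {
    best <- min(vapply(solutions, `[[`, numeric(1), "objective"))
    stop(sprintf("no admissible network found (best objective %g)", best))
  }
  structure(list(solutions = solutions, y_bar = stats::setNames(y_bar, taxa),
                 taxa = taxa, config = config, accept_tol_used = tol),
            class = "glv_ensemble")
}

#' @export
print.glv_ensemble <- function(x, ...) {
  acc <- sum(vapply(x$solutions, `[[`, logical(1), "accepted"))
  cat(sprintf("gLV solution ensemble: %d restarts, %d accepted (%d taxa)\n",
              length(x$solutions), acc, length(x$taxa)))
  invisible(x)
}

#' Read a solution ensemble written by [write_ensemble_json()]
#' @param path JSON file path.
#' @return A `glv_ensemble`.
#' @export
read_ensemble_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  taxa <- unlist(doc$taxa)
  solutions <- lapply(doc$solutions, function(s) {
    A <- do.call(rbind, lapply(s$A, unlist))
    dimnames(A) <- list(taxa, taxa)
    list(A = A, r = stats::setNames(unlist(s$r), taxa),
         y_bar = stats::setNames(unlist(s$y_bar), taxa),
         objective = s$objective,
         spectral_abscissa = s$spectral_abscissa,
         residual_max = s$residual_max, accepted = s$accepted,
         restart = s$restart)
  })
  cfg <- doc$config
  cfg$accept_tol <- if (is.null(cfg$accept_tol) ||
                          is.na(cfg$accept_tol)) NULL else cfg$accept_tol
  config <- do.call(search_config, cfg[intersect(names(cfg),
    names(formals(search_config)))])
  structure(list(solutions = solutions,
                 y_bar = stats::setNames(unlist(doc$y_bar), taxa),
                 taxa = taxa, config = config,
                 accept_tol_used = doc$accept_tol_used),
            class = "glv_ensemble")
}

#' Accepted solutions of an ensemble
#' @param ensemble A `glv_ensemble`.
#' @return List of accepted solution records.
#' @export
accepted_solutions <- function(ensemble) {
  Filter(function(s) isTRUE(s$accepted), ensemble$solutions)
}

#' Serialize a solution ensemble to JSON
#' @param ensemble A `glv_ensemble`.
#' @param path Output file path.
#' @export
write_ensemble_json <- function(ensemble, path) {
  doc <- list(
    taxa = ensemble$taxa,
    y_bar = unname(ensemble$y_bar),
    config = unclass(ensemble$config),
    accept_tol_used = ensemble$accept_tol_used,
    solutions = lapply(ensemble$solutions, function(s) {
      list(A = unname(s$A), r = unname(s$r), y_bar = unname(s$y_bar),
           objective = s$objective,
           spectral_abscissa = s$spectral_abscissa,
           residual_max = s$residual_max, accepted = s$accepted,
           restart = s$restart)
    })
  )
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
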