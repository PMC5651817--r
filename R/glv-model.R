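#' Construct a generalized Lotka-Volterra community model
#'
#' A community model couples a vector of intrinsic growth rates `r` with an
#' interaction matrix `A` under the generalized Lotka-Volterra (gLV) dynamics
#' \deqn{y'(t) = \mathrm{diag}(y(t)) (r + A y(t)).}
#' Entry `A[i, j]` is the per-capita influence of taxon `j` on the growth of
#' taxon `i`: positive values are facilitation, negative values inhibition,
#' and the diagonal encodes self-limitation.
#'
#' @param taxa Character vector of unique taxon labels.
#' @param r Numeric vector of intrinsic growth rates, one per taxon
#'   (units 1/time).
#' @param A Numeric interaction matrix, `n x n` with `n = length(taxa)`
#'   (units 1/(abundance * time)).
#' @return An object of class `glv_model` with elements `taxa`, `r`, `A`.
#' @examples
#' m <- community_model(c("x", "y"), r = c(1, -1),
#'                      A = matrix(c(-1, 0.5, 0, -0.5), 2))
#' glv_rhs(c(1, 2), m)
#' @export
community_model <- function(taxa, r, A) {
  taxa <- as.character(taxa)
  n <- length(taxa)
  if (anyDuplicated(taxa)) {
    stop("taxon labels must be unique")
  }
  r <- as.numeric(r)
  A <- as.matrix(A)
  if (length(r) != n) {
    stop(sprintf("length(r) is %d but %d taxa were given", length(r), n))
  }
  if (!all(dim(A) == c(n, n))) {
    stop(sprintf("A must be %d x %d, got %d x %d", n, n, nrow(A), ncol(A)))
  }
  if (!all(is.finite(r)) || !all(is.finite(A))) {
    stop("r and A must be finite")
  }
  dimnames(A) <- list(taxa, taxa)
  names(r) <- taxa
  structure(list(taxa = taxa, r = r, A = A), class = "glv_model")
}

#' @export
print.glv_model <- function(x, ...) {
  cat(sprintf("gLV community model: %d taxa\n", length(x$taxa)))
  cat("  taxa:", paste(x$taxa, collapse = ", "), "\n")
  cat("  growth rates r:", paste(signif(x$r, 3), collapse = ", "), "\n")
  cat(sprintf("  interaction matrix A: %d nonzero off-diagonal entries\n",
              sum(x$A[row(x$A) != col(x$A)] != 0)))
  invisible(x)
}

check_state <- function(y, model, what = "y") {
  n <- length(model$taxa)
  if (length(y) != n) {
    stop(sprintf("%s has length %d but the model expects n = %d",
                 what, length(y), n))
  }
  if (!all(is.finite(y))) stop(sprintf("%s must be finite", what))
  as.numeric(y)
}

#' gLV right-hand side
#'
#' Evaluates the instantaneous growth `diag(y) (r + A y)` of the gLV system.
#' This is exact algebraic evaluation with no clipping; it is the derivative
#' field used by [simulate_glv()] and the equilibrium residual.
#'
#' @param y Numeric abundance vector of length `n`.
#' @param model A [community_model()].
#' @return Numeric derivative vector `y * (r + A %*% y)`.
#' @export
glv_rhs <- function(y, model) {
  y <- check_state(y, model)
  as.numeric(y * (model$r + model$A %*% y))
}

#' Equilibrium residual of the gLV system
#'
#' Returns `diag(y_bar) (r + A y_bar)`; the zero vector exactly when `y_bar`
#' is a fixed point of the dynamics.
#'
#' @param model A [community_model()].
#' @param y_bar Candidate equilibrium abundance vector.
#' @return Numeric residual vector.
#' @export
equilibrium_residual <- function(model, y_bar) {
  glv_rhs(y_bar, model)
}

#' Growth rates making a given composition an interior equilibrium
#'
#' For a strictly positive target composition the equilibrium condition
#' `r + A y_bar = 0` has the unique solution `r = -A y_bar`. This eliminates
#' `r` from the inverse problem: searching over `A` alone, with `r` implied,
#' keeps the equilibrium constraint satisfied exactly.
#'
#' @param A Interaction matrix.
#' @param y_bar Strictly positive abundance vector.
#' @return Growth-rate vector `-A %*% y_bar`.
#' @export
growth_rates_for_equilibrium <- function(A, y_bar) {
  A <- as.matrix(A)
  y_bar <- as.numeric(y_bar)
  if (length(y_bar) != nrow(A) || nrow(A) != ncol(A)) {
    stop(sprintf("A must be square with dimension length(y_bar) = %d",
                 length(y_bar)))
  }
  if (any(y_bar <= 0)) {
    stop("y_bar must be strictly positive (interior equilibrium assumption)")
  }
  r <- as.numeric(-A %*% y_bar)
  names(r) <- rownames(A)
  r
}

#' Serialize a community model to JSON
#'
#' @param model A [community_model()].
#' @param path File path; if `NULL` the JSON string is returned.
#' @return The path (invisibly) or a JSON string.
#' @export
write_model_json <- function(model, path = NULL) {
  doc <- list(taxa = model$taxa, r = unname(model$r),
              A = unname(model$A))
  json <- jsonlite::toJSON(doc, digits = NA, auto_unbox = FALSE)
  if (is.null(path)) return(as.character(json))
  writeLines(as.character(json), path)
  invisible(path)
}

#' Read a community model from JSON
#'
#' @param path File path or a JSON string produced by [write_model_json()].
#' @return A [community_model()].
#' @export
read_model_json <- function(path) {
  doc <- jsonlite::fromJSON(path)
  community_model(doc$taxa, doc$r, doc$A)
}
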