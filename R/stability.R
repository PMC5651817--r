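#' Stability (Jacobian) matrix of the gLV system at a point
#'
#' The Jacobian of `diag(y)(r + Ay)` evaluated at `y_bar` is
#' `J = diag(r + A y_bar) + diag(y_bar) A`. Both terms are kept, so the
#' expression is valid at boundary points (some `y_bar[i] = 0`) as well as
#' interior equilibria, where the first term vanishes.
#'
#' @param model A [community_model()].
#' @param y_bar Evaluation point (abundance vector).
#' @return The `n x n` Jacobian matrix.
#' @export
stability_matrix <- function(model, y_bar) {
  y_bar <- check_state(y_bar, model, "y_bar")
  A <- unname(model$A)
  J <- diag(as.numeric(model$r + A %*% y_bar), nrow = length(y_bar)) +
    y_bar * A
  dimnames(J) <- list(model$taxa, model$taxa)
  J
}

#' Spectral abscissa: maximum real part of the spectrum
#'
#' @param J A square numeric matrix.
#' @return `max(Re(eigenvalues(J)))`.
#' @export
spectral_abscissa <- function(J) {
  J <- as.matrix(J)
  if (nrow(J) != ncol(J)) stop("J must be square")
  if (!all(is.finite(J))) stop("J must be finite")
  max(Re(eigen(J, only.values = TRUE)$values))
}

#' Assess local asymptotic stability of an equilibrium
#'
#' An equilibrium is accepted as asymptotically stable when every eigenvalue
#' of the stability matrix has real part below `-margin` (strict negativity,
#' with a small default margin so that numerically marginal spectra — whose
#' computed real parts are sign-unreliable near zero — are never accepted).
#'
#' @param model A [community_model()].
#' @param y_bar Equilibrium abundance vector.
#' @param margin Nonnegative stability margin (default `1e-6`).
#' @return A `stability_report`: list with `J`, `eigenvalues`,
#'   `spectral_abscissa` and logical `stable`.
#' @export
assess_stability <- function(model, y_bar, margin = 1e-6) {
  if (margin < 0) stop("margin must be nonnegative")
  J <- stability_matrix(model, y_bar)
  ev <- eigen(unname(J), only.values = TRUE)$values
  sa <- max(Re(ev))
  structure(list(J = J, eigenvalues = ev, spectral_abscissa = sa,
                 margin = margin, stable = sa < -margin),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("stability report: spectral abscissa %.6g (margin %g) -> %s\n",
              x$spectral_abscissa, x$margin,
              if (x$stable) "stable" else "NOT stable"))
  invisible(x)
}

#' Serialize a stability report to JSON (eigenvalues as re/im pairs)
#' @param report A `stability_report`.
#' @param path File path; if `NULL` the JSON string is returned.
#' @export
write_stability_json <- function(report, path = NULL) {
  doc <- list(
    J = unname(report$J),
    eigenvalues = lapply(report$eigenvalues,
                         function(z) list(re = Re(z), im = Im(z))),
    spectral_abscissa = report$spectral_abscissa,
    margin = report$margin,
    stable = report$stable
  )
  json <- jsonlite::toJSON(doc, digits = NA, auto_unbox = TRUE)
  if (is.null(path)) return(as.character(json))
  writeLines(as.character(json), path)
  invisible(path)
}
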