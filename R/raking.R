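#' Raking (iterative proportional fitting) weights
#'
#' Computes poststratification weights so that a simulated
#' subgroup-by-age-band count table reproduces target marginal counts.
#' This is how the simulated population is re-weighted each cycle to track
#' compositional change not modelled mechanistically (migration, differential
#' background mortality): the joint structure of the simulation is retained
#' while the margins are matched.
#'
#' Row and column scaling passes alternate until both margins are matched
#' within `tol`. The returned table of weights multiplies `sim_counts`
#' cell-wise; a cell weight is the product of its row and column scale
#' factors.
#'
#' @param sim_counts non-negative numeric matrix of simulated counts.
#' @param row_targets desired row margin (length `nrow(sim_counts)`).
#' @param col_targets desired column margin (length `ncol(sim_counts)`).
#'   The two margin totals must agree within 0.5; the column targets are
#'   rescaled to the row total before fitting.
#' @param tol maximum absolute margin error accepted (default `1e-10`).
#' @param max_iter maximum number of row+column passes.
#' @return Numeric matrix of weights, same dimensions as `sim_counts`.
#' @export
raking_weights <- function(sim_counts, row_targets, col_targets,
                           tol = 1e-10, max_iter = 1000L) {
  m <- as.matrix(sim_counts)
  stopifnot(is.numeric(m), all(is.finite(m)), all(m >= 0))
  row_targets <- as.numeric(row_targets)
  col_targets <- as.numeric(col_targets)
  stopifnot(length(row_targets) == nrow(m), length(col_targets) == ncol(m),
            all(row_targets >= 0), all(col_targets >= 0))
  if (abs(sum(row_targets) - sum(col_targets)) > 0.5) {
    stop("margin totals disagree by more than 0.5", call. = FALSE)
  }
  if (any(row_targets > 0 & rowSums(m) == 0) ||
      any(col_targets > 0 & colSums(m) == 0)) {
    stop("infeasible raking: positive target on an empty margin",
         call. = FALSE)
  }
  if (sum(row_targets) > 0) {
    col_targets <- col_targets * sum(row_targets) / sum(col_targets)
  }
  w <- matrix(1, nrow(m), ncol(m), dimnames = dimnames(m))
  for (it in seq_len(max_iter)) {
    rs <- rowSums(m * w)
    rfac <- ifelse(rs > 0, row_targets / rs, 1)
    w <- w * rfac
    cs <- colSums(m * w)
    cfac <- ifelse(cs > 0, col_targets / cs, 1)
    w <- sweep(w, 2L, cfac, `*`)
    err <- max(abs(rowSums(m * w) - row_targets),
               abs(colSums(m * w) - col_targets))
    if (err <= tol) return(w)
  }
  stop(sprintf("raking did not converge in %d iterations (residual %.3g)",
               max_iter, err), call. = FALSE)
}
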