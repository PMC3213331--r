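# Rigid-body superposition engine: Kabsch least-squares fit, cRMS, and the
# iterative average-model construction used by the heterogeneity score.

coords_of <- function(x) {
  if (inherits(x, "ca_structure")) x$xyz else as.matrix(x)
}

# error unless the point set spans at least a line-with-width (the Kabsch
# rotation is ill-determined for collinear sets)
check_degenerate <- function(xyz, what) {
  ctr <- scale(xyz, scale = FALSE)
  sv <- svd(ctr, nu = 0, nv = 0)$d
  if (sv[2] < 1e-8 * max(sv[1], 1))
    stop(data_error(sprintf("degenerate (collinear) geometry in %s", what)))
}

#' Kabsch least-squares superposition
#'
#' Finds the proper rotation and translation minimising the sum of squared
#' Calpha deviations of `mobile` onto `reference`. Reflections are excluded
#' by the usual determinant sign correction, so the rotation always has
#' determinant +1.
#'
#' @param mobile,reference [ca_structure] objects (or n x 3 coordinate
#'   matrices) with equal residue counts, at least 3 residues, not all
#'   collinear.
#' @return object of class `superposition`: `rotation` (3 x 3, applied as
#'   `xyz %*% rotation`), `translation` (length-3), and `rmsd` (Angstrom,
#'   the minimised root-mean-square deviation).
#' @examples
#' x <- cbind(rnorm(10), rnorm(10), rnorm(10)) * 5
#' sp <- kabsch_superpose(x, x)
#' sp$rmsd  # 0
#' @export
kabsch_superpose <- function(mobile, reference) {
  xm <- coords_of(mobile)
  xr <- coords_of(reference)
  if (nrow(xm) != nrow(xr))
    stop(data_error(sprintf(
      "superposition length mismatch: %d vs %d residues",
      nrow(xm), nrow(xr))))
  if (nrow(xm) < 3L)
    stop(data_error("superposition needs at least 3 residues"))
  check_degenerate(xm, "mobile structure")
  check_degenerate(xr, "reference structure")
  cm <- colMeans(xm)
  cr <- colMeans(xr)
  pm <- sweep(xm, 2, cm)
  pr <- sweep(xr, 2, cr)
  s <- svd(crossprod(pm, pr))          # t(pm) %*% pr
  d <- sign(det(s$u %*% t(s$v)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  fitted <- pm %*% rot
  rmsd <- sqrt(mean(rowSums((fitted - pr)^2)))
  structure(list(rotation = rot,
                 translation = as.numeric(cr - cm %*% rot),
                 rmsd = rmsd),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("Superposition: rmsd = %.4f A, det(R) = %+.0f\n",
              x$rmsd, det(x$rotation)))
  invisible(x)
}

#' Apply a superposition to coordinates
#' @param sp a `superposition` from [kabsch_superpose()].
#' @param x a [ca_structure] or n x 3 matrix.
#' @return object of the same kind with transformed coordinates.
#' @export
apply_superposition <- function(sp, x) {
  if (inherits(x, "ca_structure")) {
    x$xyz <- sweep(x$xyz %*% sp$rotation, 2, sp$translation, `+`)
    x
  } else {
    sweep(coords_of(x) %*% sp$rotation, 2, sp$translation, `+`)
  }
}

#' Coordinate RMS deviation after optimal superposition
#'
#' The cRMS between two equal-length Calpha traces: the RMSD that remains
#' after the optimal rigid-body fit. Symmetric in its arguments. Pairing is
#' positional (residue i to residue i); alignment-mediated pairing for
#' structures of different sequences is provided by [domain_crms()].
#'
#' @param a,b [ca_structure] objects or n x 3 matrices, equal lengths.
#' @return cRMS in Angstrom.
#' @export
crms <- function(a, b) {
  kabsch_superpose(a, b)$rmsd
}

#' Iterative average model of an ensemble
#'
#' Computes the average model MA whose coordinates are the per-residue
#' means of the superposed ensemble: starting from the first model as
#' reference, every model is superposed onto the current mean and the mean
#' is recomputed, until the mean coordinate displacement falls below `tol`
#' or `max_iter` is reached. The average model's stereochemistry is
#' deliberately unconstrained, as for an NMR mean structure.
#'
#' @param ensemble a [model_ensemble] with n >= 2 models.
#' @param tol convergence tolerance on the RMS displacement of the mean
#'   coordinates between iterations (Angstrom).
#' @param max_iter iteration cap; non-convergence is flagged, not an error.
#' @return object of class `average_model`: `structure` (a
#'   [ca_structure]), `iterations`, `converged`.
#' @export
average_model <- function(ensemble, tol = 1e-4, max_iter = 100L) {
  stopifnot(inherits(ensemble, "model_ensemble"))
  if (ensemble$n < 2L)
    stop(data_error("average model requires an ensemble of at least 2 models"))
  ref <- ensemble$models[[1]]$xyz
  iters <- 0L
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    iters <- it
    fitted <- lapply(ensemble$models, function(m)
      apply_superposition(kabsch_superpose(m$xyz, ref), m$xyz))
    newref <- Reduce(`+`, fitted) / length(fitted)
    disp <- sqrt(mean(rowSums((newref - ref)^2)))
    ref <- newref
    if (disp < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf(
      "average model did not converge in %d iterations", max_iter),
      call. = FALSE)
  m1 <- ensemble$models[[1]]
  structure(list(
    structure = ca_structure("average", m1$resno, m1$resnames, ref,
                             inscode = m1$inscode),
    iterations = iters, converged = converged),
    class = "average_model")
}

#' @export
print.average_model <- function(x, ...) {
  cat(sprintf("Average model: %d residues, %d iteration(s), converged = %s\n",
              nresidues(x$structure), x$iterations, x$converged))
  invisible(x)
}

#' Average cRMS of an ensemble to its average model
#'
#' The ensemble heterogeneity statistic: the mean over models of
#' cRMS(M_i, MA). This is the quantity the heterogeneity score maps onto
#' the 0-10 scale.
#'
#' @param ensemble a [model_ensemble].
#' @param ma an [average_model] (computed with [average_model()] if
#'   omitted).
#' @return mean cRMS in Angstrom.
#' @export
ensemble_spread <- function(ensemble, ma = average_model(ensemble)) {
  stopifnot(inherits(ensemble, "model_ensemble"))
  ref <- if (inherits(ma, "average_model")) ma$structure else ma
  mean(vapply(ensemble$models, crms, 0, b = ref))
}
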