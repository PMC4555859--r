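#' Distance-matrix RMSD (dRMSD)
#'
#' Root of the mean squared difference between the intra-structure pairwise
#' Euclidean distances of two equal-length coordinate sets, averaged over
#' all n(n-1)/2 pairs. Being a function of internal distances only, it is
#' invariant to rigid motion of either input and needs no superposition.
#' Note the all-pairs range: unlike the contact energy, pairs at sequence
#' separation 1 are included.
#'
#' @param observed,native n x 3 coordinate matrices (lattice units and
#'   angstroms respectively, unless `scale` is used).
#' @param scale Optional uniform factor applied to `observed` first.
#' @return The dRMSD value.
#' @export
#' @examples
#' a <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
#' b <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))
#' drmsd(a, b)
drmsd <- function(observed, native, scale = 1) {
  observed <- as.matrix(observed) * scale
  native <- as.matrix(native)
  if (nrow(observed) != nrow(native))
    stop("coordinate sets differ in length")
  if (nrow(observed) < 2L) stop("need at least 2 points")
  do <- stats::dist(observed)
  dn <- stats::dist(native)
  sqrt(mean((do - dn)^2))
}

#' Relative improvement (percent)
#'
#' `(E_t - E_r) / E_r * 100`: the improvement of a target energy over a
#' reference energy, normalized by the reference. For minimization with
#' negative energies, a positive value means the target is lower (better).
#'
#' @param target_energy,reference_energy Energies; the reference must be
#'   nonzero.
#' @return Percentage (vectorized).
#' @export
#' @examples
#' relative_improvement(-170.27, -166.88)  # about 2.03
relative_improvement <- function(target_energy, reference_energy) {
  if (any(reference_energy == 0)) stop("reference energy must be nonzero")
  (target_energy - reference_energy) / reference_energy * 100
}

#' Search speed-up
#'
#' Ratio of the reference method's average objective-evaluation count to
#' the target's: how many times fewer candidate scorings the target needed.
#'
#' @param reference_avg_evals,target_avg_evals Positive counts.
#' @return The ratio (vectorized).
#' @export
#' @examples
#' speedup(39.82e6, 1.86e6)  # about 21.41
speedup <- function(reference_avg_evals, target_avg_evals) {
  if (any(reference_avg_evals <= 0) || any(target_avg_evals <= 0))
    stop("evaluation counts must be positive")
  reference_avg_evals / target_avg_evals
}

#' Least-squares trend line
#'
#' Ordinary least-squares slope and intercept by the closed forms
#' `m = (n sum(xy) - sum(x) sum(y)) / (n sum(x^2) - sum(x)^2)` and
#' `c = (sum(y) - m sum(x)) / n`.
#'
#' @param x,y Numeric vectors of equal length (>= 2, x not constant).
#' @return A list of class `"trend_line"` with `slope` and `intercept`.
#' @export
#' @examples
#' trend_fit(0:2, c(0, 1, 0))  # slope 0, intercept 1/3
trend_fit <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length")
  n <- length(x)
  if (n < 2L) stop("need at least 2 points")
  denom <- n * sum(x^2) - sum(x)^2
  if (denom == 0) stop("degenerate fit: all x values equal")
  m <- (n * sum(x * y) - sum(x) * sum(y)) / denom
  c0 <- (sum(y) - m * sum(x)) / n
  structure(list(slope = m, intercept = c0), class = "trend_line")
}

#' @export
print.trend_line <- function(x, ...) {
  cat(sprintf("trend line: y = %.6g x + %.6g\n", x$slope, x$intercept))
  invisible(x)
}

#' Read native alpha-carbon coordinates from a PDB file
#'
#' Reads only the CA atoms of the first model (and one chain), matching the
#' single-point-per-residue representation of the lattice model.
#'
#' @param path PDB file path.
#' @param chain Optional chain identifier; default takes the first chain.
#' @return An n x 3 coordinate matrix in angstroms.
#' @export
read_native_ca <- function(path, chain = NULL) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("reading PDB files requires the 'bio3d' package")
  pdb <- bio3d::read.pdb(path, multi = FALSE)
  sel <- bio3d::atom.select(pdb, elety = "CA",
                            chain = if (is.null(chain))
                              pdb$atom$chain[1] else chain)
  m <- matrix(pdb$xyz[1, sel$xyz], ncol = 3, byrow = TRUE)
  colnames(m) <- c("x", "y", "z")
  m
}
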