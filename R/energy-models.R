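#' The 20-letter amino-acid alphabet
#'
#' @return Character vector of the 20 one-letter codes, alphabetical order.
#' @export
amino_acids <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Construct a contact energy matrix
#'
#' A contact potential assigns an additive energy to every unordered pair of
#' amino-acid types; the energy of a conformation is the sum over all its
#' contacts ([evaluate_energy()]). The matrix must be complete over the
#' 20-letter alphabet and symmetric (the potential is commutative).
#'
#' @param entries 20 x 20 numeric matrix; dimnames either absent (assumed in
#'   [amino_acids()] order) or a permutation of the alphabet.
#' @param label Character tag, conventionally one of `"BM"`, `"HP"`, `"GW"`.
#' @return A `"contact_energy_matrix"`: a 20 x 20 symmetric numeric matrix
#'   with alphabet dimnames and a `label` attribute.
#' @export
contact_energy_matrix <- function(entries, label = "BM") {
  aa <- amino_acids()
  m <- as.matrix(entries)
  if (!all(dim(m) == c(20L, 20L)))
    stop("a contact energy matrix must be 20 x 20")
  if (is.null(dimnames(m))) {
    dimnames(m) <- list(aa, aa)
  } else {
    if (!setequal(rownames(m), aa) || !setequal(colnames(m), aa))
      stop("matrix dimnames must be the 20 one-letter amino-acid codes")
    m <- m[aa, aa]
  }
  if (anyNA(m)) stop("contact energy matrix has missing entries")
  if (max(abs(m - t(m))) > 1e-9)
    stop("contact energy matrix must be symmetric")
  m <- (m + t(m)) / 2
  structure(m, class = c("contact_energy_matrix", "matrix", "array"),
            label = label)
}

#' @export
print.contact_energy_matrix <- function(x, ...) {
  cat(sprintf("contact energy matrix [%s]: 210 unordered pairs, |E| in [%.3f, %.3f]\n",
              attr(x, "label"), min(abs(x)), max(abs(x))))
  invisible(x)
}

#' Read a contact energy matrix from a tab-separated file
#'
#' Accepts a full 20 x 20 table or a lower triangle (missing upper entries
#' mirrored), with one-letter row and column headers; lines starting with
#' `#` are comments. Unless a custom `scheme` is supplied, magnitudes above
#' the default grouping range (|E| x 1000 > 3477) are rejected so that every
#' entry can be assigned a group.
#'
#' @param path File path.
#' @param label Matrix label (default `"BM"`).
#' @param scheme Optional [group_scheme()] defining the admissible range.
#' @return A [contact_energy_matrix()].
#' @export
read_energy_matrix <- function(path, label = "BM", scheme = NULL) {
  tab <- read.delim(path, comment.char = "#", check.names = FALSE,
                    row.names = 1)
  m <- as.matrix(tab)
  if (!all(dim(m) == c(20L, 20L)))
    stop("expected a 20 x 20 table in ", path)
  lower_only <- anyNA(m)
  if (lower_only) {
    miss <- is.na(m)
    tm <- t(m)
    m[miss] <- tm[miss]
    if (anyNA(m)) stop("incomplete matrix in ", path)
  }
  sch <- if (is.null(scheme)) group_scheme() else scheme
  top <- max(sch$upper)
  if (max(abs(m)) * 1000 > top + 1e-6)
    stop(sprintf(
      "matrix magnitude %.3f exceeds the grouping range (max |E| x 1000 = %g); supply a matching scheme",
      max(abs(m)), top))
  contact_energy_matrix(m, label = label)
}

#' The bundled pairwise contact potential (synthetic stand-in)
#'
#' Returns the 20 x 20 contact potential shipped with the package. This
#' table is a *synthetic* stand-in for an empirical statistical contact
#' potential: it is constructed deterministically from the Fauchere-Pliska
#' side-chain hydrophobicity scale plus formal residue charges, and scaled
#' so that the largest magnitude is 3.477 (matching the default grouping
#' range). It reproduces the qualitative features that matter to the search
#' -- strongly attractive hydrophobic pairs, mildly repulsive like-charged
#' pairs, a quasi-linear magnitude spectrum -- but its individual entries
#' are not empirical values. To use a real empirical table, load it with
#' [read_energy_matrix()].
#'
#' @return A [contact_energy_matrix()] with label `"BM"`.
#' @export
bm_matrix <- function() {
  path <- system.file("extdata", "bm_synthetic_contact_energies.tsv",
                      package = "gwfold", mustWork = TRUE)
  read_energy_matrix(path, label = "BM")
}

#' The hydrophobic-polar (HP) contact potential
#'
#' Assigns unit negative energy to hydrophobic-hydrophobic contacts and
#' zero to all others. The default hydrophobic set is the common Dill-style
#' assignment \{A, C, F, I, L, M, V, W, Y\}.
#'
#' @param hydrophobic Character vector: the residues treated as H. Must be
#'   a nonempty proper subset of the alphabet.
#' @return A [contact_energy_matrix()] with label `"HP"`.
#' @export
hp_matrix <- function(hydrophobic = c("A", "C", "F", "I", "L", "M", "V",
                                      "W", "Y")) {
  aa <- amino_acids()
  hydrophobic <- unique(hydrophobic)
  if (!all(hydrophobic %in% aa))
    stop("hydrophobic set contains letters outside the amino-acid alphabet")
  if (length(hydrophobic) == 0L || length(hydrophobic) >= length(aa))
    stop("hydrophobic set must be a nonempty proper subset of the alphabet")
  h <- aa %in% hydrophobic
  m <- -1 * outer(h, h)
  contact_energy_matrix(m, label = "HP")
}

#' Group multiplier
#'
#' The multiplier attached to magnitude group m is `1 + m (m + 1) / 2`,
#' giving 1, 2, 4, 7, 11, 16 for groups 0..5.
#'
#' @param m Non-negative integer group number (vectorized).
#' @return Integer multiplier(s).
#' @export
#' @examples
#' group_multiplier(0:5)
group_multiplier <- function(m) {
  if (any(m < 0)) stop("group number must be non-negative")
  as.integer(1 + m * (m + 1) / 2)
}

#' Magnitude-band grouping scheme
#'
#' Defines the bands of |E| x 1000 used to assign every contact energy to a
#' group; group m gets the multiplier [group_multiplier()]. The default is
#' the six-band scheme 0-100, 101-500, 501-1000, 1001-1500, 1501-2000,
#' 2000-3477. The two top printed bands share the edge 2000; ties at that
#' shared edge go to the higher group, all other band edges are
#' upper-inclusive.
#'
#' @param upper Upper band edges of |E| x 1000, ascending.
#' @param lower Lower band edges; defaults to 0 followed by the printed
#'   integer successors of `upper`, with the top band's lower edge equal to
#'   the previous band's upper edge (the shared-edge convention).
#' @return A data frame of class `"group_scheme"` with columns `group`,
#'   `multiplier`, `lower`, `upper`.
#' @export
#' @examples
#' group_scheme()
#' group_scheme(upper = 3477)  # single band: GW becomes identical to BM
group_scheme <- function(upper = c(100, 500, 1000, 1500, 2000, 3477),
                         lower = NULL) {
  upper <- as.numeric(upper)
  if (is.unsorted(upper, strictly = TRUE))
    stop("band edges must be strictly increasing")
  G <- length(upper)
  if (is.null(lower)) {
    lower <- if (G == 1L) 0 else c(0, upper[-G] + 1)
    if (G > 1L) lower[G] <- upper[G - 1L]  # shared printed edge
  }
  if (length(lower) != G) stop("lower and upper must have equal length")
  sch <- data.frame(group = 0:(G - 1L),
                    multiplier = group_multiplier(0:(G - 1L)),
                    lower = lower, upper = upper)
  class(sch) <- c("group_scheme", "data.frame")
  sch
}

#' Assign contact energies to magnitude groups
#'
#' Grouping operates on the magnitude |E| (both signs are scaled alike).
#' Band edges are upper-inclusive, except that any magnitude at or above
#' the top band's lower edge belongs to the top band -- the convention that
#' resolves the shared printed edge of the default scheme.
#'
#' @param bm_energy Numeric energies (BM scale), vectorized.
#' @param scheme A [group_scheme()].
#' @return Integer group number(s).
#' @export
#' @examples
#' assign_group(c(0.05, 1.25, 3.477))
assign_group <- function(bm_energy, scheme = group_scheme()) {
  v <- abs(bm_energy) * 1000
  G <- nrow(scheme)
  if (any(v > scheme$upper[G] + 1e-6))
    stop("energy magnitude above the top band's upper edge")
  m <- if (G == 1L) rep(0L, length(v))
       else rowSums(outer(v, scheme$upper[-G], ">"))
  m[v >= scheme$lower[G]] <- G - 1L
  as.integer(m)
}

#' Derive the group-weighted (GW) potential
#'
#' Every entry of the input potential is multiplied by the multiplier of
#' the magnitude group it falls in: entries with large |E| are amplified
#' far more than entries with small |E|, which widens the separation
#' between strong and weak contact types while preserving sign, symmetry
#' and the within-group magnitude ordering. A single-band scheme leaves the
#' matrix unchanged.
#'
#' @param bm A [contact_energy_matrix()] (BM scale).
#' @param scheme A [group_scheme()].
#' @return A [contact_energy_matrix()] with label `"GW"` and the scheme
#'   attached as attribute `scheme`.
#' @export
#' @examples
#' gw <- derive_gw_matrix(bm_matrix())
#' range(abs(gw) / pmax(abs(bm_matrix()), 1e-12))
derive_gw_matrix <- function(bm, scheme = group_scheme()) {
  if (!inherits(bm, "contact_energy_matrix"))
    bm <- contact_energy_matrix(bm)
  g <- group_multiplier(assign_group(as.numeric(bm), scheme))
  gw <- matrix(as.numeric(bm) * g, 20L, 20L, dimnames = dimnames(bm))
  out <- contact_energy_matrix(gw, label = "GW")
  attr(out, "scheme") <- scheme
  out
}

#' Conformation energy under a contact potential
#'
#' Sums the potential over all contacts of the conformation: residue pairs
#' with sequence separation > 1 whose lattice points are FCC-adjacent.
#'
#' @param conf A valid [conformation()].
#' @param seq A protein sequence (string or [read_sequence()] result) of
#'   matching length.
#' @param matrix A [contact_energy_matrix()].
#' @return The scalar energy.
#' @export
#' @examples
#' evaluate_energy(conformation(c(1, 1, 1)), "ACDE", bm_matrix())  # 0
evaluate_energy <- function(conf, seq, matrix) {
  conf <- as_conformation(conf)
  codes <- sequence_codes(seq)
  if (length(codes) != length(conf) + 1L)
    stop("sequence length (", length(codes),
         ") does not match conformation length (", length(conf) + 1L, ")")
  if (!inherits(matrix, "contact_energy_matrix"))
    matrix <- contact_energy_matrix(matrix)
  energy_cpp(unclass(conf), codes, unclass(matrix))
}

# 0-based codes into amino_acids() order
sequence_codes <- function(seq) {
  r <- sequence_residues(seq)
  match(r, amino_acids()) - 1L
}

sequence_residues <- function(seq) {
  if (length(seq) == 1L && is.character(seq)) {
    s <- read_sequence(seq)
    strsplit(unclass(s), "")[[1]]
  } else if (is.character(seq)) {
    seq
  } else {
    stop("seq must be a character string or vector of residues")
  }
}

#' Number of potential contacts
#'
#' A potential contact is any residue pair with sequence separation greater
#' than one, i.e. a pair that could form a contact in some conformation;
#' there are (n - 1)(n - 2) / 2 of them.
#'
#' @param n Residue count.
#' @return Integer count (0 for n < 3).
#' @export
#' @examples
#' count_potential_contacts(74)  # 2628
count_potential_contacts <- function(n) {
  n <- as.integer(n)
  ifelse(n < 3L, 0L, as.integer((n - 1) * (n - 2) / 2))
}

#' Number of distinct contact types
#'
#' Counts the distinct unordered amino-acid-type pairs realised over all
#' potential contacts (pairs with sequence separation > 1) of a sequence.
#'
#' @param seq A protein sequence.
#' @return Integer count of distinct type pairs.
#' @export
count_contact_types <- function(seq) {
  r <- sequence_residues(seq)
  n <- length(r)
  if (n < 3L) return(0L)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx <- idx[idx[, 2] - idx[, 1] > 1L, , drop = FALSE]
  a <- r[idx[, 1]]; b <- r[idx[, 2]]
  length(unique(paste(pmin(a, b), pmax(a, b))))
}

#' Energy-level distribution over potential contacts
#'
#' Tabulates, for every distinct energy level of the potential, how many
#' potential contacts of the sequence carry that level. The counts
#' partition all (n - 1)(n - 2) / 2 potential contacts.
#'
#' @param seq A protein sequence.
#' @param matrix A [contact_energy_matrix()].
#' @param normalize If `TRUE`, energy levels are divided by the largest
#'   magnitude level present.
#' @return A data frame with columns `energy` (ascending) and `count`.
#' @export
energy_distribution <- function(seq, matrix, normalize = FALSE) {
  r <- sequence_residues(seq)
  n <- length(r)
  if (n < 3L) stop("sequence must have at least 3 residues")
  if (!inherits(matrix, "contact_energy_matrix"))
    matrix <- contact_energy_matrix(matrix)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx <- idx[idx[, 2] - idx[, 1] > 1L, , drop = FALSE]
  e <- unclass(matrix)[cbind(r[idx[, 1]], r[idx[, 2]])]
  tab <- table(e)
  lev <- as.numeric(names(tab))
  ord <- order(lev)
  out <- data.frame(energy = lev[ord], count = as.integer(tab)[ord])
  if (normalize) out$energy <- out$energy / max(abs(out$energy))
  out
}
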