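#' The 12 FCC basis vectors
#'
#' Returns the twelve nearest-neighbour displacement vectors of the
#' face-centred-cubic lattice, in the conventional order v1..v12. Every
#' vector has components in \{-1, 0, 1\} and L1 norm 2, and the set is
#' closed under negation (v2 = -v1, v4 = -v3, and so on).
#'
#' @return A 12 x 3 integer matrix with rownames `v1`..`v12`.
#' @export
#' @examples
#' fcc_basis_vectors()
fcc_basis_vectors <- function() {
  m <- matrix(c(
    1, 1, 0, -1, -1, 0, -1, 1, 0, 1, -1, 0,
    0, 1, 1, 0, 1, -1, 0, -1, 1, 0, -1, -1,
    1, 0, 1, -1, 0, 1, 1, 0, -1, -1, 0, -1),
    ncol = 3, byrow = TRUE)
  storage.mode(m) <- "integer"
  dimnames(m) <- list(paste0("v", 1:12), c("x", "y", "z"))
  m
}

#' FCC adjacency test
#'
#' Two lattice points are adjacent when every coordinate differs by at most
#' one and the L1 distance is exactly two.
#'
#' @param p,q Integer vectors of length 3.
#' @return `TRUE` or `FALSE`.
#' @export
#' @examples
#' fcc_is_adjacent(c(0, 0, 0), c(1, 1, 0))  # TRUE
#' fcc_is_adjacent(c(0, 0, 0), c(2, 0, 0))  # FALSE
fcc_is_adjacent <- function(p, q) {
  d <- abs(as.integer(p) - as.integer(q))
  all(d <= 1L) && sum(d) == 2L
}

#' The 12 FCC neighbours of a point
#'
#' @param p Integer vector of length 3.
#' @return A 12 x 3 integer matrix, `p` plus each basis vector.
#' @export
fcc_neighbors <- function(p) {
  sweep(fcc_basis_vectors(), 2, -as.integer(p))
}

#' Construct a conformation from direction indices
#'
#' A conformation of an n-residue chain is a sequence of n-1 indices into
#' the FCC basis vectors ([fcc_basis_vectors()]); residue 1 sits at the
#' origin and residue k+1 at the position of residue k plus the k-th basis
#' vector. The encoding guarantees the chain constraint by construction;
#' self-avoidance is checked separately by [validate_conformation()].
#'
#' @param directions Integer vector with values in 1..12, length >= 1.
#' @return An integer vector of class `"conformation"`.
#' @seealso [decode_conformation()], [validate_conformation()],
#'   [chain_growth_init()]
#' @export
#' @examples
#' conformation(c(1, 1, 5))
conformation <- function(directions) {
  d <- as.integer(directions)
  if (length(d) < 1L)
    stop("a conformation needs at least 2 residues (1 direction)")
  if (anyNA(d) || any(d < 1L | d > 12L))
    stop("direction indices must lie in 1..12")
  structure(d, class = "conformation")
}

as_conformation <- function(x) {
  if (inherits(x, "conformation")) x else conformation(x)
}

#' @export
print.conformation <- function(x, ...) {
  cat("FCC conformation:", length(x) + 1L, "residues\n")
  cat("directions:", paste(unclass(x), collapse = " "), "\n")
  invisible(x)
}

#' Decode a conformation into lattice coordinates
#'
#' @param conf A [conformation()] (or bare integer vector of directions).
#' @param origin Integer vector of length 3; position of residue 1.
#' @return An n x 3 integer matrix of lattice coordinates. Decoding does not
#'   check self-avoidance; use [validate_conformation()].
#' @export
#' @examples
#' decode_conformation(conformation(c(1, 1)))
decode_conformation <- function(conf, origin = c(0L, 0L, 0L)) {
  conf <- as_conformation(conf)
  m <- decode_cpp(unclass(conf), as.integer(origin))
  colnames(m) <- c("x", "y", "z")
  m
}

#' Check the self-avoiding walk constraint
#'
#' @param conf A conformation.
#' @return A list with `valid` (logical) and, when invalid, `violation`:
#'   the 1-based index of the first residue that lands on an occupied point.
#' @export
#' @examples
#' validate_conformation(conformation(c(1, 1, 1)))  # straight chain, valid
#' validate_conformation(conformation(c(1, 2)))     # immediate backtrack
validate_conformation <- function(conf) {
  conf <- as_conformation(conf)
  v <- validate_cpp(unclass(conf))
  if (v == 0L) list(valid = TRUE, violation = NULL)
  else list(valid = FALSE, violation = v)
}

#' Contact test for a residue pair
#'
#' Residues a and b of a decoded conformation are in contact when they are
#' non-adjacent in sequence (|a - b| > 1) and their lattice points are
#' FCC-adjacent.
#'
#' @param a,b 1-based residue indices.
#' @param coords n x 3 coordinate matrix from [decode_conformation()].
#' @return `TRUE` or `FALSE`.
#' @export
is_contact <- function(a, b, coords) {
  n <- nrow(coords)
  if (a < 1 || a > n || b < 1 || b > n)
    stop("residue index out of range 1..", n)
  abs(a - b) > 1L && fcc_is_adjacent(coords[a, ], coords[b, ])
}

#' Enumerate all contacts of a conformation
#'
#' @param conf A valid conformation.
#' @return A 2-column integer matrix of residue index pairs (a, b), a < b,
#'   each pair FCC-adjacent with sequence separation > 1.
#' @export
enumerate_contacts <- function(conf) {
  conf <- as_conformation(conf)
  m <- contacts_cpp(unclass(conf))
  colnames(m) <- c("a", "b")
  m
}

#' Random chain-growth initialization
#'
#' Grows a self-avoiding walk one residue at a time, sampling uniformly
#' among the basis directions that lead to unoccupied points. A dead end
#' (no free neighbour) restarts the whole chain; persistent failure is an
#' error. Reproducible under [set.seed()].
#'
#' @param n Residue count, n >= 2.
#' @param max_restarts Restart budget before giving up (default 1000).
#' @return A valid [conformation()] of length n.
#' @export
#' @examples
#' set.seed(1)
#' chain_growth_init(10)
chain_growth_init <- function(n, max_restarts = 1000L) {
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("n must be at least 2")
  structure(chain_growth_cpp(n, as.integer(max_restarts)),
            class = "conformation")
}
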