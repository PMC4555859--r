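#' Crossover of two conformations
#'
#' Swaps the direction-string suffixes of two equal-length parents at a cut
#' point, producing two children. Children are returned together with their
#' self-avoidance verdicts; invalid children are reported, not discarded.
#'
#' @param parent1,parent2 Conformations of equal length.
#' @param cut Cut position, 1 <= cut <= n - 2 (measured in direction-string
#'   positions: the first `cut` directions come from one parent).
#' @return A list with `children` (list of two conformations) and `valid`
#'   (logical vector of length 2).
#' @export
#' @examples
#' crossover(conformation(c(1, 1, 1)), conformation(c(3, 3, 3)), cut = 1)
crossover <- function(parent1, parent2, cut) {
  p1 <- as_conformation(parent1)
  p2 <- as_conformation(parent2)
  if (length(p1) != length(p2))
    stop("parent conformations differ in length")
  L <- length(p1)
  cut <- as.integer(cut)
  if (cut < 1L || cut > L - 1L)
    stop("cut must lie in 1..", L - 1L)
  c1 <- conformation(c(unclass(p1)[seq_len(cut)],
                       unclass(p2)[(cut + 1L):L]))
  c2 <- conformation(c(unclass(p2)[seq_len(cut)],
                       unclass(p1)[(cut + 1L):L]))
  list(children = list(c1, c2),
       valid = c(validate_conformation(c1)$valid,
                 validate_conformation(c2)$valid))
}

#' Pull move
#'
#' Relocates the pulling-point residue to a free target point and drags the
#' residues on the pulled side along the old chain -- each steps into the
#' position its predecessor just vacated -- until chain adjacency is
#' restored. The target must be FCC-adjacent to the chain neighbour on the
#' side opposite the pulled end (for an end residue with no such neighbour,
#' to the residue's own current position). Self-avoidance holds by
#' construction; the full conformation is still validated and infeasible
#' moves return `NULL`.
#'
#' @param conf A valid conformation.
#' @param residue 1-based index of the pulling point.
#' @param end Which side of the chain is dragged: `"tail"` (residues after
#'   `residue`) or `"head"` (residues before it).
#' @param target Integer length-3 lattice point, in the coordinate frame of
#'   `decode_conformation(conf)` (residue 1 at the origin).
#' @return The new [conformation()], or `NULL` when infeasible.
#' @export
pull_move <- function(conf, residue, end = c("tail", "head"), target) {
  conf <- as_conformation(conf)
  end <- match.arg(end)
  side <- if (end == "tail") 1L else -1L
  out <- pull_move_cpp(unclass(conf), as.integer(residue), side,
                       as.integer(target))
  if (is.null(out)) NULL else structure(out, class = "conformation")
}

#' Diagonal move (kink jump)
#'
#' Relocates a single residue to a free point that is FCC-adjacent to the
#' positions of both its chain neighbours (to its single neighbour for a
#' terminal residue). Two FCC-adjacent points share exactly four common
#' neighbours, so an interior residue has at most four candidate targets.
#'
#' @param conf A valid conformation.
#' @param residue 1-based residue index.
#' @param target Integer length-3 lattice point.
#' @return The new [conformation()], or `NULL` when infeasible.
#' @export
diagonal_move <- function(conf, residue, target) {
  conf <- as_conformation(conf)
  out <- diagonal_move_cpp(unclass(conf), as.integer(residue),
                           as.integer(target))
  if (is.null(out)) NULL else structure(out, class = "conformation")
}

#' Rotation move
#'
#' Re-samples all directions from a start position onward uniformly at
#' random, retrying until the conformation validates or the retry budget is
#' spent. The prefix (residues 1..start) is unchanged.
#'
#' @param conf A valid conformation.
#' @param start First direction-string position to re-sample, 1..n-1.
#' @param retries Re-sampling budget (default 50).
#' @return The new [conformation()], or `NULL` if no valid re-sampling was
#'   found within the budget.
#' @export
rotation <- function(conf, start, retries = 50L) {
  conf <- as_conformation(conf)
  out <- rotation_cpp(unclass(conf), as.integer(start), as.integer(retries))
  if (is.null(out)) NULL else structure(out, class = "conformation")
}

#' Exhaustive operator application
#'
#' Applies an operator in all possible ways to an individual and returns
#' the best-fit (minimum-energy) valid result: crossover enumerates every
#' cut point and both children; pull enumerates every residue, both pull
#' directions and every free target; diagonal enumerates every residue and
#' every candidate target; rotation draws one re-sampled suffix per start
#' position. Ties are broken by enumeration order, so the result is
#' deterministic given the RNG state. When no candidate is feasible the
#' input is returned unchanged with `feasible = FALSE`.
#'
#' @param op One of `"pull"`, `"crossover"`, `"diagonal"`, `"rotation"`.
#' @param conf The individual's conformation.
#' @param seq The protein sequence.
#' @param matrix Guidance [contact_energy_matrix()].
#' @param partner Second parent (crossover only).
#' @param rot_retries Per-start re-sampling budget for rotation.
#' @return A list (`MoveResult`) with `conformation`, `energy`, `operator`,
#'   `feasible` and `n_evaluations` (candidates scored).
#' @export
#' @examples
#' set.seed(7)
#' conf <- chain_growth_init(12)
#' exhaustive_apply("diagonal", conf, strrep("A", 12), hp_matrix())
exhaustive_apply <- function(op = c("pull", "crossover", "diagonal",
                                    "rotation"),
                             conf, seq, matrix, partner = NULL,
                             rot_retries = 50L) {
  op <- match.arg(op)
  conf <- as_conformation(conf)
  codes <- sequence_codes(seq)
  if (!inherits(matrix, "contact_energy_matrix"))
    matrix <- contact_energy_matrix(matrix)
  opcode <- match(op, c("pull", "crossover", "diagonal", "rotation"))
  partner_d <- if (is.null(partner)) NULL else
    unclass(as_conformation(partner))
  res <- exhaustive_move_cpp(opcode, unclass(conf), partner_d, codes,
                             unclass(matrix), as.integer(rot_retries))
  if (res$feasible) {
    list(conformation = structure(res$directions, class = "conformation"),
         energy = res$energy, operator = op, feasible = TRUE,
         n_evaluations = res$n_evaluations)
  } else {
    list(conformation = conf,
         energy = evaluate_energy(conf, seq, matrix), operator = op,
         feasible = FALSE, n_evaluations = res$n_evaluations)
  }
}

#' Random-walk perturbation by successive pull moves
#'
#' Applies `n_pulls` random feasible pull moves in sequence; this is the
#' population-shuffling primitive of the stagnation recovery.
#'
#' @param conf A valid conformation.
#' @param n_pulls Number of successive pulls.
#' @param retries Attempts per pull to find a feasible move.
#' @return The perturbed [conformation()] (always valid).
#' @export
random_walk_perturb <- function(conf, n_pulls, retries = 50L) {
  conf <- as_conformation(conf)
  structure(perturb_pulls_cpp(unclass(conf), as.integer(n_pulls),
                              as.integer(retries)),
            class = "conformation")
}
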