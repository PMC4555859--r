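#' Default stagnation threshold by sequence length
#'
#' The number of consecutive non-improving generations tolerated before the
#' random-walk recovery is invoked, keyed by residue count: 50 up to length
#' 63, stepping down to 15 from length 160 on (the benchmark calibration).
#'
#' @param n Residue count.
#' @return Integer threshold.
#' @export
#' @examples
#' default_threshold(74)  # 40
default_threshold <- function(n) {
  steps <- c(64, 74, 90, 108, 120, 142, 160)
  values <- c(50L, 45L, 40L, 35L, 30L, 25L, 20L, 15L)
  values[findInterval(n, steps) + 1L]
}

#' Genetic-algorithm configuration
#'
#' @param population_size Number of individuals (default 50).
#' @param operator_probabilities Named numeric vector over `pull`,
#'   `crossover`, `diagonal`, `rotation`; must sum to 1. Defaults to the
#'   calibrated non-uniform distribution 0.40 / 0.25 / 0.20 / 0.15.
#' @param threshold Non-improving-generation limit before stagnation
#'   recovery; `NULL` selects [default_threshold()] by sequence length.
#' @param guidance Guidance potential: `"GW"`, `"BM"` or `"HP"`.
#' @param exhaustive Apply operators exhaustively (default `TRUE`); the
#'   non-exhaustive variant applies each operator once at random.
#' @param max_generations,max_evaluations,time_budget Stopping criteria;
#'   `NULL` disables one. At least one must be set. `max_evaluations`
#'   bounds the number of objective-function (candidate-scoring)
#'   evaluations, the hardware-independent cost metric; `time_budget` is in
#'   seconds.
#' @param seed Optional integer seed applied at the start of the run.
#' @param group_scheme Grouping scheme used when `guidance = "GW"`.
#' @param matrix Optional base [contact_energy_matrix()]; defaults to
#'   [bm_matrix()]. Reported energies are always on this base scale.
#' @param chain_restarts,rot_retries,move_retries,recovery_retries Retry
#'   budgets for chain growth, rotation re-sampling, non-exhaustive move
#'   draws, and recovery pulls.
#' @return A list of class `"ga_config"`.
#' @export
ga_config <- function(population_size = 50L,
                      operator_probabilities = c(pull = 0.40,
                                                 crossover = 0.25,
                                                 diagonal = 0.20,
                                                 rotation = 0.15),
                      threshold = NULL,
                      guidance = c("GW", "BM", "HP"),
                      exhaustive = TRUE,
                      max_generations = NULL,
                      max_evaluations = NULL,
                      time_budget = NULL,
                      seed = NULL,
                      group_scheme = gwfold::group_scheme(),
                      matrix = NULL,
                      chain_restarts = 1000L,
                      rot_retries = 50L,
                      move_retries = 50L,
                      recovery_retries = 50L) {
  guidance <- match.arg(guidance)
  p <- operator_probabilities
  req <- c("pull", "crossover", "diagonal", "rotation")
  if (!setequal(names(p), req))
    stop("operator_probabilities must be named: ",
         paste(req, collapse = ", "))
  p <- p[req]
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
    stop("operator probabilities must be non-negative and sum to 1")
  if (population_size < 2L) stop("population_size must be at least 2")
  if (!is.null(threshold) && threshold < 1L)
    stop("threshold must be at least 1")
  if (is.null(max_generations) && is.null(max_evaluations) &&
      is.null(time_budget))
    stop("set at least one of max_generations, max_evaluations, time_budget")
  structure(list(population_size = as.integer(population_size),
                 operator_probabilities = p,
                 threshold = threshold,
                 guidance = guidance,
                 exhaustive = isTRUE(exhaustive),
                 max_generations = max_generations,
                 max_evaluations = max_evaluations,
                 time_budget = time_budget,
                 seed = seed,
                 group_scheme = group_scheme,
                 matrix = matrix,
                 chain_restarts = as.integer(chain_restarts),
                 rot_retries = as.integer(rot_retries),
                 move_retries = as.integer(move_retries),
                 recovery_retries = as.integer(recovery_retries)),
            class = "ga_config")
}

#' Draw an operator from the configured distribution
#'
#' Consumes exactly one uniform draw and walks the cumulative distribution,
#' so a degenerate distribution is deterministic and a fixed seed gives an
#' identical draw sequence.
#'
#' @param probs Named probability vector (must sum to 1).
#' @return One of the operator names.
#' @export
select_operator <- function(probs) {
  if (any(probs < 0) || abs(sum(probs) - 1) > 1e-8)
    stop("malformed probability distribution")
  u <- runif(1)
  names(probs)[min(which(u < cumsum(probs)), length(probs))]
}

#' Elitist replacement
#'
#' The child survives only when strictly fitter (lower energy) than its
#' parent; ties keep the parent.
#'
#' @param parent,child Lists with at least `conformation` and `energy`,
#'   scored under the same matrix.
#' @return The surviving individual.
#' @export
elitist_replace <- function(parent, child) {
  if (child$energy < parent$energy) child else parent
}

#' Run the folding search
#'
#' Initializes a population by random chain growth, then iterates: draw one
#' operator from the configured probabilities, apply it (exhaustively by
#' default) to every individual, keep each child only if strictly fitter
#' than its parent, and track the best individual ever seen. After more
#' than `threshold` non-improving generations the population is shuffled by
#' successive random pull moves (random-walk recovery); the shuffle
#' magnitude grows when consecutive recoveries bring no new best. The best
#' individual is archived outside the population and is never lost to
#' recovery. Search guidance uses the configured potential (GW by default);
#' the best individual is additionally re-scored under the base (BM-scale)
#' matrix for reporting.
#'
#' @param seq A protein sequence (string, FASTA path, or benchmark
#'   sequence).
#' @param cfg A [ga_config()].
#' @param init_population Optional list of conformations used instead of
#'   chain-growth initialization (mainly for reproducible experiments).
#' @return A list of class `"gwfold_run"`: best conformation, guidance and
#'   base-scale best energies, evaluation and generation counts, the
#'   per-generation trajectory data frame, per-operator application and
#'   acceptance counts, and the echoed configuration.
#' @export
#' @examples
#' cfg <- ga_config(max_generations = 5, seed = 1, population_size = 10)
#' run <- run_search("MKKYTCTVCGYIYN", cfg)
#' run$best_energy_bm
run_search <- function(seq, cfg = ga_config(max_generations = 100L),
                       init_population = NULL) {
  stopifnot(inherits(cfg, "ga_config"))
  s <- read_sequence(seq)
  codes <- sequence_codes(s)
  n <- length(codes)
  if (n < 3L) stop("sequence too short to fold (need n >= 3)")

  base <- if (is.null(cfg$matrix)) bm_matrix() else cfg$matrix
  guide <- switch(cfg$guidance,
                  GW = derive_gw_matrix(base, cfg$group_scheme),
                  BM = base,
                  HP = hp_matrix())
  threshold <- if (is.null(cfg$threshold)) default_threshold(n)
               else as.integer(cfg$threshold)

  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  init <- NULL
  if (!is.null(init_population)) {
    init <- lapply(init_population, function(x) unclass(as_conformation(x)))
  }
  res <- run_ga_cpp(codes, unclass(guide), unclass(base),
                    cfg$population_size,
                    unname(cfg$operator_probabilities), threshold,
                    if (is.null(cfg$max_generations)) -1L
                    else as.integer(cfg$max_generations),
                    if (is.null(cfg$max_evaluations)) -1
                    else as.numeric(cfg$max_evaluations),
                    if (is.null(cfg$time_budget)) -1
                    else as.numeric(cfg$time_budget),
                    cfg$exhaustive, cfg$chain_restarts, cfg$rot_retries,
                    cfg$move_retries, cfg$recovery_retries, init)

  traj <- as.data.frame(res$trajectory)
  ops <- c("pull", "crossover", "diagonal", "rotation")
  structure(list(
    best_conformation = structure(res$best_directions,
                                  class = "conformation"),
    best_energy = res$best_energy,
    best_energy_bm = res$best_energy_bm,
    initial_best_energy = res$initial_best_energy,
    initial_best_energy_bm = res$initial_best_energy_bm,
    evaluations = res$evaluations,
    generations = res$generations,
    trajectory = traj,
    operators_applied = stats::setNames(res$operators_applied, ops),
    operators_accepted = stats::setNames(res$operators_accepted, ops),
    shuffle_parameter = res$shuffle_parameter,
    recoveries = res$recoveries,
    elapsed = res$elapsed,
    population = lapply(res$population, structure, class = "conformation"),
    population_energies = res$population_energies,
    sequence = unclass(s),
    guidance = cfg$guidance,
    threshold = threshold,
    config = cfg), class = "gwfold_run")
}

#' @export
print.gwfold_run <- function(x, ...) {
  cat(sprintf("gwfold run: n = %d, guidance = %s\n",
              length(x$best_conformation) + 1L, x$guidance))
  cat(sprintf("  best energy (%s guidance): %.3f\n", x$guidance,
              x$best_energy))
  cat(sprintf("  best energy (base scale): %.3f\n", x$best_energy_bm))
  cat(sprintf("  generations: %d, objective evaluations: %.0f, recoveries: %d\n",
              x$generations, x$evaluations, x$recoveries))
  cat(sprintf("  elapsed: %.2f s\n", x$elapsed))
  invisible(x)
}
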