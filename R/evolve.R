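#' Canonical amino-acid alphabet
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Wimley-White interface partitioning scale (kcal/mol, water ->
# POPC interface; negative = favourable). W and F are the most
# favourable residues, matching the aromatic-insertion mechanism that
# drives packing-defect sensing.
.WW_INTERFACE <- c(A = 0.17, R = 0.81, N = 0.42, D = 1.23, C = -0.24,
                   Q = 0.58, E = 2.02, G = 0.01, H = 0.96, I = -0.31,
                   L = -0.56, K = 0.99, M = -0.23, F = -1.13, P = 0.45,
                   S = 0.13, T = 0.14, W = -1.85, Y = -0.94, V = 0.07)

#' Surrogate sensing fitness for peptide sequences
#'
#' A cheap stand-in for an MD-derived sensing free energy, built from
#' the two signatures of strong defect sensors: interface
#' hydrophobicity (Wimley-White interface scale, summed over residues)
#' and enrichment in the large aromatics W and F (an extra -0.5 per
#' aromatic). Lower is better, mirroring the convention that fitness is
#' the sensing free energy; the global optimum is poly-tryptophan by
#' construction. The surrogate ranks sequences plausibly but makes no
#' claim to reproduce MD optima.
#'
#' @param sequence character vector of amino-acid strings.
#' @return numeric fitness (pseudo-energy, lower = better sensing).
#' @export
surrogate_fitness <- function(sequence) {
  vapply(sequence, function(s) {
    aa <- strsplit(s, "")[[1]]
    bad <- setdiff(aa, AA_ALPHABET)
    if (length(bad) > 0L)
      stop("invalid residue(s) ", paste(bad, collapse = ""), " in sequence ",
           s, call. = FALSE)
    sum(.WW_INTERFACE[aa]) - 0.5 * sum(aa %in% c("W", "F"))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Genetic-algorithm parameters
#'
#' Defaults (population 32, 8 parents, crossover 0.9, per-residue
#' mutation 0.02, elitism 2, 24-residue sequences) follow common
#' directed-evolution practice for fixed-length peptide design; all are
#' exposed.
#'
#' @param population_size individuals per generation.
#' @param n_generations generations to run.
#' @param n_parents top individuals eligible as parents.
#' @param crossover_rate probability an offspring is a single-point
#'   recombination of two parents (else a clone of one).
#' @param mutation_rate per-residue point-mutation probability.
#' @param elitism_count best individuals copied unchanged.
#' @param seq_length fixed sequence length.
#' @param alphabet residue alphabet (restrict it for toy problems).
#' @param stall_window generations of unchanged best fitness that
#'   trigger the convergence flag.
#' @param seed RNG seed for the whole run.
#' @return an `evolution_params` list.
#' @export
evolution_params <- function(population_size = 32L, n_generations = 25L,
                             n_parents = 8L, crossover_rate = 0.9,
                             mutation_rate = 0.02, elitism_count = 2L,
                             seq_length = 24L, alphabet = AA_ALPHABET,
                             stall_window = 5L, seed = 1L) {
  stopifnot(population_size >= 1L, n_generations >= 1L,
            n_parents >= 1L, n_parents <= population_size,
            crossover_rate >= 0, crossover_rate <= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            elitism_count >= 0L, elitism_count <= population_size,
            seq_length >= 1L, length(alphabet) >= 2L, stall_window >= 1L)
  structure(list(population_size = as.integer(population_size),
                 n_generations = as.integer(n_generations),
                 n_parents = as.integer(n_parents),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 elitism_count = as.integer(elitism_count),
                 seq_length = as.integer(seq_length),
                 alphabet = alphabet,
                 stall_window = as.integer(stall_window),
                 seed = as.integer(seed)),
            class = "evolution_params")
}

#' Random initial population
#'
#' Draws `population_size` sequences uniformly over the alphabet.
#' Randomness comes from the current RNG state; [run_evolution()] seeds
#' it once from `params$seed`.
#'
#' @param params an [evolution_params()].
#' @return data frame with `sequence` and unset `fitness`.
#' @export
initialize_population <- function(params) {
  stopifnot(inherits(params, "evolution_params"))
  if (params$population_size < 1L)
    stop("population size must be >= 1", call. = FALSE)
  seqs <- vapply(seq_len(params$population_size), function(i)
    paste(sample(params$alphabet, params$seq_length, replace = TRUE),
          collapse = ""),
    character(1))
  data.frame(sequence = seqs, fitness = NA_real_, stringsAsFactors = FALSE)
}

#' Evaluate one sequence
#'
#' Applies the fitness function (lower = better; the convention is that
#' fitness is a sensing free energy) to a single sequence, wrapping any
#' failure with the offending sequence for context. MD-backed fitness
#' functions plug in through the same signature.
#'
#' @param sequence an amino-acid string.
#' @param fitness_fn function mapping a sequence to a single number.
#' @return numeric fitness.
#' @export
evaluate_fitness <- function(sequence, fitness_fn = surrogate_fitness) {
  val <- tryCatch(fitness_fn(sequence), error = function(e)
    stop("fitness evaluation failed for sequence ", sQuote(sequence), ": ",
         conditionMessage(e), call. = FALSE))
  if (!is.numeric(val) || length(val) != 1L || !is.finite(val))
    stop("fitness function must return one finite number for ",
         sQuote(sequence), call. = FALSE)
  as.numeric(val)
}

.evaluate_population <- function(pop, fitness_fn) {
  todo <- which(is.na(pop$fitness))
  if (length(todo) > 0L)
    pop$fitness[todo] <- vapply(pop$sequence[todo], evaluate_fitness,
                                numeric(1), fitness_fn = fitness_fn,
                                USE.NAMES = FALSE)
  pop
}

#' Produce the next generation
#'
#' Elitism carries the `elitism_count` best individuals over unchanged;
#' the remaining slots are filled by offspring of random pairs drawn
#' from the `n_parents` best: with probability `crossover_rate` a
#' single-point crossover of the pair, otherwise a clone of the first
#' parent, followed by per-residue point mutation (to a different
#' letter) at `mutation_rate`. Population size and sequence length are
#' preserved. All individuals must already be evaluated.
#'
#' @param population evaluated population data frame.
#' @param params an [evolution_params()].
#' @return new population data frame (offspring fitness unset).
#' @export
next_generation <- function(population, params) {
  stopifnot(inherits(params, "evolution_params"))
  if (anyNA(population$fitness))
    stop("all individuals must be evaluated before selection", call. = FALSE)
  ord <- order(population$fitness)
  pop <- population[ord, , drop = FALSE]
  L <- params$seq_length
  elite <- utils::head(pop, params$elitism_count)
  n_off <- params$population_size - nrow(elite)
  parents <- utils::head(pop$sequence, params$n_parents)
  offspring <- character(n_off)
  for (i in seq_len(n_off)) {
    pr <- sample(length(parents), 2L, replace = length(parents) == 1L)
    child <- if (stats::runif(1) < params$crossover_rate && L >= 2L) {
      k <- sample(L - 1L, 1L)
      a <- strsplit(parents[pr[1]], "")[[1]]
      b <- strsplit(parents[pr[2]], "")[[1]]
      c(a[1:k], b[(k + 1L):L])
    } else {
      strsplit(parents[pr[1]], "")[[1]]
    }
    mut <- stats::runif(L) < params$mutation_rate
    if (any(mut))
      child[mut] <- vapply(child[mut], function(aa)
        sample(setdiff(params$alphabet, aa), 1L), character(1))
    offspring[i] <- paste(child, collapse = "")
  }
  out <- rbind(elite,
               data.frame(sequence = offspring,
                          fitness = rep(NA_real_, n_off),
                          stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Run a directed-evolution optimization
#'
#' Iterates evaluate - select - recombine - mutate from a random
#' population, recording the best and mean fitness of every generation.
#' With elitism >= 1 the best fitness is monotone non-increasing. The
#' run is flagged converged the first time the best fitness is
#' unchanged for `stall_window` consecutive generations. The whole run
#' is reproducible from `params$seed`; the caller's RNG state is left
#' untouched.
#'
#' @param params an [evolution_params()].
#' @param fitness_fn fitness function (lower = better); default the
#'   built-in surrogate.
#' @return an `evolution_history`: list with `history` (data frame
#'   `generation`, `best_fitness`, `mean_fitness`, `best_sequence`),
#'   `converged`, `converged_at`, `best_sequence`, `best_fitness`,
#'   `final_population`, `params`.
#' @export
run_evolution <- function(params, fitness_fn = surrogate_fitness) {
  stopifnot(inherits(params, "evolution_params"))
  withr::with_seed(params$seed, {
    pop <- .evaluate_population(initialize_population(params), fitness_fn)
    record <- function(gen, pop) {
      i <- which.min(pop$fitness)
      data.frame(generation = gen, best_fitness = pop$fitness[i],
                 mean_fitness = mean(pop$fitness),
                 best_sequence = pop$sequence[i],
                 stringsAsFactors = FALSE)
    }
    hist <- record(0L, pop)
    stall <- 0L
    converged_at <- NA_integer_
    for (g in seq_len(params$n_generations)) {
      pop <- .evaluate_population(next_generation(pop, params), fitness_fn)
      hist <- rbind(hist, record(g, pop))
      if (hist$best_fitness[g + 1L] >= hist$best_fitness[g] - 1e-12) {
        stall <- stall + 1L
        if (is.na(converged_at) && stall >= params$stall_window)
          converged_at <- g
      } else {
        stall <- 0L
      }
    }
    i <- which.min(pop$fitness)
    structure(list(history = hist,
                   converged = !is.na(converged_at),
                   converged_at = converged_at,
                   best_sequence = pop$sequence[i],
                   best_fitness = pop$fitness[i],
                   final_population = pop,
                   params = params),
              class = "evolution_history")
  })
}

#' @export
print.evolution_history <- function(x, ...) {
  n <- nrow(x$history) - 1L
  cat("Directed evolution: ", n, " generations, population ",
      x$params$population_size, "\n", sep = "")
  cat(sprintf("best fitness %.4g (%s)\n", x$best_fitness, x$best_sequence))
  cat(if (x$converged)
    paste0("converged at generation ", x$converged_at, "\n")
    else "did not converge\n")
  invisible(x)
}
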