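#' Initialise a fixed-cardinality GA population
#'
#' Individuals are sorted integer vectors of exactly `m` distinct gene
#' indices in `1..p` — the "choose m of p" encoding (equivalently a binary
#' string with exactly m ones). Duplicate individuals in the population are
#' allowed.
#'
#' @param p Number of available genes.
#' @param m Subset size per individual.
#' @param pop_size Population size.
#' @return A `ga_state` list: `population` (list of sorted index vectors),
#'   `fitness` (numeric, `NA` until evaluated), `generation`, `p`, `m`.
#' @export
init_population <- function(p, m, pop_size) {
  if (m > p) abort(sprintf("subset size m=%d exceeds gene count p=%d.", m, p))
  population <- purrr::map(seq_len(pop_size), function(i) sort(sample.int(p, m)))
  structure(list(population = population,
                 fitness = rep(NA_real_, pop_size),
                 generation = 0L, p = p, m = m),
            class = "ga_state")
}

#' Cardinality-preserving crossover
#'
#' The child keeps every index both parents share and fills the remaining
#' slots by uniform draws without replacement from the symmetric difference,
#' so the child always has exactly the parents' cardinality.
#'
#' @param a,b Sorted integer index vectors of equal length.
#' @return Sorted integer index vector of the same length.
#' @export
crossover <- function(a, b) {
  common <- intersect(a, b)
  need <- length(a) - length(common)
  if (need == 0) return(sort(common))
  pool <- c(setdiff(a, b), setdiff(b, a))
  picked <- pool[sample.int(length(pool), need)]
  sort(c(common, picked))
}

#' Cardinality-preserving mutation
#'
#' Each selected index is, independently with probability `rate`, swapped for
#' a uniform draw from the currently unselected indices.
#'
#' @param ind Sorted integer index vector.
#' @param rate Per-index swap probability in `[0, 1]`.
#' @param p Total number of genes.
#' @return Sorted integer index vector of the same length.
#' @export
mutate <- function(ind, rate, p) {
  m <- length(ind)
  flip <- runif(m) < rate
  if (!any(flip)) return(ind)
  out <- ind
  for (i in which(flip)) {
    pool <- setdiff(seq_len(p), out)
    if (length(pool) == 0) break
    out[i] <- pool[sample.int(length(pool), 1)]
  }
  sort(out)
}

eval_population <- function(state, fitness_fn) {
  todo <- which(is.na(state$fitness))
  for (i in todo) {
    val <- fitness_fn(state$population[[i]])
    if (is.na(val) || is.nan(val)) {
      warn("fitness returned NaN; treated as +Inf.")
      val <- Inf
    }
    state$fitness[i] <- val
  }
  state
}

sort_state <- function(state) {
  ord <- order(state$fitness,
               vapply(state$population,
                      function(s) paste(sprintf("%09d", s), collapse = ""),
                      character(1)))
  state$population <- state$population[ord]
  state$fitness <- state$fitness[ord]
  state
}

#' Run the genetic algorithm
#'
#' Minimises `fitness_fn` over fixed-size index subsets. Each generation the
#' best `elitism` individuals are copied unchanged; the remaining slots are
#' filled by tournament selection (smaller fitness wins), crossover, and
#' mutation. The returned population is sorted ascending by fitness with
#' lexicographic tie-breaking, so runs are deterministic given the RNG state.
#'
#' @param state A `ga_state` from [init_population()].
#' @param fitness_fn Function mapping an index vector to a real value
#'   (minimised); `NaN` is treated as `Inf` with a warning.
#' @param generations Number of generations (`>= 1`).
#' @param tournament_size Tournament size for parent selection.
#' @param elitism Number of elites copied unchanged per generation.
#' @param mutation_rate Per-index mutation probability.
#' @return The final `ga_state`, sorted ascending by fitness, with a
#'   `history` element (best fitness per generation).
#' @export
evolve <- function(state, fitness_fn, generations = 100,
                   tournament_size = 2, elitism = 1, mutation_rate = 0.01) {
  stopifnot(generations >= 1)
  pop_size <- length(state$population)
  state <- eval_population(state, fitness_fn)
  state <- sort_state(state)
  history <- numeric(generations)
  pick_parent <- function() {
    cand <- sample.int(pop_size, tournament_size, replace = TRUE)
    cand[which.min(state$fitness[cand])]
  }
  for (g in seq_len(generations)) {
    newpop <- vector("list", pop_size)
    newfit <- rep(NA_real_, pop_size)
    if (elitism > 0) {
      keep <- seq_len(min(elitism, pop_size))
      newpop[keep] <- state$population[keep]
      newfit[keep] <- state$fitness[keep]
    }
    for (i in seq(from = elitism + 1, length.out = pop_size - elitism)) {
      a <- state$population[[pick_parent()]]
      b <- state$population[[pick_parent()]]
      newpop[[i]] <- mutate(crossover(a, b), mutation_rate, state$p)
    }
    state$population <- newpop
    state$fitness <- newfit
    state <- eval_population(state, fitness_fn)
    state <- sort_state(state)
    state$generation <- state$generation + 1L
    history[g] <- state$fitness[1]
  }
  state$history <- history
  state
}

#' Best distinct individuals of the final generation
#'
#' Collapses duplicate subsets, then returns up to `count` distinct subsets
#' in ascending fitness order (lexicographic subset order on ties). Fewer
#' than `count` are returned when the population holds fewer distinct
#' subsets.
#'
#' @param state A `ga_state` (evaluated).
#' @param count Maximum number of subsets to return.
#' @return A list with elements `subsets` (list of index vectors) and
#'   `fitness` (ascending numeric vector of matching length).
#' @export
top_k <- function(state, count) {
  stopifnot(count <= length(state$population))
  keys <- vapply(state$population,
                 function(s) paste(sprintf("%09d", s), collapse = ""),
                 character(1))
  first <- !duplicated(keys)
  subsets <- state$population[first]
  fit <- state$fitness[first]
  ord <- order(fit, keys[first])
  take <- seq_len(min(count, length(subsets)))
  list(subsets = subsets[ord][take], fitness = fit[ord][take])
}
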