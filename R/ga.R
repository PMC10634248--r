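# Genetic-algorithm search for parsimonious marker subsets maximising
# cross-validated LDA accuracy, with a final-generation pooling,
# re-evaluation and ranking protocol: the GA is run several times, the
# unique subsets of each run's final generation are pooled and re-evaluated
# with an independent, longer CV, and ranked by mean correct classification
# rate.

#' Genetic-algorithm configuration
#'
#' Binary-chromosome GA over marker subsets (one bit per marker).  Fitness
#' is the cross-validated LDA accuracy minus a parsimony penalty of
#' `parsimony_lambda` per included marker.  Search-time fitness uses a
#' shorter CV (`search_repeats`) than the final re-evaluation
#' (`reeval_repeats`), which draws on an independent seed stream.
#'
#' @param population_size chromosomes per generation (default 100).
#' @param n_generations generations per run (default 50).
#' @param crossover_prob probability of uniform crossover (default 0.8).
#' @param mutation_prob per-bit mutation probability; default `NULL` means
#'   `1/p` with `p` the number of markers.
#' @param tournament_size selection tournament size (default 3).
#' @param elitism number of best chromosomes copied unchanged (default 1).
#' @param parsimony_lambda accuracy penalty per marker (default 0.005).
#' @param n_runs independent GA runs whose final generations are pooled
#'   (default 4).
#' @param search_repeats CV repeats for search-time fitness (default 5).
#' @param reeval_repeats,reeval_folds CV protocol for the final
#'   re-evaluation (default 30 repeats, 2 folds).
#' @param max_subset_size optional cap on subset size (`Inf` = none).
#' @param seed integer seed.
#' @return A validated list of class `ga_config`.
#' @export
ga_config <- function(population_size = 100L, n_generations = 50L,
                      crossover_prob = 0.8, mutation_prob = NULL,
                      tournament_size = 3L, elitism = 1L,
                      parsimony_lambda = 0.005, n_runs = 4L,
                      search_repeats = 5L, reeval_repeats = 30L,
                      reeval_folds = 2L, max_subset_size = Inf, seed = 1L) {
  stopifnot(population_size >= 2, n_generations >= 1,
            crossover_prob >= 0, crossover_prob <= 1,
            is.null(mutation_prob) ||
              (mutation_prob >= 0 && mutation_prob <= 1),
            tournament_size >= 1, elitism >= 0,
            parsimony_lambda >= 0, n_runs >= 1,
            search_repeats >= 1, reeval_repeats >= 1, reeval_folds >= 2)
  structure(list(population_size = as.integer(population_size),
                 n_generations = as.integer(n_generations),
                 crossover_prob = crossover_prob,
                 mutation_prob = mutation_prob,
                 tournament_size = as.integer(tournament_size),
                 elitism = as.integer(elitism),
                 parsimony_lambda = parsimony_lambda,
                 n_runs = as.integer(n_runs),
                 search_repeats = as.integer(search_repeats),
                 reeval_repeats = as.integer(reeval_repeats),
                 reeval_folds = as.integer(reeval_folds),
                 max_subset_size = max_subset_size,
                 seed = as.integer(seed)),
            class = "ga_config")
}

#' Fitness of a marker subset
#'
#' Mean cross-validated LDA accuracy of the subset minus
#' `parsimony_lambda` times the subset size.
#'
#' @param subset character vector of marker ids (non-empty).
#' @param x patients x markers matrix with named columns.
#' @param y logical labels.
#' @param config a [ga_config()].
#' @param cv_seed seed for the CV folds (defaults to the config seed).
#' @return A single fitness value.
#' @export
ga_fitness <- function(subset, x, y, config = ga_config(),
                       cv_seed = config$seed) {
  if (length(subset) == 0) stop2("subset must be non-empty")
  idx <- match(subset, colnames(x))
  if (anyNA(idx)) stop2("unknown marker id: ",
                        paste(subset[is.na(idx)], collapse = ", "))
  cv <- cv_evaluate(x[, idx, drop = FALSE], y,
                    n_repeats = config$search_repeats,
                    n_folds = config$reeval_folds, seed = cv_seed)
  cv$accuracy - config$parsimony_lambda * length(subset)
}

# Fitness of a logical chromosome with memoisation (same subset is never
# re-evaluated within a run; folds are fixed per run so fitness is a
# deterministic function of the subset).
.chrom_fitness <- function(chrom, x, y, config, cv_seed, cache) {
  key <- paste(which(chrom), collapse = ",")
  hit <- cache[[key]]
  if (!is.null(hit)) return(hit)
  f <- ga_fitness(colnames(x)[chrom], x, y, config, cv_seed)
  cache[[key]] <- f
  f
}

# Repair a chromosome: activate one uniformly random bit if empty; trim to
# the size cap by deactivating random bits.
.repair <- function(chrom, max_size) {
  if (!any(chrom)) chrom[sample.int(length(chrom), 1L)] <- TRUE
  if (is.finite(max_size) && sum(chrom) > max_size) {
    on <- which(chrom)
    chrom[sample(on, sum(chrom) - max_size)] <- FALSE
  }
  chrom
}

#' Run the genetic algorithm
#'
#' Runs `config$n_runs` independent GA searches (tournament selection,
#' uniform crossover, per-bit mutation, elitism; empty chromosomes repaired
#' by activating one random bit) and returns the de-duplicated final
#' generation of each run with search-time fitness.  Deterministic given
#' the config seed.
#'
#' @param x patients x markers matrix with named columns (>= 2 markers).
#' @param y logical labels.
#' @param config a [ga_config()].
#' @return A list with one element per run; each is a list of
#'   `list(markers =, fitness =)` entries sorted by decreasing fitness.
#' @export
run_ga <- function(x, y, config = ga_config()) {
  x <- as.matrix(x)
  p <- ncol(x)
  if (p < 2) stop2("need at least 2 markers")
  if (is.null(colnames(x))) colnames(x) <- paste0("m", seq_len(p))
  pmut <- config$mutation_prob %||% (1 / p)
  run_seeds <- derive_seeds(config$seed, 2L * config$n_runs)
  lapply(seq_len(config$n_runs), function(run) {
    cv_seed <- run_seeds[2 * run - 1]
    cache <- new.env(parent = emptyenv())
    with_seed(run_seeds[2 * run], {
      pop <- lapply(seq_len(config$population_size), function(i)
        .repair(stats::runif(p) < 0.5, config$max_subset_size))
      fit <- vapply(pop, .chrom_fitness, numeric(1),
                    x = x, y = y, config = config, cv_seed = cv_seed,
                    cache = cache)
      for (gen in seq_len(config$n_generations)) {
        ord <- order(-fit)
        new_pop <- pop[ord[seq_len(min(config$elitism,
                                       config$population_size))]]
        tournament <- function() {
          cand <- sample.int(config$population_size, config$tournament_size,
                             replace = TRUE)
          pop[[cand[which.max(fit[cand])]]]
        }
        while (length(new_pop) < config$population_size) {
          p1 <- tournament(); p2 <- tournament()
          if (stats::runif(1) < config$crossover_prob) {
            take <- stats::runif(p) < 0.5
            c1 <- ifelse(take, p1, p2)
            c2 <- ifelse(take, p2, p1)
          } else {
            c1 <- p1; c2 <- p2
          }
          for (child in list(c1, c2)) {
            if (length(new_pop) >= config$population_size) break
            flip <- stats::runif(p) < pmut
            child <- xor(child, flip)
            new_pop[[length(new_pop) + 1L]] <-
              .repair(child, config$max_subset_size)
          }
        }
        pop <- new_pop
        fit <- vapply(pop, .chrom_fitness, numeric(1),
                      x = x, y = y, config = config, cv_seed = cv_seed,
                      cache = cache)
      }
      keys <- vapply(pop, function(ch) paste(which(ch), collapse = ","), "")
      keep <- !duplicated(keys)
      out <- lapply(which(keep), function(i)
        list(markers = colnames(x)[pop[[i]]], fitness = fit[i]))
      out[order(-vapply(out, `[[`, numeric(1), "fitness"))]
    })
  })
}

#' Select and rank genetic-algorithm solutions
#'
#' Pools the unique final-generation subsets over all GA runs, re-evaluates
#' each with the full repeated-CV protocol (`reeval_repeats` x
#' `reeval_folds`, on a seed stream independent of the search), and ranks
#' the solutions by mean re-evaluated accuracy (ties broken by smaller
#' subset, then lexicographic marker ids).
#'
#' @inheritParams run_ga
#' @return A data.frame of class `ga_solutions`: `rank`, `markers`
#'   (semicolon-joined ids), `n_markers`, `accuracy`, `sensitivity`,
#'   `specificity`, `search_fitness`.
#' @export
select_solutions <- function(x, y, config = ga_config()) {
  runs <- run_ga(x, y, config)
  pool <- list()
  for (r in runs) for (s in r) {
    key <- paste(sort(s$markers), collapse = ";")
    if (is.null(pool[[key]])) pool[[key]] <- s
  }
  reeval_seed <- derive_seeds(config$seed + 1L, 1L)
  x <- as.matrix(x)
  rows <- lapply(pool, function(s) {
    idx <- match(s$markers, colnames(x))
    cv <- cv_evaluate(x[, idx, drop = FALSE], y,
                      n_repeats = config$reeval_repeats,
                      n_folds = config$reeval_folds, seed = reeval_seed)
    data.frame(markers = paste(sort(s$markers), collapse = ";"),
               n_markers = length(s$markers),
               accuracy = cv$accuracy,
               sensitivity = cv$sensitivity,
               specificity = cv$specificity,
               search_fitness = s$fitness,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res <- res[order(-res$accuracy, res$n_markers, res$markers), , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  res <- res[, c("rank", "markers", "n_markers", "accuracy", "sensitivity",
                 "specificity", "search_fitness")]
  class(res) <- c("ga_solutions", "data.frame")
  res
}
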