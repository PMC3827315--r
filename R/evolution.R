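#' Fast non-dominated sorting (NSGA-II)
#'
#' Ranks points of a multi-objective cloud into Pareto fronts, both
#' objectives maximized: front 1 is the non-dominated set, front 2 is
#' non-dominated once front 1 is removed, and so on. A point dominates
#' another if it is no worse on every objective and strictly better on
#' at least one.
#'
#' @param objectives Numeric matrix, one row per individual, one
#'   column per objective (maximized).
#' @return Integer vector of front numbers (1 = best).
#' @export
fast_nondominated_sort <- function(objectives) {
  n <- nrow(objectives)
  if (n == 0) return(integer(0))
  dominated_by <- vector("list", n)
  n_dom <- integer(n)
  for (p in seq_len(n)) {
    for (q in seq_len(n)) {
      if (p == q) next
      if (all(objectives[p, ] >= objectives[q, ]) &&
          any(objectives[p, ] > objectives[q, ])) {
        dominated_by[[p]] <- c(dominated_by[[p]], q)
      } else if (all(objectives[q, ] >= objectives[p, ]) &&
                 any(objectives[q, ] > objectives[p, ])) {
        n_dom[p] <- n_dom[p] + 1L
      }
    }
  }
  front <- integer(n)
  current <- which(n_dom == 0L)
  f <- 1L
  while (length(current) > 0) {
    front[current] <- f
    nxt <- integer(0)
    for (p in current) {
      for (q in dominated_by[[p]]) {
        n_dom[q] <- n_dom[q] - 1L
        if (n_dom[q] == 0L) nxt <- c(nxt, q)
      }
    }
    current <- nxt
    f <- f + 1L
  }
  front
}

#' Crowding distance within one front
#'
#' Boundary individuals on each objective get infinite distance;
#' interior individuals accumulate the normalized gap between their
#' neighbors, per objective. Used to spread selection pressure along a
#' front.
#'
#' @param objectives Numeric matrix for the members of one front.
#' @return Numeric vector of crowding distances.
#' @export
crowding_distance <- function(objectives) {
  n <- nrow(objectives)
  if (n == 0) return(numeric(0))
  d <- rep(0, n)
  for (m in seq_len(ncol(objectives))) {
    o <- objectives[, m]
    ord <- order(o)
    d[ord[c(1, n)]] <- Inf
    span <- o[ord[n]] - o[ord[1]]
    if (n > 2 && span > 0)
      d[ord[2:(n - 1)]] <- d[ord[2:(n - 1)]] +
        (o[ord[3:n]] - o[ord[1:(n - 2)]]) / span
  }
  d
}

#' Behavioral novelty
#'
#' The mean Euclidean distance from an individual's behavior
#' descriptor to its `k` nearest neighbors in the union of the archive
#' and the current population (itself excluded). When fewer than `k`
#' others exist, the mean is over the whole pool.
#'
#' @param descriptor Numeric behavior descriptor.
#' @param pool Matrix of descriptors (one per row), excluding the
#'   individual itself.
#' @param k Neighborhood size.
#' @return Non-negative novelty score (0 for an empty pool).
#' @export
novelty <- function(descriptor, pool, k = 15) {
  if (is.null(pool) || nrow(pool) == 0) return(0)
  if (ncol(pool) != length(descriptor))
    stop("descriptor length mismatch", call. = FALSE)
  d <- sqrt(colSums((t(pool) - descriptor)^2))
  mean(sort(d)[seq_len(min(k, length(d)))])
}

#' Encoding interfaces for the evolutionary loop
#'
#' Each encoding bundles three closures: `init()` draws a random
#' first-generation genotype, `mutate(genotype)` applies the
#' encoding's variation, and `develop(genotype)` maps it to a
#' `plastic_network` (possibly raising a classed development error
#' that the loop converts to minimal fitness).
#'
#' @param io Input/output specification for the task (10 inputs, 4
#'   outputs by default).
#' @param rates A [mutation_rates()].
#' @param lambda,eta Network simulation parameters.
#' @return A list of class `encoding` with fields `name`, `init`,
#'   `mutate`, `develop`.
#' @export
encoding_direct <- function(io = list(n_in = 10, n_out = 4),
                            rates = mutation_rates(),
                            lambda = 5, eta = 0.1) {
  structure(list(
    name = "direct",
    init = function() random_init_direct(io, type = "network"),
    mutate = function(g) mutate_direct(g, rates),
    develop = function(g) develop_direct(g, lambda = lambda, eta = eta)),
    class = "encoding")
}

#' @rdname encoding_direct
#' @param config Encoding-specific configuration ([map_config()] or
#'   [hnn_config()]).
#' @export
encoding_map <- function(config = map_config(), rates = mutation_rates(),
                         lambda = 5, eta = 0.1) {
  structure(list(
    name = "map",
    init = function() random_init_map(),
    mutate = function(g) mutate_map(g, rates),
    develop = function(g) develop_map(g, config, lambda = lambda, eta = eta)),
    class = "encoding")
}

#' @rdname encoding_direct
#' @param substrate A [default_substrate()].
#' @export
encoding_hnn <- function(substrate = default_substrate(),
                         config = hnn_config(), rates = mutation_rates(),
                         lambda = 5, eta = 0.1) {
  structure(list(
    name = "hnn",
    init = function() random_init_hnn(),
    mutate = function(g) mutate_hnn(g, rates),
    develop = function(g) develop_hnn(g, substrate, config,
                                      lambda = lambda, eta = eta)),
    class = "encoding")
}

#' Evolution configuration
#'
#' @param pop_size Population size (even, at least 4). The study-scale
#'   value is 400; desk-scale work uses 100.
#' @param generations Generation cap; the study-scale value is 4000.
#' @param k Novelty neighborhood size.
#' @param stop_on_perfect Stop as soon as the best individual reaches
#'   perfect fitness on the evolutionary training set?
#' @param seed Base seed; per-individual evaluation seeds are derived
#'   from (seed, generation, index) so any evaluation can be replayed.
#' @return A list of class `evolution_config`.
#' @export
evolution_config <- function(pop_size = 400, generations = 4000,
                             k = 15, stop_on_perfect = TRUE, seed = 1) {
  stopifnot(pop_size >= 4, pop_size %% 2 == 0, generations >= 1, k >= 1)
  structure(list(pop_size = pop_size, generations = generations,
                 k = k, stop_on_perfect = stop_on_perfect, seed = seed),
            class = "evolution_config")
}

# internal: deterministic per-evaluation seed below 2^31
derive_seed <- function(seed, gen, idx) {
  (as.numeric(seed) * 48271 + gen * 10007 + idx * 101) %% 2147483629 + 1
}

# internal: develop + evaluate one genotype; development or evaluation
# errors yield minimal fitness and a zero descriptor
evaluate_genotype <- function(genotype, enc, sets, config, eval_seed) {
  desc_len <- config$n_stimuli * config$n_actions * nrow(sets)
  tryCatch({
    net <- enc$develop(genotype)
    ev <- withr::with_seed(eval_seed,
                           evaluate_fitness(net, sets, config))
    list(fitness = ev$fitness, set_fitness = ev$set_fitness,
         descriptor = ev$descriptor, ok = TRUE)
  }, plastevo_development_error = function(e) {
    list(fitness = 0, set_fitness = 0,
         descriptor = rep(0, desc_len), ok = FALSE)
  }, plastevo_cppn_cycle = function(e) {
    list(fitness = 0, set_fitness = 0,
         descriptor = rep(0, desc_len), ok = FALSE)
  })
}

# internal: binary tournament on (front rank, crowding distance)
tournament_pick <- function(rank, crowd) {
  ij <- sample.int(length(rank), 2, replace = TRUE)
  i <- ij[1]; j <- ij[2]
  if (rank[i] < rank[j]) return(i)
  if (rank[j] < rank[i]) return(j)
  if (crowd[i] > crowd[j]) return(i)
  if (crowd[j] > crowd[i]) return(j)
  ij[sample.int(2, 1)]
}

#' Evolve plastic networks on the conditioning task
#'
#' Mutation-only NSGA-II over two maximized objectives: lifetime
#' learning fitness on the evolutionary training set (the
#' association-level average, the finer gradient) and behavioral
#' novelty. Parents are chosen by binary tournament on (front rank,
#' crowding distance); survivors by mu+lambda non-dominated truncation.
#' One uniformly chosen offspring descriptor is appended to the
#' novelty archive each generation. Each individual is evaluated once,
#' with a reproducible seed derived from (run seed, generation,
#' index). The run stops at the generation cap or as soon as some
#' individual attains perfect fitness; the champion is the individual
#' with the best fitness, novelty ignored.
#'
#' @param encoding An [encoding_direct()], [encoding_map()] or
#'   [encoding_hnn()].
#' @param sets Evolutionary training set: integer matrix of
#'   association sets (see [sample_training_set()]).
#' @param config An [evolution_config()].
#' @param task A [task_config()].
#' @param verbose Print a progress line every 25 generations?
#' @return An object of class `evolution_result`: `champion` (list
#'   with `genotype`, `network`, `fitness`, `set_fitness`,
#'   `descriptor`), `history` (one tibble row per generation),
#'   `population`, `archive_size`, `generations`, `converged`.
#' @export
evolve <- function(encoding, sets, config = evolution_config(),
                   task = task_config(), verbose = FALSE) {
  set.seed(config$seed)
  n <- config$pop_size
  genotypes <- purrr::map(seq_len(n), function(i) encoding$init())
  evals <- purrr::map(seq_len(n), function(i)
    evaluate_genotype(genotypes[[i]], encoding, sets, task,
                      derive_seed(config$seed, 0, i)))
  fitness <- purrr::map_dbl(evals, "fitness")
  descriptors <- do.call(rbind, purrr::map(evals, "descriptor"))
  archive <- NULL
  history <- vector("list", config$generations + 1)
  converged <- FALSE
  gen <- 0L

  record <- function(gen, fitness, nov) {
    tibble::tibble(generation = gen, best_fitness = max(fitness),
                   mean_fitness = mean(fitness),
                   best_novelty = max(nov),
                   archive_size = if (is.null(archive)) 0L else nrow(archive))
  }

  pool_novelty <- function(descriptors) {
    pool <- rbind(archive, descriptors)
    vapply(seq_len(nrow(descriptors)), function(i)
      novelty(descriptors[i, ], pool[-(nrow(pool) - nrow(descriptors) + i), ,
                                     drop = FALSE], config$k),
      numeric(1))
  }

  nov <- pool_novelty(descriptors)
  history[[1]] <- record(0L, fitness, nov)
  if (config$stop_on_perfect && max(fitness) >= 1) converged <- TRUE

  while (!converged && gen < config$generations) {
    gen <- gen + 1L
    obj <- cbind(fitness, nov)
    rank <- fast_nondominated_sort(obj)
    crowd <- rep(0, n)
    for (f in unique(rank)) {
      idx <- which(rank == f)
      crowd[idx] <- crowding_distance(obj[idx, , drop = FALSE])
    }
    off_geno <- purrr::map(seq_len(n), function(i)
      encoding$mutate(genotypes[[tournament_pick(rank, crowd)]]))
    off_eval <- purrr::map(seq_len(n), function(i)
      evaluate_genotype(off_geno[[i]], encoding, sets, task,
                        derive_seed(config$seed, gen, i)))
    off_fit <- purrr::map_dbl(off_eval, "fitness")
    off_desc <- do.call(rbind, purrr::map(off_eval, "descriptor"))
    archive <- rbind(archive, off_desc[sample.int(n, 1), , drop = FALSE])

    all_geno <- c(genotypes, off_geno)
    all_fit <- c(fitness, off_fit)
    all_desc <- rbind(descriptors, off_desc)
    all_nov <- pool_novelty(all_desc)
    all_obj <- cbind(all_fit, all_nov)
    all_rank <- fast_nondominated_sort(all_obj)
    keep <- integer(0)
    for (f in sort(unique(all_rank))) {
      idx <- which(all_rank == f)
      if (length(keep) + length(idx) <= n) {
        keep <- c(keep, idx)
      } else {
        cd <- crowding_distance(all_obj[idx, , drop = FALSE])
        keep <- c(keep, idx[order(-cd)][seq_len(n - length(keep))])
        break
      }
    }
    genotypes <- all_geno[keep]
    fitness <- all_fit[keep]
    descriptors <- all_desc[keep, , drop = FALSE]
    nov <- all_nov[keep]
    history[[gen + 1]] <- record(gen, fitness, nov)
    if (verbose && gen %% 25 == 0)
      message(sprintf("gen %d: best %.3f mean %.3f", gen,
                      max(fitness), mean(fitness)))
    if (config$stop_on_perfect && max(fitness) >= 1) converged <- TRUE
  }

  best <- which.max(fitness)
  champion_net <- tryCatch(encoding$develop(genotypes[[best]]),
                           error = function(e) NULL)
  structure(list(
    champion = list(genotype = genotypes[[best]], network = champion_net,
                    fitness = fitness[best],
                    descriptor = descriptors[best, ]),
    history = dplyr::bind_rows(history),
    population = list(genotypes = genotypes, fitness = fitness,
                      novelty = nov),
    archive_size = if (is.null(archive)) 0L else nrow(archive),
    generations = gen,
    converged = converged,
    encoding = encoding$name,
    sets = sets),
    class = "evolution_result")
}

#' @export
print.evolution_result <- function(x, ...) {
  cat(sprintf(
    "<evolution_result> %s encoding, %d generations%s, champion fitness %.3f\n",
    x$encoding, x$generations,
    if (x$converged) " (converged)" else "", x$champion$fitness))
  invisible(x)
}
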