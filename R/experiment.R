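#' Scale presets for the experimental series
#'
#' `"full"` matches the study scale (population 400, up to 4000
#' generations, training-set sizes 1 to 7) and needs cluster-class
#' compute; `"desk"` (population 100, cap 500, sizes 1 to 3, 5
#' replicates) runs a qualitative echo on a workstation.
#'
#' @param preset `"desk"` or `"full"`.
#' @return A list with `pop_size`, `generations`, `n_train`,
#'   `replicates`.
#' @export
scale_preset <- function(preset = c("desk", "full")) {
  preset <- match.arg(preset)
  if (preset == "full")
    list(pop_size = 400, generations = 4000, n_train = 1:7, replicates = 20)
  else
    list(pop_size = 100, generations = 500, n_train = 1:3, replicates = 5)
}

# internal: encoding constructor by name
encoding_by_name <- function(name, rates = mutation_rates()) {
  switch(name,
         direct = encoding_direct(rates = rates),
         map = encoding_map(rates = rates),
         hnn = encoding_hnn(rates = rates),
         stop("unknown encoding: ", name, call. = FALSE))
}

#' Run one evolution experiment cell
#'
#' Samples an evolutionary training set of `n_train` association sets,
#' evolves networks with the requested encoding, then measures the
#' champion: its GLA score over the full global training set and the
#' automorphism count of its developed, pruned network. All randomness
#' derives from `seed`, so identical calls give identical records.
#'
#' @param encoding Encoding name: `"direct"`, `"map"` or `"hnn"`.
#' @param n_train Evolutionary training-set size (1 to 7).
#' @param seed Integer seed for the whole cell.
#' @param pop_size,generations Evolution scale.
#' @param task A [task_config()].
#' @param gla_repeats Lifetimes per set in the GLA measurement.
#' @param keep_network Keep the champion network in the record (as a
#'   list column)?
#' @param verbose Progress output.
#' @return A one-row tibble: encoding, n_train, seed, generations
#'   used, convergence flag, champion fitness, GLA scores (set- and
#'   association-level), automorphism count, network size, and the
#'   champion network.
#' @export
run_experiment <- function(encoding = "map", n_train = 1, seed = 1,
                           pop_size = 100, generations = 500,
                           task = task_config(), gla_repeats = 3,
                           keep_network = TRUE, verbose = FALSE) {
  enc <- encoding_by_name(encoding)
  withr::with_seed(seed, {
    global <- enumerate_global_set(task$n_stimuli, task$n_actions)
    sets <- sample_training_set(global, n_train)
  })
  res <- evolve(enc, sets,
                evolution_config(pop_size = pop_size,
                                 generations = generations,
                                 seed = seed),
                task = task, verbose = verbose)
  net <- res$champion$network
  gla <- if (is.null(net)) NULL else
    withr::with_seed(seed + 1,
                     gla_score(net, task, n_repeats = gla_repeats))
  aut <- if (is.null(net)) NA_real_ else count_automorphisms(net)
  tibble::tibble(
    encoding = encoding, n_train = n_train, seed = seed,
    generations = res$generations, converged = res$converged,
    fitness = res$champion$fitness,
    gla_set = if (is.null(gla)) NA_real_ else gla$set_level,
    gla_assoc = if (is.null(gla)) NA_real_ else gla$association_level,
    automorphisms = aut,
    n_neurons = if (is.null(net)) NA_integer_ else nrow(net$neurons),
    n_connections = if (is.null(net)) NA_integer_ else
      nrow(net$connections),
    network = if (keep_network) list(net) else list(NULL))
}

#' Run a series of experiments over encodings and training-set sizes
#'
#' The grid encodings x n_train x replicates, each cell one
#' [run_experiment()] with a seed derived from `base_seed`. Failed
#' cells are recorded with `NA` measurements rather than aborting the
#' series.
#'
#' @param encodings Character vector of encoding names.
#' @param n_train Integer vector of training-set sizes.
#' @param replicates Replicates per cell.
#' @param pop_size,generations Evolution scale (see [scale_preset()]).
#' @param task A [task_config()].
#' @param base_seed Base seed; cell seeds are derived deterministically.
#' @param gla_repeats Lifetimes per set in the GLA measurement.
#' @param verbose Progress output.
#' @return A tibble of run records, class `plastevo_series`.
#' @export
run_series <- function(encodings = c("direct", "map", "hnn"),
                       n_train = 1:3, replicates = 5,
                       pop_size = 100, generations = 500,
                       task = task_config(), base_seed = 1,
                       gla_repeats = 3, verbose = FALSE) {
  grid <- tidyr::expand_grid(encoding = encodings, n_train = n_train,
                             replicate = seq_len(replicates))
  grid$seed <- base_seed + 1000 * (seq_len(nrow(grid)) - 1)
  rows <- purrr::pmap(grid, function(encoding, n_train, replicate, seed) {
    if (verbose)
      message(sprintf("series: %s n_train=%d replicate=%d",
                      encoding, n_train, replicate))
    rec <- tryCatch(
      run_experiment(encoding, n_train, seed, pop_size, generations,
                     task, gla_repeats, keep_network = FALSE),
      error = function(e) {
        warning("cell failed: ", conditionMessage(e), call. = FALSE)
        tibble::tibble(encoding = encoding, n_train = n_train,
                       seed = seed, generations = NA_integer_,
                       converged = NA, fitness = NA_real_,
                       gla_set = NA_real_, gla_assoc = NA_real_,
                       automorphisms = NA_real_,
                       n_neurons = NA_integer_,
                       n_connections = NA_integer_,
                       network = list(NULL))
      })
    rec$replicate <- replicate
    rec
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("plastevo_series", class(out))
  out
}

#' Aggregate a series of run records
#'
#' Per (encoding, n_train) cell: median and quartiles of the
#' set-level GLA score and champion fitness, and the fraction of
#' champions whose automorphism count exceeds 1, exceeds 3, and
#' reaches 10 — the regularity summaries used to compare encodings.
#'
#' @param records A tibble from [run_series()].
#' @return A tibble with one row per cell.
#' @export
summarize_series <- function(records) {
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(records), .data$encoding,
                    .data$n_train),
    n_runs = dplyr::n(),
    fitness_median = stats::median(.data$fitness, na.rm = TRUE),
    gla_median = stats::median(.data$gla_set, na.rm = TRUE),
    gla_q1 = stats::quantile(.data$gla_set, 0.25, na.rm = TRUE,
                             names = FALSE),
    gla_q3 = stats::quantile(.data$gla_set, 0.75, na.rm = TRUE,
                             names = FALSE),
    aut_median = stats::median(.data$automorphisms, na.rm = TRUE),
    frac_aut_gt1 = mean(.data$automorphisms > 1, na.rm = TRUE),
    frac_aut_gt3 = mean(.data$automorphisms > 3, na.rm = TRUE),
    frac_aut_ge10 = mean(.data$automorphisms >= 10, na.rm = TRUE),
    .groups = "drop")
}

#' Compare two series cells with a Mann-Whitney U test
#'
#' Convenience wrapper around [stats::wilcox.test()] on a chosen
#' measurement between two encodings (optionally within one `n_train`
#' cell).
#'
#' @param records A tibble from [run_series()].
#' @param measure Column to compare (default `"gla_set"`).
#' @param encodings The two encoding names to compare.
#' @param n_train Optional training-set size to restrict to.
#' @return A tidy one-row tibble with the U statistic and p-value.
#' @export
compare_series <- function(records, measure = "gla_set",
                           encodings = c("map", "direct"),
                           n_train = NULL) {
  d <- tibble::as_tibble(records)
  if (!is.null(n_train)) d <- d[d$n_train %in% n_train, ]
  x <- d[[measure]][d$encoding == encodings[1]]
  y <- d[[measure]][d$encoding == encodings[2]]
  ht <- stats::wilcox.test(x, y, exact = FALSE)
  tibble::tibble(measure = measure,
                 encoding_x = encodings[1], encoding_y = encodings[2],
                 n_x = length(x), n_y = length(y),
                 statistic = unname(ht$statistic),
                 p_value = ht$p.value)
}

#' Write run records to CSV
#'
#' Drops the list column holding champion networks; archive those
#' separately with [write_network_json()].
#'
#' @param records A tibble from [run_series()].
#' @param path File path.
#' @export
write_series_csv <- function(records, path) {
  flat <- tibble::as_tibble(records)
  flat$network <- NULL
  utils::write.csv(flat, path, row.names = FALSE)
  invisible(path)
}
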