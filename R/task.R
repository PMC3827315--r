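#' Task configuration for the Skinner-box conditioning task
#'
#' The task has 4 stimuli (lights) and 4 actions (levers). A lifetime
#' consists of `n_episodes` learning episodes; each episode presents the
#' 4 stimulus-action associations of one association set in fixed
#' order. An association presentation has two phases of
#' `n_steps_per_phase` synchronous simulation steps: stimulus only,
#' then stimulus + reward + action feedback, with Hebbian learning
#' active throughout.
#'
#' @param n_stimuli,n_actions Numbers of stimuli and actions.
#' @param n_episodes Learning episodes per association set (lifetime).
#' @param n_steps_per_phase Simulation steps per phase; 5 is enough for
#'   a signal to travel from inputs to outputs.
#' @param tau Softmax temperature for action selection.
#' @param reward Reward magnitude credited per correct association.
#' @return A list of class `task_config`.
#' @export
task_config <- function(n_stimuli = 4, n_actions = 4, n_episodes = 90,
                        n_steps_per_phase = 5, tau = 0.1, reward = 1) {
  stopifnot(n_stimuli >= 1, n_actions >= 1, n_episodes >= 1,
            n_steps_per_phase >= 1, tau > 0, reward > 0)
  structure(list(n_stimuli = n_stimuli, n_actions = n_actions,
                 n_episodes = n_episodes,
                 n_steps_per_phase = n_steps_per_phase,
                 tau = tau, reward = reward),
            class = "task_config")
}

#' Enumerate the global training set
#'
#' An association set assigns exactly one correct action to each
#' stimulus; the global training set is the set of all
#' `n_actions ^ n_stimuli` such assignments (256 for the 4 x 4 task).
#' Sets are enumerated in lexicographic order (stimulus 1 most
#' significant), duplicate-free.
#'
#' @param n_stimuli,n_actions Positive integers.
#' @return An integer matrix of class `global_training_set`, one row
#'   per association set, column `s` holding the 1-based correct action
#'   for stimulus `s`.
#' @export
#' @examples
#' nrow(enumerate_global_set(4, 4)) # 256
enumerate_global_set <- function(n_stimuli = 4, n_actions = 4) {
  if (n_stimuli < 1 || n_actions < 1)
    stop("n_stimuli and n_actions must be positive", call. = FALSE)
  cols <- rev(lapply(seq_len(n_stimuli), function(s) seq_len(n_actions)))
  g <- as.matrix(rev(expand.grid(cols, KEEP.OUT.ATTRS = FALSE)))
  dimnames(g) <- list(NULL, paste0("stimulus_", seq_len(n_stimuli)))
  structure(g, class = c("global_training_set", class(g)))
}

#' Sample an evolutionary training set
#'
#' Draws `n_train` distinct association sets from the global set; in an
#' evolution run this subset is drawn once and stays fixed for the
#' whole run. Uses R's global RNG.
#'
#' @param global A `global_training_set` (or any matrix of sets).
#' @param n_train Number of sets, `1 <= n_train <= nrow(global)`.
#' @return Integer matrix of `n_train` association sets.
#' @export
sample_training_set <- function(global, n_train) {
  if (n_train < 1 || n_train > nrow(global))
    stop("n_train must be between 1 and nrow(global)", call. = FALSE)
  sel <- sample.int(nrow(global), n_train)
  m <- global[sel, , drop = FALSE]
  class(m) <- "matrix"
  m
}

#' Softmax action-selection probabilities
#'
#' `p_i = exp(o_i / tau) / sum_k exp(o_k / tau)`. Low temperatures
#' approach a max function; high temperatures approach uniform choice.
#'
#' @param outputs Numeric vector of output activations.
#' @param tau Positive temperature.
#' @return Probability vector summing to one.
#' @export
softmax_probs <- function(outputs, tau = 0.1) {
  if (tau <= 0) stop("tau must be positive", call. = FALSE)
  z <- outputs / tau
  e <- exp(z - max(z))
  e / sum(e)
}

#' Sample an action through the softmax
#'
#' Draws one action index with the [softmax_probs()] distribution,
#' consuming a single uniform deviate (inverse-CDF sampling) from R's
#' global RNG.
#'
#' @inheritParams softmax_probs
#' @return 1-based action index.
#' @export
softmax_select <- function(outputs, tau = 0.1) {
  p <- softmax_probs(outputs, tau)
  u <- stats::runif(1)
  sum(cumsum(p) < u) + 1L
}

#' Encode the input vector presented to a network
#'
#' The network has 10 input lines: a one-hot stimulus block (4), a
#' positive- and a negative-reward line, and a one-hot feedback block
#' (4) echoing the softmax-chosen action back to the input layer.
#' Absent fields are zero.
#'
#' @param stimulus 1-based stimulus index.
#' @param action 1-based chosen action for the feedback block, or
#'   `NULL` during the stimulus-only phase.
#' @param reward `"none"`, `"pos"` or `"neg"`.
#' @param config A [task_config()].
#' @return Numeric vector of length `n_stimuli + 2 + n_actions`.
#' @export
#' @examples
#' encode_input_vector(1)                        # stimulus only
#' encode_input_vector(1, action = 3, reward = "neg")
encode_input_vector <- function(stimulus, action = NULL,
                                reward = c("none", "pos", "neg"),
                                config = task_config()) {
  reward <- match.arg(reward)
  ns <- config$n_stimuli; na <- config$n_actions
  if (stimulus < 1 || stimulus > ns)
    stop("invalid stimulus index", call. = FALSE)
  stim <- rep(0, ns); stim[stimulus] <- 1
  rew <- c(pos = 0, neg = 0)
  if (reward == "pos") rew["pos"] <- config$reward
  if (reward == "neg") rew["neg"] <- config$reward
  fb <- rep(0, na)
  if (!is.null(action)) {
    if (action < 1 || action > na)
      stop("invalid action index", call. = FALSE)
    fb[action] <- 1
  }
  unname(c(stim, rew, fb))
}

#' An agent that always answers correctly
#'
#' A non-neural stand-in that bypasses the network and the softmax and
#' returns the correct action for every stimulus. Used to calibrate the
#' upper bound of the fitness function and the GLA score.
#'
#' @return An object of class `oracle_agent`.
#' @export
oracle_agent <- function() structure(list(), class = "oracle_agent")

# internal: lifetime evaluation of one association set, pure-R
# reference engine. Consumes R's RNG in the exact order of the C++
# engine: one uniform per plastic matrix entry (column-major) for the
# reset, then one uniform per softmax selection.
eval_set_r <- function(cm, actions, config, lambda, eta, w_max, learn = TRUE) {
  n <- cm$n
  Amag <- cm$Amag; Asgn <- cm$Asgn
  pl <- which(cm$P)                      # column-major order
  Amag[pl] <- stats::runif(length(pl), 0, w_max)
  o <- rep(0, n)
  is_in <- seq_len(n) %in% cm$input_idx
  ns <- config$n_stimuli
  n_in <- length(cm$input_idx)
  flags <- logical(ns)
  chosen_v <- integer(ns)
  descriptor <- numeric(ns * config$n_actions)
  run_phase <- function(invec) {
    o[cm$input_idx] <<- invec        # clamp before propagation
    for (t in seq_len(config$n_steps_per_phase)) {
      drive <- (Asgn * Amag) %*% o + cm$bias
      new_o <- sigmoid(lambda * drive)[, 1]
      m <- (cm$Msig %*% o)[, 1]
      new_o[cm$input_idx] <- invec
      o <<- new_o
      if (learn && length(pl) > 0) {
        hebb <- (eta * tanh(m) * o) %o% o   # [i, j] = eta*tanh(m_i)*o_i*o_j
        Amag[pl] <<- pmin(pmax(Amag[pl] + hebb[pl], 0), w_max)
      }
    }
  }
  make_in <- function(stimulus, action, rew) {
    if (n_in == ns + 2 + config$n_actions) {
      v <- rep(0, n_in); v[stimulus] <- 1
      if (rew > 0) v[ns + 1] <- config$reward
      if (rew < 0) v[ns + 2] <- config$reward
      if (!is.na(action)) v[ns + 2 + action] <- 1
    } else {                              # 9-line variant: one signed reward
      v <- rep(0, n_in); v[stimulus] <- 1
      v[ns + 1] <- rew * config$reward
      if (!is.na(action)) v[ns + 1 + action] <- 1
    }
    v
  }
  for (ep in seq_len(config$n_episodes)) {
    for (a in seq_len(ns)) {
      run_phase(make_in(a, NA, 0))
      out <- o[cm$output_idx]
      p <- softmax_probs(out, config$tau)
      u <- stats::runif(1)
      chosen <- sum(cumsum(p) < u) + 1L
      correct <- chosen == actions[a]
      run_phase(make_in(a, chosen, if (correct) 1 else -1))
      if (ep == config$n_episodes) {
        flags[a] <- correct
        chosen_v[a] <- chosen
        descriptor[(a - 1) * config$n_actions + seq_len(config$n_actions)] <- out
      }
    }
  }
  list(correct = flags, chosen = chosen_v, descriptor = descriptor, Amag = Amag)
}

# internal: dispatch one set evaluation to the C++ or R engine
eval_one_set <- function(cm, actions, config, params, engine) {
  if (engine == "cpp") {
    res <- eval_set_cpp(cm$Amag, cm$Asgn, cm$Msig, cm$P, cm$bias,
                        cm$input_idx, cm$output_idx,
                        as.integer(actions),
                        as.integer(config$n_episodes),
                        as.integer(config$n_steps_per_phase),
                        params$lambda, params$eta, params$w_max,
                        config$tau, config$reward, TRUE)
    res
  } else {
    eval_set_r(cm, actions, config, params$lambda, params$eta, params$w_max)
  }
}

#' Evaluate lifetime learning fitness on a training set
#'
#' For each association set: the plastic weights are randomized
#' ([reset_plastic_weights()] semantics), then the network lives
#' through `n_episodes` episodes. Each episode presents the four
#' associations in fixed stimulus order: clamp the stimulus and
#' simulate `n_steps_per_phase` steps with learning; select an action
#' by softmax over the four output activations; clamp stimulus +
#' reward (positive if correct, negative otherwise) + one-hot action
#' feedback and simulate another `n_steps_per_phase` learning steps.
#' On the last episode each association scores, and its four raw
#' (pre-softmax) outputs are appended to the behavior descriptor.
#'
#' Two granularities are reported: `fitness` is the association-level
#' average (fraction of the `4 * n_sets` last-episode presentations
#' answered correctly, each worth `reward / (4 * n_sets)` with
#' `reward = 1`) — the finer gradient used as the evolutionary
#' objective — and `set_fitness` is the fraction of sets with all four
#' associations correct, the granularity the GLA score uses.
#'
#' @param network A `plastic_network` with 10 (or 9, single signed
#'   reward line) input neurons and `n_actions` outputs, or an
#'   [oracle_agent()].
#' @param sets Integer matrix of association sets (rows), or a single
#'   set as a vector.
#' @param config A [task_config()].
#' @param engine `"cpp"` (compiled fast path) or `"r"` (reference
#'   implementation); both consume R's RNG identically.
#' @return A list of class `fitness_eval`: `fitness`, `set_fitness`,
#'   `success` (per-set logical), `correct` (set x association logical
#'   matrix), `chosen` (actions on the last episode), and `descriptor`
#'   (length `4 * n_actions * n_sets`).
#' @export
evaluate_fitness <- function(network, sets, config = task_config(),
                             engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  if (is.vector(sets)) sets <- matrix(sets, nrow = 1)
  if (nrow(sets) == 0) stop("empty training set", call. = FALSE)
  ns <- config$n_stimuli
  if (ncol(sets) != ns) stop("sets must have one action per stimulus", call. = FALSE)

  if (inherits(network, "oracle_agent")) {
    correct <- matrix(TRUE, nrow(sets), ns)
    desc <- numeric(0)
    for (i in seq_len(nrow(sets))) for (a in seq_len(ns)) {
      oh <- rep(0, config$n_actions); oh[sets[i, a]] <- 1
      desc <- c(desc, oh)
    }
    return(structure(list(fitness = 1, set_fitness = 1,
                          success = rep(TRUE, nrow(sets)),
                          correct = correct, chosen = sets,
                          descriptor = desc),
                     class = "fitness_eval"))
  }

  n_in <- sum(network$neurons$role == "input")
  if (!n_in %in% c(ns + 2 + config$n_actions, ns + 1 + config$n_actions))
    stop("network must have ", ns + 2 + config$n_actions,
         " (or ", ns + 1 + config$n_actions, ") input neurons", call. = FALSE)
  if (sum(network$neurons$role == "output") != config$n_actions)
    stop("network must have ", config$n_actions, " output neurons", call. = FALSE)

  cm <- compile_network(network)
  correct <- matrix(FALSE, nrow(sets), ns)
  chosen <- matrix(NA_integer_, nrow(sets), ns)
  desc <- vector("list", nrow(sets))
  for (i in seq_len(nrow(sets))) {
    res <- eval_one_set(cm, sets[i, ], config, network$params, engine)
    correct[i, ] <- res$correct
    chosen[i, ] <- res$chosen
    desc[[i]] <- res$descriptor
  }
  structure(list(fitness = mean(correct),
                 set_fitness = mean(apply(correct, 1, all)),
                 success = apply(correct, 1, all),
                 correct = correct, chosen = chosen,
                 descriptor = unlist(desc)),
            class = "fitness_eval")
}

#' General Learning Abilities (GLA) score
#'
#' Evaluates the fitness procedure on the *global* training set — all
#' 256 association sets for the 4 x 4 task — and reports the fraction
#' of sets fully learned (all four associations correct on the last
#' episode), averaged over `n_repeats` independent lifetimes per set to
#' tame softmax sampling noise. The association-level average is also
#' reported. Measures generalization of the learning ability beyond
#' the sets seen by evolution.
#'
#' @inheritParams evaluate_fitness
#' @param global Matrix of association sets; defaults to
#'   [enumerate_global_set()] for the task's dimensions.
#' @param n_repeats Independent evaluations to average.
#' @return List of class `gla_score`: `set_level`, `association_level`,
#'   `per_repeat` tibble, `n_sets`, `n_repeats`.
#' @export
gla_score <- function(network, config = task_config(), global = NULL,
                      n_repeats = 5, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  if (is.null(global))
    global <- enumerate_global_set(config$n_stimuli, config$n_actions)
  reps <- purrr::map(seq_len(n_repeats), function(r) {
    ev <- evaluate_fitness(network, unclass(global), config, engine)
    tibble::tibble(repeat_id = r, set_level = ev$set_fitness,
                   association_level = ev$fitness)
  })
  per_repeat <- dplyr::bind_rows(reps)
  structure(list(set_level = mean(per_repeat$set_level),
                 association_level = mean(per_repeat$association_level),
                 per_repeat = per_repeat,
                 n_sets = nrow(global), n_repeats = n_repeats),
            class = "gla_score")
}

#' @export
print.gla_score <- function(x, ...) {
  cat(sprintf(
    "<gla_score> set-level %.4f, association-level %.4f (%d sets x %d repeats)\n",
    x$set_level, x$association_level, x$n_sets, x$n_repeats))
  invisible(x)
}

#' Read and write association sets
#'
#' Two plain-text forms: JSON (a list of integer vectors) and a simple
#' table with one set per line, e.g. `1->3,2->1,3->4,4->2`.
#'
#' @param sets Integer matrix of association sets.
#' @param path File path.
#' @param format `"json"` or `"table"`.
#' @return `write_association_sets()` returns `path` invisibly;
#'   `read_association_sets()` returns the integer matrix.
#' @export
write_association_sets <- function(sets, path, format = c("json", "table")) {
  format <- match.arg(format)
  if (is.vector(sets)) sets <- matrix(sets, nrow = 1)
  if (format == "json") {
    jsonlite::write_json(apply(sets, 1, identity, simplify = FALSE),
                         path, auto_unbox = FALSE)
  } else {
    lines <- apply(sets, 1, function(s)
      paste(sprintf("%d->%d", seq_along(s), s), collapse = ","))
    writeLines(lines, path)
  }
  invisible(path)
}

#' @rdname write_association_sets
#' @export
read_association_sets <- function(path, format = c("json", "table")) {
  format <- match.arg(format)
  if (format == "json") {
    l <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.list(l)) l <- do.call(rbind, l)
    if (!is.matrix(l)) l <- matrix(l, nrow = 1)
    storage.mode(l) <- "integer"
    l
  } else {
    lines <- readLines(path)
    do.call(rbind, lapply(lines, function(ln) {
      parts <- strsplit(strsplit(ln, ",")[[1]], "->")
      acts <- vapply(parts, function(p) as.integer(p[2]), integer(1))
      stim <- vapply(parts, function(p) as.integer(p[1]), integer(1))
      acts[order(stim)]
    }))
  }
}
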