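#' The CPPN activation-function set
#'
#' Compositional pattern-producing networks compose sine, sigmoid,
#' Gaussian and linear nodes; the mix of periodic, saturating and
#' bell-shaped primitives is what lets a CPPN paint symmetric and
#' repetitive connectivity patterns over the substrate.
#'
#' @return Character vector of function names.
#' @export
cppn_function_set <- function() c("sine", "sigmoid", "gaussian", "linear")

cppn_apply_fun <- function(fun, x) {
  switch(fun,
         sine = sin(x),
         sigmoid = 1 / (1 + exp(-x)),
         gaussian = exp(-x^2),
         linear = x,
         stop("unknown CPPN function: ", fun, call. = FALSE))
}

#' Evaluate a CPPN
#'
#' Feed-forward evaluation in topological order: input nodes relay the
#' query values, every other node outputs `f(sum(sign * weight * value)
#' + bias)` with `f` its activation-function selector. A cycle in the
#' genotype raises a classed error (`plastevo_cppn_cycle`); the
#' evolutionary loop converts it into minimal fitness.
#'
#' @param g A CPPN-type `direct_genotype`.
#' @param inputs Numeric vector matching the declared input arity.
#' @return Numeric vector of the output-node values.
#' @export
cppn_eval <- function(g, inputs) {
  if (length(inputs) != g$io$n_in)
    stop("CPPN input arity mismatch", call. = FALSE)
  ids <- g$nodes$id
  n <- length(ids)
  idx <- stats::setNames(seq_len(n), ids)
  adj_from <- idx[g$edges$from]; adj_to <- idx[g$edges$to]
  indeg <- tabulate(adj_to, n)
  order <- integer(0)
  queue <- which(indeg == 0)
  indeg_w <- indeg
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    order <- c(order, v)
    for (e in which(adj_from == v)) {
      t <- adj_to[e]
      indeg_w[t] <- indeg_w[t] - 1
      if (indeg_w[t] == 0) queue <- c(queue, t)
    }
  }
  if (length(order) < n)
    rlang::abort("CPPN genotype contains a cycle",
                 class = "plastevo_cppn_cycle")
  val <- numeric(n)
  in_idx <- idx[g$nodes$id[g$nodes$role == "input"]]
  val[in_idx] <- inputs
  for (v in order) {
    if (v %in% in_idx) next
    ein <- which(adj_to == v)
    s <- g$nodes$bias[v] +
      sum(g$edges$sign[ein] * g$edges$weight[ein] * val[adj_from[ein]])
    val[v] <- cppn_apply_fun(g$nodes$fun[v], s)
  }
  val[idx[g$nodes$id[g$nodes$role == "output"]]]
}

#' Default 3D substrate for the conditioning task
#'
#' Input neurons sit on the plane `z = -1`, hidden neurons on `z = 0`,
#' output neurons on `z = +1`. Within each plane, neurons are evenly
#' spaced on `[-1, 1]` in `x`, grouped in `y` by semantic role:
#' stimulus lines at `y = 1`, reward lines at `y = 0`, feedback lines
#' at `y = -1`; hidden and output neurons at `y = 0`. The 10-input
#' layout matches the task's input vector (4 stimuli + 2 rewards + 4
#' feedback); `n_inputs = 9` gives the strict layout with a single
#' signed reward line.
#'
#' @param n_inputs 10 (default) or 9.
#' @param n_hidden Number of hidden substrate neurons.
#' @param n_outputs Number of output substrate neurons.
#' @return A tibble of class `substrate` with columns `id`, `role`,
#'   `group`, `x`, `y`, `z`.
#' @export
default_substrate <- function(n_inputs = 10, n_hidden = 5, n_outputs = 4) {
  if (!n_inputs %in% c(9, 10))
    stop("n_inputs must be 9 or 10", call. = FALSE)
  spread <- function(k) if (k == 1) 0 else seq(-1, 1, length.out = k)
  n_rew <- n_inputs - 8
  inputs <- tibble::tibble(
    id = c(paste0("in_stim_", 1:4),
           if (n_rew == 2) c("in_rpos", "in_rneg") else "in_reward",
           paste0("in_fb_", 1:4)),
    role = "input",
    group = c(rep("stimulus", 4), rep("reward", n_rew), rep("feedback", 4)),
    x = c(spread(4), spread(n_rew), spread(4)),
    y = c(rep(1, 4), rep(0, n_rew), rep(-1, 4)),
    z = -1)
  hidden <- tibble::tibble(
    id = paste0("hid_", seq_len(n_hidden)), role = "hidden",
    group = "hidden", x = spread(n_hidden), y = 0, z = 0)
  outputs <- tibble::tibble(
    id = paste0("out_", seq_len(n_outputs)), role = "output",
    group = "action", x = spread(n_outputs), y = 0, z = 1)
  structure(dplyr::bind_rows(inputs, hidden, outputs),
            class = c("substrate", class(inputs)))
}

#' HNN development configuration
#'
#' @param leo_threshold A connection is created iff the connection
#'   CPPN's link-expression output (LEO) exceeds this threshold.
#' @param modulatory_cutoff A hidden neuron is modulatory iff the node
#'   CPPN's kind output is below this cutoff (inputs and outputs are
#'   always standard).
#' @param w_max Developed magnitudes are `|clipped weight| * w_max`
#'   with the raw weight output clipped to `[-1, 1]`; the sign of the
#'   raw output gives the connection polarity.
#' @param bias_max Developed biases are the clipped bias output scaled
#'   to `[-bias_max, bias_max]`.
#' @return A list of class `hnn_config`.
#' @export
hnn_config <- function(leo_threshold = 0.5, modulatory_cutoff = 0.4,
                       w_max = 2, bias_max = 2) {
  stopifnot(modulatory_cutoff > 0, modulatory_cutoff < 1)
  structure(list(leo_threshold = leo_threshold,
                 modulatory_cutoff = modulatory_cutoff,
                 w_max = w_max, bias_max = bias_max),
            class = "hnn_config")
}

#' Create a random pair of first-generation CPPNs
#'
#' The connection CPPN takes the two endpoint coordinates plus a
#' constant bias input (arity 7) and returns (LEO, weight); the node
#' CPPN takes one coordinate plus the bias input (arity 4) and returns
#' (bias, kind).
#'
#' @return A list of class `hnn_genotype` with elements `conn` and
#'   `node`, each a CPPN-type `direct_genotype`.
#' @export
random_init_hnn <- function() {
  structure(list(
    conn = random_init_direct(list(n_in = 7, n_out = 2,
                                   input_labels = c("x1", "y1", "z1",
                                                    "x2", "y2", "z2", "b"),
                                   output_labels = c("leo", "weight")),
                              type = "cppn"),
    node = random_init_direct(list(n_in = 4, n_out = 2,
                                   input_labels = c("x", "y", "z", "b"),
                                   output_labels = c("bias", "kind")),
                              type = "cppn")),
    class = "hnn_genotype")
}

#' Develop a CPPN pair over a substrate into a plastic network
#'
#' For every ordered neuron pair allowed by the layering (input to
#' hidden, input to output, hidden to hidden including self and
#' recurrent pairs, hidden to output) the connection CPPN is queried
#' with the six endpoint coordinates (plus the constant bias input): a
#' connection is created iff the LEO output exceeds `leo_threshold`,
#' with polarity the sign of the weight output and magnitude
#' `|weight output|` (clipped to `[-1, 1]`) scaled to `[0, w_max]`.
#' The node CPPN is queried per neuron for its bias and, for hidden
#' neurons, its kind: modulatory iff the kind output is below
#' `modulatory_cutoff`. Development is deterministic.
#'
#' @param genotype An `hnn_genotype` (or pass `conn` and `node`
#'   CPPNs via `genotype = list(conn = ..., node = ...)`).
#' @param substrate A [default_substrate()].
#' @param config An [hnn_config()].
#' @param lambda,eta Network simulation parameters.
#' @return A `plastic_network`.
#' @export
develop_hnn <- function(genotype, substrate = default_substrate(),
                        config = hnn_config(), lambda = 5, eta = 0.1) {
  conn <- genotype$conn; node <- genotype$node
  if (conn$io$n_in != 7 || conn$io$n_out != 2)
    stop("connection CPPN must have arity 7 -> 2", call. = FALSE)
  if (node$io$n_in != 4 || node$io$n_out != 2)
    stop("node CPPN must have arity 4 -> 2", call. = FALSE)
  s <- substrate
  clip1 <- function(x) pmin(pmax(x, -1), 1)
  nres <- lapply(seq_len(nrow(s)), function(i)
    cppn_eval(node, c(s$x[i], s$y[i], s$z[i], 1)))
  neurons <- tibble::tibble(
    id = s$id, role = s$role,
    kind = ifelse(
      s$role == "hidden" &
        vapply(nres, function(v) v[2], numeric(1)) < config$modulatory_cutoff,
      "modulatory", "standard"),
    bias = ifelse(s$role == "input", 0,
                  clip1(vapply(nres, function(v) v[1], numeric(1))) *
                    config$bias_max),
    label = s$id)
  allowed <- tidyr::expand_grid(i = seq_len(nrow(s)), j = seq_len(nrow(s)))
  allowed <- allowed[s$role[allowed$j] != "input" &
                     s$role[allowed$i] != "output" &
                     !(s$role[allowed$i] == "input" & allowed$i == allowed$j), ]
  res <- Map(function(i, j) {
    out <- cppn_eval(conn, c(s$x[i], s$y[i], s$z[i],
                             s$x[j], s$y[j], s$z[j], 1))
    if (out[1] <= config$leo_threshold) return(NULL)
    w <- clip1(out[2])
    tibble::tibble(from = s$id[i], to = s$id[j],
                   sign = if (w < 0) -1 else 1,
                   weight = abs(w) * config$w_max)
  }, allowed$i, allowed$j)
  connections <- dplyr::bind_rows(res)
  plastic_network(neurons, connections, lambda = lambda, eta = eta,
                  w_min = 0, w_max = config$w_max)
}

#' Mutate an HNN genotype
#'
#' Both CPPNs are mutated independently with the direct encoding's
#' operators.
#'
#' @param g An `hnn_genotype`.
#' @param rates A [mutation_rates()].
#' @return The mutated genotype.
#' @export
mutate_hnn <- function(g, rates = mutation_rates()) {
  g$conn <- mutate_direct(g$conn, rates)
  g$node <- mutate_direct(g$node, rates)
  g
}
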