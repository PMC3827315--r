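#' Mutation rates for graph genotypes
#'
#' Seven operators are applied independently in a fixed order: add a
#' connection between two random neurons, delete a random connection,
#' move one endpoint of a random connection, add a neuron by splitting
#' an existing connection (the split connection's weight is kept on
#' both halves), delete a random hidden neuron with its connections,
#' polynomial mutation of each connection weight (probability
#' `p_weight` per connection), and mutation of each neuron's intrinsic
#' parameters (probability `p_param` per neuron). Crossover is not
#' used.
#'
#' @param p_add_conn,p_del_conn,p_move_conn Probabilities of the three
#'   connection-level structural operators.
#' @param p_add_neuron,p_del_neuron Probabilities of the neuron-level
#'   structural operators.
#' @param p_weight Per-connection probability of weight mutation (and,
#'   for network genotypes, independently of a sign flip).
#' @param p_param Per-neuron probability of intrinsic-parameter
#'   mutation (bias; kind flip for hidden neurons of network
#'   genotypes; activation-function change for CPPN nodes).
#' @param eta_m Distribution index of the polynomial mutation.
#' @return A list of class `mutation_rates`.
#' @export
mutation_rates <- function(p_add_conn = 0.1, p_del_conn = 0.1,
                           p_move_conn = 0.1, p_add_neuron = 0.05,
                           p_del_neuron = 0.05, p_weight = 0.1,
                           p_param = 0.1, eta_m = 15) {
  r <- list(p_add_conn = p_add_conn, p_del_conn = p_del_conn,
            p_move_conn = p_move_conn, p_add_neuron = p_add_neuron,
            p_del_neuron = p_del_neuron, p_weight = p_weight,
            p_param = p_param, eta_m = eta_m)
  stopifnot(all(unlist(r[1:7]) >= 0), all(unlist(r[1:7]) <= 1), eta_m > 0)
  structure(r, class = "mutation_rates")
}

#' Deb's polynomial mutation
#'
#' Bounded real-valued perturbation: with distribution index `eta_m`,
#' a deviate `u ~ U(0, 1)` yields
#' `delta = (2u)^(1/(eta_m+1)) - 1` for `u < 0.5` and
#' `1 - (2(1-u))^(1/(eta_m+1))` otherwise, scaled by the distance to
#' the violated bound so the result always stays in `[lower, upper]`.
#' Larger `eta_m` concentrates the perturbation near zero.
#'
#' @param x Numeric vector of values within bounds.
#' @param lower,upper Bounds (recycled).
#' @param eta_m Distribution index, positive.
#' @return Mutated values, same length as `x`.
#' @export
polynomial_mutation <- function(x, lower, upper, eta_m = 15) {
  if (any(x < lower - 1e-12) || any(x > upper + 1e-12))
    stop("x outside bounds", call. = FALSE)
  u <- stats::runif(length(x))
  span <- upper - lower
  d1 <- (x - lower) / span
  d2 <- (upper - x) / span
  mpow <- 1 / (eta_m + 1)
  lo <- u < 0.5
  delta <- numeric(length(x))
  delta[lo] <- (2 * u[lo] + (1 - 2 * u[lo]) * (1 - d1[lo])^(eta_m + 1))^mpow - 1
  delta[!lo] <- 1 - (2 * (1 - u[!lo]) +
    2 * (u[!lo] - 0.5) * (1 - d2[!lo])^(eta_m + 1))^mpow
  pmin(pmax(x + delta * span, lower), upper)
}

#' Create a random first-generation direct genotype
#'
#' First-generation individuals are feed-forward networks without
#' hidden layer: only the fixed input/output roster, with every
#' input-to-output connection present, random magnitudes and random
#' signs. All I/O nodes are standard, so a generation-0 network has no
#' plastic weights.
#'
#' @param io_spec A list with `n_in`, `n_out` and optionally
#'   `input_labels`, `output_labels`.
#' @param type `"network"` (nodes carry kind + bias) or `"cppn"`
#'   (nodes carry an activation-function selector + bias).
#' @param w_max Upper magnitude bound.
#' @param bias_max Bias bound (biases live in `[-bias_max, bias_max]`).
#' @return An object of class `direct_genotype`.
#' @export
random_init_direct <- function(io_spec, type = c("network", "cppn"),
                               w_max = 2, bias_max = 2) {
  type <- match.arg(type)
  n_in <- io_spec$n_in; n_out <- io_spec$n_out
  in_ids <- paste0("in_", seq_len(n_in))
  out_ids <- paste0("out_", seq_len(n_out))
  nodes <- tibble::tibble(
    id = c(in_ids, out_ids),
    role = c(rep("input", n_in), rep("output", n_out)),
    kind = "standard",
    bias = c(rep(0, n_in), stats::runif(n_out, -bias_max, bias_max)),
    fun = if (type == "cppn")
      c(rep("linear", n_in),
        sample(cppn_function_set(), n_out, replace = TRUE))
    else NA_character_,
    label = c(io_spec$input_labels %||% in_ids,
              io_spec$output_labels %||% out_ids))
  edges <- tidyr::expand_grid(from = in_ids, to = out_ids)
  edges$sign <- sample(c(-1, 1), nrow(edges), replace = TRUE)
  edges$weight <- stats::runif(nrow(edges), 0, w_max)
  structure(list(nodes = nodes, edges = edges, type = type,
                 io = list(n_in = n_in, n_out = n_out),
                 bounds = list(weight = c(0, w_max),
                               bias = c(-bias_max, bias_max)),
                 next_id = 1L),
            class = "direct_genotype")
}

#' @export
print.direct_genotype <- function(x, ...) {
  cat(sprintf("<direct_genotype:%s> %d nodes, %d edges\n",
              x$type, nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

# internal: uniform random structural edits -----------------------------

geno_add_connection <- function(g) {
  from <- sample(g$nodes$id, 1)
  targets <- g$nodes$id[g$nodes$role != "input"]
  to <- sample(targets, 1)
  key <- paste(g$edges$from, g$edges$to)
  new <- tibble::tibble(from = from, to = to,
                        sign = sample(c(-1, 1), 1),
                        weight = stats::runif(1, g$bounds$weight[1],
                                              g$bounds$weight[2]))
  hit <- key == paste(from, to)
  if (any(hit)) g$edges[hit, ] <- new else g$edges <- rbind(g$edges, new)
  g
}

geno_del_connection <- function(g) {
  if (nrow(g$edges) == 0) return(g)
  g$edges <- g$edges[-sample.int(nrow(g$edges), 1), ]
  g
}

geno_move_connection <- function(g) {
  if (nrow(g$edges) == 0) return(g)
  i <- sample.int(nrow(g$edges), 1)
  end <- sample(c("from", "to"), 1)
  cand <- if (end == "to") g$nodes$id[g$nodes$role != "input"] else g$nodes$id
  new_edge <- g$edges[i, ]
  new_edge[[end]] <- sample(cand, 1)
  dup <- paste(g$edges$from, g$edges$to)[-i] ==
    paste(new_edge$from, new_edge$to)
  g$edges <- g$edges[-i, ]
  if (!any(dup)) g$edges <- rbind(g$edges, new_edge)
  g
}

geno_add_node <- function(g, new_node) {
  if (nrow(g$edges) == 0) return(g)
  i <- sample.int(nrow(g$edges), 1)
  e <- g$edges[i, ]
  g$nodes <- rbind(g$nodes, new_node)
  halves <- tibble::tibble(from = c(e$from, new_node$id),
                           to = c(new_node$id, e$to),
                           sign = e$sign, weight = e$weight)
  g$edges <- rbind(g$edges[-i, ], halves)
  g
}

geno_del_node <- function(g) {
  hid <- g$nodes$id[g$nodes$role == "hidden"]
  if (length(hid) == 0) return(g)
  v <- sample(hid, 1)
  g$nodes <- g$nodes[g$nodes$id != v, ]
  g$edges <- g$edges[g$edges$from != v & g$edges$to != v, ]
  g
}

fresh_node_id <- function(g) {
  id <- paste0("h_", g$next_id)
  while (id %in% g$nodes$id) {
    g$next_id <- g$next_id + 1L
    id <- paste0("h_", g$next_id)
  }
  list(id = id, g = g)
}

#' Mutate a direct genotype
#'
#' Applies the seven operators of [mutation_rates()] independently in
#' fixed order. Structural invariants (unique ordered edge pairs, I/O
#' roster preserved, bounded genes) are maintained. For network
#' genotypes the per-neuron parameter operator polynomially mutates the
#' bias and flips the standard/modulatory kind of hidden neurons; for
#' CPPN genotypes it mutates the bias and re-draws the activation
#' function. Weight mutation polynomially perturbs the magnitude;
#' connection signs are flipped per edge with the parameter-mutation
#' probability (sign is an intrinsic parameter, like neuron kind).
#'
#' @param g A `direct_genotype`.
#' @param rates A [mutation_rates()].
#' @return The mutated genotype.
#' @export
mutate_direct <- function(g, rates = mutation_rates()) {
  if (stats::runif(1) < rates$p_add_conn) g <- geno_add_connection(g)
  if (stats::runif(1) < rates$p_del_conn) g <- geno_del_connection(g)
  if (stats::runif(1) < rates$p_move_conn) g <- geno_move_connection(g)
  if (stats::runif(1) < rates$p_add_neuron) {
    f <- fresh_node_id(g); g <- f$g
    node <- tibble::tibble(
      id = f$id, role = "hidden", kind = "standard", bias = 0,
      fun = if (g$type == "cppn") sample(cppn_function_set(), 1)
            else NA_character_,
      label = NA_character_)
    g <- geno_add_node(g, node)
    g$next_id <- g$next_id + 1L
  }
  if (stats::runif(1) < rates$p_del_neuron) g <- geno_del_node(g)
  if (nrow(g$edges) > 0) {
    mut <- stats::runif(nrow(g$edges)) < rates$p_weight
    if (any(mut))
      g$edges$weight[mut] <- polynomial_mutation(
        g$edges$weight[mut], g$bounds$weight[1], g$bounds$weight[2],
        rates$eta_m)
    flip <- stats::runif(nrow(g$edges)) < rates$p_param
    g$edges$sign[flip] <- -g$edges$sign[flip]
  }
  mutn <- stats::runif(nrow(g$nodes)) < rates$p_param
  mutn <- mutn & g$nodes$role != "input"
  if (any(mutn)) {
    g$nodes$bias[mutn] <- polynomial_mutation(
      g$nodes$bias[mutn], g$bounds$bias[1], g$bounds$bias[2], rates$eta_m)
    if (g$type == "network") {
      flipk <- g$nodes$role == "hidden" &
        stats::runif(nrow(g$nodes)) < rates$p_param
      g$nodes$kind[flipk] <- ifelse(g$nodes$kind[flipk] == "standard",
                                    "modulatory", "standard")
    } else {
      g$nodes$fun[mutn] <- sample(cppn_function_set(), sum(mutn),
                                  replace = TRUE)
    }
  }
  g
}

#' Develop a direct genotype into a plastic network
#'
#' One-to-one mapping: each node becomes a neuron with its kind and
#' bias, each edge a connection with its sign and magnitude.
#'
#' @param g A network-type `direct_genotype`.
#' @param lambda,eta Network simulation parameters.
#' @return A `plastic_network`.
#' @export
develop_direct <- function(g, lambda = 5, eta = 0.1) {
  if (g$type != "network")
    stop("only network-type genotypes develop into plastic networks",
         call. = FALSE)
  plastic_network(
    neurons = tibble::tibble(id = g$nodes$id, role = g$nodes$role,
                             kind = g$nodes$kind, bias = g$nodes$bias,
                             label = g$nodes$label),
    connections = g$edges,
    lambda = lambda, eta = eta,
    w_min = 0, w_max = g$bounds$weight[2])
}

#' Genotype JSON round-trip
#'
#' @param g A `direct_genotype`.
#' @param path File path.
#' @export
write_genotype_json <- function(g, path) {
  jsonlite::write_json(
    list(nodes = g$nodes, edges = g$edges, type = g$type, io = g$io,
         bounds = g$bounds, next_id = g$next_id),
    path, dataframe = "columns", auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_genotype_json
#' @export
read_genotype_json <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  edges <- tibble::as_tibble(o$edges)
  if (nrow(edges) == 0)
    edges <- tibble::tibble(from = character(), to = character(),
                            sign = numeric(), weight = numeric())
  nodes <- tibble::as_tibble(o$nodes)
  nodes$fun <- as.character(nodes$fun)      # all-NA columns read as logical
  nodes$label <- as.character(nodes$label)
  structure(list(nodes = nodes, edges = edges,
                 type = o$type,
                 io = o$io,
                 bounds = lapply(o$bounds, as.numeric),
                 next_id = as.integer(o$next_id)),
            class = "direct_genotype")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
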