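#' Construct a plastic neural network
#'
#' A plastic network is a synchronous recurrent neural network with two
#' neuron kinds: *standard* neurons, which drive activation, and
#' *modulatory* neurons, whose outgoing connections gate Hebbian
#' plasticity at their targets instead of contributing to activation.
#' A connection is *plastic* exactly when its source is standard and its
#' target receives at least one modulatory input; only plastic
#' connections are modified by [apply_plasticity()] and randomized by
#' [reset_plastic_weights()].
#'
#' Connections carry a separate sign (`+1` excitatory, `-1` inhibitory)
#' and a non-negative magnitude in `[w_min, w_max]`; plasticity modifies
#' the magnitude only, so an inhibitory connection can weaken to zero
#' but never become excitatory.
#'
#' @param neurons Data frame with columns `id` (unique character),
#'   `role` (`"input"`, `"hidden"` or `"output"`), `kind` (`"standard"`
#'   or `"modulatory"`), `bias` (numeric) and optionally `label`.
#' @param connections Data frame with columns `from`, `to` (neuron
#'   ids), `sign` (`+1` or `-1`) and `weight` (magnitude in
#'   `[w_min, w_max]`). At most one connection per ordered pair.
#' @param lambda Steepness of the activation sigmoid
#'   `phi(x) = 1 / (1 + exp(-lambda * x))`.
#' @param eta Hebbian learning coefficient (must be positive).
#' @param w_min,w_max Bounds on connection magnitudes; `w_min` is 0
#'   (no negative magnitudes; polarity is the sign flag).
#'
#' @return An object of class `plastic_network`.
#' @export
#' @examples
#' net <- plastic_network(
#'   neurons = tibble::tibble(
#'     id = c("in1", "out1"), role = c("input", "output"),
#'     kind = "standard", bias = c(0, 0)),
#'   connections = tibble::tibble(
#'     from = "in1", to = "out1", sign = 1, weight = 1.5))
#' net <- activate(net, inputs = 1, n_steps = 2)
#' network_outputs(net)
plastic_network <- function(neurons, connections,
                            lambda = 5, eta = 0.1,
                            w_min = 0, w_max = 2) {
  neurons <- tibble::as_tibble(neurons)
  if (!"label" %in% names(neurons)) neurons$label <- NA_character_
  neurons <- neurons[, c("id", "role", "kind", "bias", "label")]
  if (is.null(connections) || nrow(connections) == 0) {
    connections <- tibble::tibble(from = character(), to = character(),
                                  sign = numeric(), weight = numeric())
  }
  connections <- tibble::as_tibble(connections)[, c("from", "to", "sign", "weight")]

  if (anyDuplicated(neurons$id))
    stop("neuron ids must be unique", call. = FALSE)
  if (!all(neurons$role %in% c("input", "hidden", "output")))
    stop("neuron role must be input, hidden or output", call. = FALSE)
  if (!all(neurons$kind %in% c("standard", "modulatory")))
    stop("neuron kind must be standard or modulatory", call. = FALSE)
  if (any(neurons$role == "input" & neurons$kind == "modulatory"))
    stop("input neurons cannot be modulatory", call. = FALSE)
  if (any(neurons$role == "output" & neurons$kind == "modulatory"))
    stop("output neurons must be standard", call. = FALSE)
  if (!all(connections$from %in% neurons$id) ||
      !all(connections$to %in% neurons$id))
    stop("connection endpoints must be existing neuron ids", call. = FALSE)
  if (anyDuplicated(paste(connections$from, connections$to)))
    stop("duplicate connection between an ordered neuron pair", call. = FALSE)
  if (!all(connections$sign %in% c(-1, 1)))
    stop("connection sign must be -1 or +1", call. = FALSE)
  if (eta <= 0) stop("eta must be positive", call. = FALSE)
  if (w_min != 0) stop("w_min must be 0 (no negative magnitudes)", call. = FALSE)
  if (any(connections$weight < w_min - 1e-12 | connections$weight > w_max + 1e-12))
    stop("connection magnitudes must lie in [w_min, w_max]", call. = FALSE)

  net <- structure(
    list(neurons = neurons,
         connections = connections,
         params = list(lambda = lambda, eta = eta,
                       w_min = w_min, w_max = w_max),
         state = stats::setNames(rep(0, nrow(neurons)), neurons$id),
         mod = stats::setNames(rep(0, nrow(neurons)), neurons$id)),
    class = "plastic_network")
  net$connections$plastic <- connection_plasticity(net)
  net
}

#' Which connections are plastic?
#'
#' A connection is plastic iff its source is a standard neuron and its
#' target receives at least one connection from a modulatory neuron.
#'
#' @param net A `plastic_network`.
#' @return Logical vector along `net$connections`.
#' @export
connection_plasticity <- function(net) {
  kind <- stats::setNames(net$neurons$kind, net$neurons$id)
  con <- net$connections
  if (nrow(con) == 0) return(logical(0))
  modulated <- unique(con$to[kind[con$from] == "modulatory"])
  kind[con$from] == "standard" & con$to %in% modulated
}

#' @export
print.plastic_network <- function(x, ...) {
  n <- x$neurons
  cat(sprintf(
    "<plastic_network> %d neurons (%d in / %d hidden / %d out, %d modulatory), %d connections (%d plastic)\n",
    nrow(n), sum(n$role == "input"), sum(n$role == "hidden"),
    sum(n$role == "output"), sum(n$kind == "modulatory"),
    nrow(x$connections), sum(x$connections$plastic)))
  invisible(x)
}

#' @export
as_tibble.plastic_network <- function(x, what = c("connections", "neurons"), ...) {
  what <- match.arg(what)
  x[[what]]
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# internal: dense matrices for simulation; entry [i, j] is connection j -> i
compile_network <- function(net) {
  ids <- net$neurons$id
  n <- length(ids)
  idx <- stats::setNames(seq_len(n), ids)
  kind <- net$neurons$kind
  con <- net$connections
  Amag <- matrix(0, n, n); Asgn <- matrix(0, n, n)
  Msig <- matrix(0, n, n); P <- matrix(FALSE, n, n)
  if (nrow(con) > 0) {
    si <- idx[con$from]; ti <- idx[con$to]
    std <- kind[si] == "standard"
    Amag[cbind(ti[std], si[std])] <- con$weight[std]
    Asgn[cbind(ti[std], si[std])] <- con$sign[std]
    Msig[cbind(ti[!std], si[!std])] <- con$sign[!std] * con$weight[!std]
    P[cbind(ti[con$plastic], si[con$plastic])] <- TRUE
  }
  list(Amag = Amag, Asgn = Asgn, Msig = Msig, P = P,
       bias = net$neurons$bias,
       input_idx = which(net$neurons$role == "input"),
       output_idx = which(net$neurons$role == "output"),
       idx = idx, n = n)
}

# internal: write compiled magnitudes back into the tibble representation
uncompile_weights <- function(net, cm) {
  con <- net$connections
  if (nrow(con) > 0) {
    si <- cm$idx[con$from]; ti <- cm$idx[con$to]
    std <- net$neurons$kind[si] == "standard"
    con$weight[std] <- cm$Amag[cbind(ti[std], si[std])]
  }
  net$connections <- con
  net
}

#' Advance the network by one synchronous time step
#'
#' The clamped input values are written into the state before
#' propagation, then all new activations are computed from that state,
#' so a signal traverses one connection per step starting at the step
#' its input is presented. Input neurons relay the clamped values (no
#' sigmoid); every other neuron outputs
#' `phi(sum(sign * weight * o_source) + bias)` over its *standard*
#' inputs, with `phi(x) = 1 / (1 + exp(-lambda * x))`. Each neuron's
#' modulatory sum `m_i = sum(sign * weight * o_source)` over its
#' *modulatory* inputs is recorded for [apply_plasticity()].
#'
#' @param net A `plastic_network`.
#' @param inputs Numeric vector in `[0, 1]`, one value per input neuron
#'   (in the order input neurons appear in `net$neurons`).
#' @return The network with updated `state` and `mod`.
#' @export
net_step <- function(net, inputs) {
  cm <- compile_network(net)
  if (length(inputs) != length(cm$input_idx))
    stop("inputs length (", length(inputs), ") does not match number of input neurons (",
         length(cm$input_idx), ")", call. = FALSE)
  o <- unname(net$state)
  o[cm$input_idx] <- inputs          # clamp before propagation
  drive <- (cm$Asgn * cm$Amag) %*% o + cm$bias
  new_o <- sigmoid(net$params$lambda * drive)[, 1]
  m <- (cm$Msig %*% o)[, 1]
  new_o[cm$input_idx] <- inputs
  net$state[] <- new_o
  net$mod[] <- m
  net
}

#' Apply one neuromodulated Hebbian update
#'
#' For every plastic connection `j -> i` the magnitude is updated as
#' `w_ij <- clamp(w_ij + eta * tanh(m_i) * o_i * o_j, w_min, w_max)`
#' where `m_i` is the target's modulatory sum recorded at the last
#' [net_step()] and `o_i`, `o_j` are the current (post-step)
#' activations. `tanh` is the sign-preserving modulation transfer, so
#' with zero modulatory input no weight can change. Non-plastic
#' connections are never modified.
#'
#' @param net A `plastic_network` on which [net_step()] has been called.
#' @return The network with updated connection magnitudes.
#' @export
apply_plasticity <- function(net) {
  con <- net$connections
  pl <- which(con$plastic)
  if (length(pl) == 0) return(net)
  m <- net$mod[con$to[pl]]
  oi <- net$state[con$to[pl]]
  oj <- net$state[con$from[pl]]
  w <- con$weight[pl] + net$params$eta * tanh(m) * oi * oj
  con$weight[pl] <- pmin(pmax(w, net$params$w_min), net$params$w_max)
  net$connections <- con
  net
}

#' Run the network for several steps on a fixed input
#'
#' Performs `n_steps` synchronous [net_step()] calls with the same
#' clamped input vector; after each step, [apply_plasticity()] is
#' applied iff `learn` is `TRUE` (weight changes can occur at any time,
#' in any phase). Five steps is enough for a signal to travel from the
#' inputs to the outputs in the networks used for the conditioning task.
#'
#' @inheritParams net_step
#' @param n_steps Positive number of synchronous steps.
#' @param learn Apply the Hebbian update after each step?
#' @return The updated network; read the final output activations with
#'   [network_outputs()].
#' @export
activate <- function(net, inputs, n_steps = 5, learn = FALSE) {
  if (n_steps < 1) stop("n_steps must be >= 1", call. = FALSE)
  for (t in seq_len(n_steps)) {
    net <- net_step(net, inputs)
    if (learn) net <- apply_plasticity(net)
  }
  net
}

#' Output-neuron activations
#'
#' @param net A `plastic_network`.
#' @return Named numeric vector of the output neurons' activations, in
#'   the order output neurons appear in `net$neurons`.
#' @export
network_outputs <- function(net) {
  net$state[net$neurons$id[net$neurons$role == "output"]]
}

#' Randomize the plastic (modulated) weights
#'
#' Redraws every plastic connection magnitude uniformly from
#' `[w_min, w_max]` and resets all activations and modulatory sums to
#' zero. This is how each learning lifetime starts: the network never
#' has to un-learn a previous lifetime. Non-plastic magnitudes — the
#' fixed wiring designed by evolution — are untouched. Uses R's global
#' RNG; call `set.seed()` for reproducibility.
#'
#' @param net A `plastic_network`.
#' @return The reset network.
#' @export
reset_plastic_weights <- function(net) {
  pl <- which(net$connections$plastic)
  if (length(pl) > 0)
    net$connections$weight[pl] <-
      stats::runif(length(pl), net$params$w_min, net$params$w_max)
  net$state[] <- 0
  net$mod[] <- 0
  net
}

#' Prune a network to its input-output core
#'
#' Keeps exactly the neurons lying on some directed path from an input
#' neuron to an output neuron (inputs and outputs themselves are always
#' kept), along with the connections among them. Used before regularity
#' measurement and drawing so that disconnected vestigial structure
#' cannot contribute. A network with no input and no output neurons has
#' nothing to anchor the criterion on and is returned unchanged.
#'
#' @param net A `plastic_network`.
#' @return The pruned network.
#' @export
prune_to_io <- function(net) {
  ids <- net$neurons$id
  in_ids <- ids[net$neurons$role == "input"]
  out_ids <- ids[net$neurons$role == "output"]
  if (length(in_ids) == 0 && length(out_ids) == 0) return(net)
  g <- igraph::graph_from_data_frame(
    net$connections[, c("from", "to")], directed = TRUE,
    vertices = data.frame(name = ids))
  fwd <- rep(FALSE, length(ids)); names(fwd) <- ids
  bwd <- fwd
  for (v in in_ids) fwd[names(igraph::subcomponent(g, v, mode = "out"))] <- TRUE
  for (v in out_ids) bwd[names(igraph::subcomponent(g, v, mode = "in"))] <- TRUE
  keep <- (fwd & bwd) | ids %in% c(in_ids, out_ids)
  net$neurons <- net$neurons[keep, ]
  kc <- net$connections$from %in% net$neurons$id &
    net$connections$to %in% net$neurons$id
  net$connections <- net$connections[kc, ]
  net$state <- net$state[net$neurons$id]
  net$mod <- net$mod[net$neurons$id]
  net$connections$plastic <- connection_plasticity(net)
  net
}
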