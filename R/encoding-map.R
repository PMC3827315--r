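#' Map development configuration
#'
#' In the map-based developmental encoding, a genotype is a small
#' labeled graph whose nodes stand for *neural maps* (groups of
#' `map_size` identical neurons) or single neurons, and whose edges
#' stand for one-to-one or one-to-all connection schemes with a uniform
#' weight. All maps share the same size.
#'
#' @param map_size Neurons per map (default 4, matching the 4 stimuli
#'   and 4 actions of the conditioning task).
#' @param w_max Upper magnitude bound of developed connections.
#' @param bias_max Developed biases span `[-bias_max, bias_max]`.
#' @return A list of class `map_config`.
#' @export
map_config <- function(map_size = 4, w_max = 2, bias_max = 2) {
  stopifnot(map_size >= 1)
  structure(list(map_size = map_size, w_max = w_max,
                 bias_max = bias_max),
            class = "map_config")
}

#' Create a random first-generation map genotype
#'
#' The fixed I/O roster mirrors the task's input layer: a stimulus map
#' and a feedback map (size 4 when developed), two reward singleton
#' nodes, and one output map. First-generation genotypes connect every
#' input node to the output node with random edge labels and have no
#' hidden nodes. All label genes are reals in `[0, 1]`; see
#' [decode_labels()] for their meaning.
#'
#' @return An object of class `map_genotype`.
#' @export
random_init_map <- function() {
  nodes <- tibble::tibble(
    id = c("stim", "rpos", "rneg", "fb", "out"),
    role = c("input", "input", "input", "input", "output"),
    fixed = TRUE,
    g_map = c(1, 0, 0, 1, 1),   # fixed: maps for stim/fb/out, singles for rewards
    g_inhib = 0,
    g_kind = 1,                  # I/O neurons are standard
    g_bias = c(0.5, 0.5, 0.5, 0.5, stats::runif(1)))
  edges <- tibble::tibble(
    from = c("stim", "rpos", "rneg", "fb"),
    to = "out",
    g_weight = stats::runif(4),
    g_inhib = stats::runif(4),
    g_type = stats::runif(4))
  structure(list(nodes = nodes, edges = edges, next_id = 1L),
            class = "map_genotype")
}

#' @export
print.map_genotype <- function(x, ...) {
  cat(sprintf("<map_genotype> %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Decode label genes into semantic labels
#'
#' Every label is a real gene in `[0, 1]`. Booleans threshold at 0.5
#' (gene `>= 0.5` is "true": a map rather than a single neuron,
#' inhibitory rather than excitatory, standard rather than modulatory,
#' one-to-all rather than one-to-one); the weight gene scales affinely
#' to `[0, w_max]` and the bias gene to `[-bias_max, bias_max]`.
#' Decoding is deterministic, total on `[0, 1]` and idempotent in the
#' sense that labels do not feed back into genes.
#'
#' @param genes Numeric vector in `[0, 1]`.
#' @param what One of `"bool"`, `"weight"`, `"bias"`.
#' @param config A [map_config()].
#' @return Logical or numeric vector of decoded labels.
#' @export
decode_labels <- function(genes, what = c("bool", "weight", "bias"),
                          config = map_config()) {
  what <- match.arg(what)
  if (any(genes < 0 | genes > 1))
    stop("label genes must lie in [0, 1]", call. = FALSE)
  switch(what,
         bool = genes >= 0.5,
         weight = genes * config$w_max,
         bias = (2 * genes - 1) * config$bias_max)
}

# internal: neuron ids of a developed node, honoring the fixed roster
map_member_ids <- function(node, map_size) {
  is_map <- node$g_map >= 0.5
  if (is_map) paste0(node$id, "_", seq_len(map_size)) else node$id
}

#' Develop a map genotype into a plastic network
#'
#' Each map node expands into `map_size` identical neurons (same kind,
#' bias and polarity); singleton nodes expand into one neuron. A
#' one-to-one edge connects the k-th neuron of the source to the k-th
#' neuron of the target (requiring equal effective sizes); a one-to-all
#' edge connects every source neuron to every target neuron. All
#' connections developed from one edge share the edge's uniform
#' magnitude, and are inhibitory iff the edge or the source node is
#' labeled inhibitory. A one-to-one edge between a singleton and a map
#' is resolved as one-to-all; a one-to-one edge between groups of
#' unequal size larger than one raises a classed development error
#' (`plastevo_development_error`), which the evolutionary loop converts
#' into minimal fitness.
#'
#' Input neurons develop in the task's input order (stimulus map,
#' positive then negative reward, feedback map); hidden map nodes carry
#' free kind/polarity/bias genes.
#'
#' @param g A `map_genotype`.
#' @param config A [map_config()].
#' @param lambda,eta Network simulation parameters.
#' @return A `plastic_network`.
#' @export
develop_map <- function(g, config = map_config(), lambda = 5, eta = 0.1) {
  ms <- config$map_size
  nodes <- g$nodes
  # develop inputs in the canonical order stim, rpos, rneg, fb, then
  # hidden, then outputs
  ord <- order(match(nodes$role, c("input", "hidden", "output")),
               match(nodes$id, c("stim", "rpos", "rneg", "fb")))
  nodes <- nodes[ord, ]
  is_map <- nodes$g_map >= 0.5
  reps <- ifelse(is_map, ms, 1L)
  members <- lapply(seq_len(nrow(nodes)), function(i)
    if (is_map[i]) paste0(nodes$id[i], "_", seq_len(ms)) else nodes$id[i])
  names(members) <- nodes$id
  kind <- ifelse(nodes$role != "hidden" |
                   decode_labels(nodes$g_kind, "bool", config),
                 "standard", "modulatory")
  bias <- ifelse(nodes$role == "input", 0,
                 decode_labels(nodes$g_bias, "bias", config))
  neurons <- tibble::tibble(
    id = unlist(members, use.names = FALSE),
    role = rep(nodes$role, reps),
    kind = rep(kind, reps),
    bias = rep(bias, reps),
    label = rep(nodes$id, reps))
  inhib_node <- stats::setNames(decode_labels(nodes$g_inhib, "bool", config),
                                nodes$id)
  e_from <- list(); e_to <- list(); e_sign <- numeric(0); e_w <- numeric(0)
  for (i in seq_len(nrow(g$edges))) {
    e <- g$edges[i, ]
    src <- members[[e$from]]; tgt <- members[[e$to]]
    one_to_all <- decode_labels(e$g_type, "bool", config)
    if (!one_to_all && length(src) != length(tgt)) {
      if (length(src) == 1 || length(tgt) == 1) {
        one_to_all <- TRUE    # singleton-map mixing falls back to one-to-all
      } else {
        rlang::abort("one-to-one connection between maps of unequal size",
                     class = "plastevo_development_error")
      }
    }
    if (one_to_all) {
      e_from[[i]] <- rep(src, times = length(tgt))
      e_to[[i]] <- rep(tgt, each = length(src))
    } else {
      e_from[[i]] <- src
      e_to[[i]] <- tgt
    }
    sgn <- if (decode_labels(e$g_inhib, "bool", config) ||
               inhib_node[[e$from]]) -1 else 1
    e_sign <- c(e_sign, rep(sgn, length(e_from[[i]])))
    e_w <- c(e_w, rep(decode_labels(e$g_weight, "weight", config),
                      length(e_from[[i]])))
  }
  connections <- tibble::tibble(
    from = unlist(e_from, use.names = FALSE) %||% character(),
    to = unlist(e_to, use.names = FALSE) %||% character(),
    sign = e_sign, weight = e_w)
  connections <- connections[!duplicated(paste(connections$from,
                                               connections$to)), ]
  plastic_network(neurons, connections, lambda = lambda, eta = eta,
                  w_min = 0, w_max = config$w_max)
}

#' Mutate a map genotype
#'
#' Structural operators are the direct encoding's: add/delete/move an
#' edge, add a node by splitting an edge (both halves keep the split
#' edge's labels; the new hidden node receives uniform-random label
#' genes), delete a hidden node. Label genes are perturbed by
#' polynomial mutation within `[0, 1]`: the edge weight gene with
#' probability `p_weight` per edge, the remaining edge genes and all
#' node genes with probability `p_param` per element owner.
#'
#' @param g A `map_genotype`.
#' @param rates A [mutation_rates()].
#' @return The mutated genotype.
#' @export
mutate_map <- function(g, rates = mutation_rates()) {
  new_edge_genes <- function(from, to)
    tibble::tibble(from = from, to = to, g_weight = stats::runif(1),
                   g_inhib = stats::runif(1), g_type = stats::runif(1))
  if (stats::runif(1) < rates$p_add_conn) {
    from <- sample(g$nodes$id, 1)
    to <- sample(g$nodes$id[g$nodes$role != "input"], 1)
    hit <- paste(g$edges$from, g$edges$to) == paste(from, to)
    ne <- new_edge_genes(from, to)
    if (any(hit)) g$edges[hit, ] <- ne else g$edges <- rbind(g$edges, ne)
  }
  if (stats::runif(1) < rates$p_del_conn && nrow(g$edges) > 0)
    g$edges <- g$edges[-sample.int(nrow(g$edges), 1), ]
  if (stats::runif(1) < rates$p_move_conn && nrow(g$edges) > 0) {
    i <- sample.int(nrow(g$edges), 1)
    end <- sample(c("from", "to"), 1)
    cand <- if (end == "to") g$nodes$id[g$nodes$role != "input"]
            else g$nodes$id
    e <- g$edges[i, ]; e[[end]] <- sample(cand, 1)
    dup <- paste(g$edges$from, g$edges$to)[-i] == paste(e$from, e$to)
    g$edges <- g$edges[-i, ]
    if (!any(dup)) g$edges <- rbind(g$edges, e)
  }
  if (stats::runif(1) < rates$p_add_neuron && nrow(g$edges) > 0) {
    id <- paste0("h_", g$next_id)
    while (id %in% g$nodes$id) {
      g$next_id <- g$next_id + 1L
      id <- paste0("h_", g$next_id)
    }
    g$next_id <- g$next_id + 1L
    i <- sample.int(nrow(g$edges), 1)
    e <- g$edges[i, ]
    g$nodes <- rbind(g$nodes, tibble::tibble(
      id = id, role = "hidden", fixed = FALSE,
      g_map = stats::runif(1), g_inhib = stats::runif(1),
      g_kind = stats::runif(1), g_bias = stats::runif(1)))
    halves <- e[c(1, 1), ]
    halves$from <- c(e$from, id); halves$to <- c(id, e$to)
    g$edges <- rbind(g$edges[-i, ], halves)
  }
  if (stats::runif(1) < rates$p_del_neuron) {
    hid <- g$nodes$id[g$nodes$role == "hidden"]
    if (length(hid) > 0) {
      v <- sample(hid, 1)
      g$nodes <- g$nodes[g$nodes$id != v, ]
      g$edges <- g$edges[g$edges$from != v & g$edges$to != v, ]
    }
  }
  if (nrow(g$edges) > 0) {
    mw <- stats::runif(nrow(g$edges)) < rates$p_weight
    if (any(mw))
      g$edges$g_weight[mw] <- polynomial_mutation(g$edges$g_weight[mw],
                                                  0, 1, rates$eta_m)
    me <- stats::runif(nrow(g$edges)) < rates$p_param
    if (any(me)) {
      g$edges$g_inhib[me] <- polynomial_mutation(g$edges$g_inhib[me],
                                                 0, 1, rates$eta_m)
      g$edges$g_type[me] <- polynomial_mutation(g$edges$g_type[me],
                                                0, 1, rates$eta_m)
    }
  }
  free <- !g$nodes$fixed
  mn <- free & stats::runif(nrow(g$nodes)) < rates$p_param
  if (any(mn)) {
    for (col in c("g_map", "g_inhib", "g_kind", "g_bias"))
      g$nodes[[col]][mn] <- polynomial_mutation(g$nodes[[col]][mn],
                                                0, 1, rates$eta_m)
  }
  # output bias gene is evolvable even though the node itself is fixed
  ob <- g$nodes$role == "output" & stats::runif(nrow(g$nodes)) < rates$p_param
  if (any(ob))
    g$nodes$g_bias[ob] <- polynomial_mutation(g$nodes$g_bias[ob],
                                              0, 1, rates$eta_m)
  g
}
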