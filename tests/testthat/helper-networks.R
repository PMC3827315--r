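# Builders used across test files; all draw from R's global RNG so
# tests control reproducibility with set.seed().

# random plastic network with given layer sizes
rand_network <- function(n_in = 3, n_hid = 4, n_out = 2, p_edge = 0.4,
                         p_mod = 0.3) {
  ids <- c(paste0("i", seq_len(n_in)), paste0("h", seq_len(n_hid)),
           paste0("o", seq_len(n_out)))
  roles <- c(rep("input", n_in), rep("hidden", n_hid), rep("output", n_out))
  kinds <- ifelse(roles == "hidden" & stats::runif(length(ids)) < p_mod,
                  "modulatory", "standard")
  pairs <- expand.grid(from = ids, to = ids, stringsAsFactors = FALSE)
  pairs <- pairs[roles[match(pairs$to, ids)] != "input", ]
  pairs <- pairs[stats::runif(nrow(pairs)) < p_edge, ]
  plastic_network(
    tibble::tibble(id = ids, role = roles, kind = kinds,
                   bias = stats::runif(length(ids), -1, 1)),
    tibble::tibble(from = pairs$from, to = pairs$to,
                   sign = sample(c(-1, 1), nrow(pairs), replace = TRUE),
                   weight = stats::runif(nrow(pairs), 0, 2)))
}

# naive two-buffer synchronous step, written independently of net_step
naive_step <- function(net, inputs) {
  old <- net$state
  old[net$neurons$id[net$neurons$role == "input"]] <- inputs
  new <- old
  m <- net$mod
  lam <- net$params$lambda
  kind <- stats::setNames(net$neurons$kind, net$neurons$id)
  in_ids <- net$neurons$id[net$neurons$role == "input"]
  for (i in seq_len(nrow(net$neurons))) {
    id <- net$neurons$id[i]
    s <- net$neurons$bias[i]
    msum <- 0
    for (j in seq_len(nrow(net$connections))) {
      con <- net$connections[j, ]
      if (con$to != id) next
      term <- con$sign * con$weight * old[[con$from]]
      if (kind[[con$from]] == "modulatory") msum <- msum + term
      else s <- s + term
    }
    new[[id]] <- 1 / (1 + exp(-lam * s))
    m[[id]] <- msum
  }
  new[in_ids] <- inputs
  net$state <- new
  net$mod <- m
  net
}

# minimal chain: input -> hidden -> output, with optional modulatory
# neuron feeding the output
chain_network <- function(w1 = 1.5, w2 = 0.8, bias_h = 0.2, bias_o = -0.3,
                          modulated = FALSE, lambda = 5, eta = 0.1) {
  neurons <- tibble::tibble(
    id = c("in", "h", "out", if (modulated) "m"),
    role = c("input", "hidden", "output", if (modulated) "hidden"),
    kind = c("standard", "standard", "standard",
             if (modulated) "modulatory"),
    bias = c(0, bias_h, bias_o, if (modulated) 0.5))
  con <- tibble::tibble(
    from = c("in", "h", if (modulated) "m"),
    to = c("h", "out", if (modulated) "out"),
    sign = 1,
    weight = c(w1, w2, if (modulated) 1))
  plastic_network(neurons, con, lambda = lambda, eta = eta)
}

# random small colored graph for automorphism cross-checks
rand_colored_graph <- function(max_n = 8, n_colors = 2, p_edge = 0.3) {
  n <- sample(2:max_n, 1)
  ids <- paste0("v", seq_len(n))
  cols <- sample(letters[seq_len(n_colors)], n, replace = TRUE)
  pairs <- expand.grid(from = ids, to = ids, stringsAsFactors = FALSE)
  pairs <- pairs[stats::runif(nrow(pairs)) < p_edge, ]
  colored_graph(tibble::tibble(id = ids, color = cols),
                tibble::tibble(from = pairs$from, to = pairs$to))
}

# zero network: task-shaped direct development with all weights and
# biases zero, so all outputs tie and the softmax is uniform
zero_network <- function() {
  g <- random_init_direct(list(n_in = 10, n_out = 4))
  net <- develop_direct(g)
  net$connections$weight[] <- 0
  net$neurons$bias[] <- 0
  net
}

# hand-built constant CPPN: no edges, outputs are linear nodes whose
# bias fixes the value
const_cppn <- function(n_in, values) {
  n_out <- length(values)
  in_ids <- paste0("in_", seq_len(n_in))
  out_ids <- paste0("out_", seq_len(n_out))
  structure(list(
    nodes = tibble::tibble(
      id = c(in_ids, out_ids),
      role = c(rep("input", n_in), rep("output", n_out)),
      kind = "standard",
      bias = c(rep(0, n_in), values),
      fun = c(rep("linear", n_in), rep("linear", n_out)),
      label = NA_character_),
    edges = tibble::tibble(from = character(), to = character(),
                           sign = numeric(), weight = numeric()),
    type = "cppn", io = list(n_in = n_in, n_out = n_out),
    bounds = list(weight = c(0, 2), bias = c(-2, 2)),
    next_id = 1L),
    class = "direct_genotype")
}

# does a developed map genotype retain a hidden map whose edges are all
# one-to-all? (the condition under which member swaps are guaranteed
# automorphisms)
has_free_hidden_map <- function(geno, net_pruned, map_size = 4) {
  hidden <- geno$nodes[geno$nodes$role == "hidden" & geno$nodes$g_map >= 0.5, ]
  if (nrow(hidden) == 0) return(FALSE)
  for (id in hidden$id) {
    inc <- geno$edges[geno$edges$from == id | geno$edges$to == id, ]
    if (nrow(inc) == 0) next
    if (any(inc$g_type < 0.5)) next
    if (sum(net_pruned$neurons$label == id) == map_size) return(TRUE)
  }
  FALSE
}

# independent front oracle: repeatedly peel the mutually non-dominated
# subset using explicit pairwise comparisons
peel_fronts <- function(obj) {
  n <- nrow(obj)
  front <- integer(n)
  remaining <- seq_len(n)
  f <- 1L
  dominates <- function(a, b)
    all(obj[a, ] >= obj[b, ]) && any(obj[a, ] > obj[b, ])
  while (length(remaining) > 0) {
    nd <- remaining[vapply(remaining, function(p)
      !any(vapply(remaining, function(q) q != p && dominates(q, p),
                  logical(1))), logical(1))]
    front[nd] <- f
    remaining <- setdiff(remaining, nd)
    f <- f + 1L
  }
  front
}
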