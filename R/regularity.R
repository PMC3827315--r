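#' Weight-binning configuration
#'
#' For the regularity measure, signed synaptic weights are binned into
#' four categories: large negative, small negative, small positive,
#' large positive. The boundary between "small" and "large" is a
#' magnitude threshold (default `w_max / 2`); zero weight ties break to
#' "small positive".
#'
#' @param boundary Magnitude threshold between small and large.
#' @return A list of class `weight_bins`.
#' @export
weight_bins <- function(boundary = 1) {
  stopifnot(boundary > 0)
  structure(list(boundary = boundary), class = "weight_bins")
}

#' Bin a signed weight into its category color
#'
#' @param w Numeric vector of signed weights (sign times magnitude).
#' @param bins A [weight_bins()].
#' @return Character vector in `{"large_negative", "small_negative",
#'   "small_positive", "large_positive"}`.
#' @export
bin_weight <- function(w, bins = weight_bins()) {
  size <- ifelse(abs(w) < bins$boundary, "small", "large")
  pol <- ifelse(w < 0, "negative", "positive")   # 0 -> positive
  paste(size, pol, sep = "_")
}

#' Construct a vertex-colored directed graph
#'
#' @param vertices Data frame with columns `id` and `color`.
#' @param edges Data frame with columns `from` and `to` (vertex ids).
#' @return An object of class `colored_graph`.
#' @export
colored_graph <- function(vertices, edges) {
  vertices <- tibble::as_tibble(vertices)[, c("id", "color")]
  if (is.null(edges) || nrow(edges) == 0)
    edges <- tibble::tibble(from = character(), to = character())
  edges <- tibble::as_tibble(edges)[, c("from", "to")]
  if (anyDuplicated(vertices$id)) stop("vertex ids must be unique", call. = FALSE)
  if (!all(edges$from %in% vertices$id) || !all(edges$to %in% vertices$id))
    stop("edge endpoints must be existing vertices", call. = FALSE)
  structure(list(vertices = vertices, edges = edges),
            class = "colored_graph")
}

#' @export
print.colored_graph <- function(x, ...) {
  cat(sprintf("<colored_graph> %d vertices (%d colors), %d edges\n",
              nrow(x$vertices), length(unique(x$vertices$color)),
              nrow(x$edges)))
  invisible(x)
}

#' Transform a network into a colored graph for regularity measurement
#'
#' The network is first pruned to its input-output core
#' ([prune_to_io()]). Neurons become vertices colored `"m"`
#' (modulatory) or `"n"` (all others) — inputs and outputs carry no
#' further role color, so same-role neurons may be swapped by an
#' automorphism; `strict_io = TRUE` additionally colors vertices by
#' role. Each connection, with signed weight `sign * magnitude`, is
#' replaced by a two-edge path through a new vertex colored by the
#' weight's [bin_weight()] category (an exact-automorphism engine
#' needs vertex colors, not edge labels). Biases are ignored.
#'
#' Plastic magnitudes depend on learning history; by default they are
#' set to the midpoint `(w_min + w_max) / 2` before binning so the
#' measure is deterministic (`plastic_weights = "snapshot"` keeps the
#' current magnitudes instead).
#'
#' @param net A `plastic_network`.
#' @param bins A [weight_bins()].
#' @param plastic_weights `"midpoint"` or `"snapshot"`.
#' @param prune Prune to the I/O core first?
#' @param strict_io Add role colors to input/output vertices?
#' @return A `colored_graph` with `N + C` vertices and `2C` edges for
#'   a pruned network of `N` neurons and `C` connections.
#' @export
to_colored_graph <- function(net, bins = weight_bins(),
                             plastic_weights = c("midpoint", "snapshot"),
                             prune = TRUE, strict_io = FALSE) {
  plastic_weights <- match.arg(plastic_weights)
  if (prune) net <- prune_to_io(net)
  con <- net$connections
  if (plastic_weights == "midpoint" && nrow(con) > 0)
    con$weight[con$plastic] <- (net$params$w_min + net$params$w_max) / 2
  vcol <- ifelse(net$neurons$kind == "modulatory", "m", "n")
  if (strict_io)
    vcol <- ifelse(net$neurons$role == "hidden", vcol,
                   paste(vcol, net$neurons$role, sep = "_"))
  verts <- tibble::tibble(id = net$neurons$id, color = vcol)
  if (nrow(con) > 0) {
    wid <- paste0("w", seq_len(nrow(con)))
    verts <- rbind(verts, tibble::tibble(
      id = wid, color = bin_weight(con$sign * con$weight, bins)))
    edges <- tibble::tibble(from = c(con$from, wid), to = c(wid, con$to))
  } else {
    edges <- NULL
  }
  colored_graph(verts, edges)
}

#' Count the automorphisms of a colored graph, exactly
#'
#' The number of color-preserving, direction-preserving vertex
#' permutations that fix the edge relation — at least 1 (the
#' identity). The count is computed exactly with the BLISS canonical
#' labeling engine (via igraph); it quantifies structural regularity:
#' each extra automorphism is a symmetry that lets part of the
#' structure be described once and reused.
#'
#' @param graph A `colored_graph` (or a `plastic_network`, transformed
#'   with [to_colored_graph()] defaults first).
#' @param ... Passed to [to_colored_graph()] when `graph` is a network.
#' @return The automorphism count as a numeric scalar.
#' @export
count_automorphisms <- function(graph, ...) {
  if (inherits(graph, "plastic_network"))
    graph <- to_colored_graph(graph, ...)
  if (nrow(graph$vertices) == 0) return(1)
  g <- igraph::graph_from_data_frame(
    graph$edges, directed = TRUE,
    vertices = data.frame(name = graph$vertices$id))
  colors <- as.integer(factor(graph$vertices$color))
  as.numeric(igraph::count_automorphisms(g, colors = colors)$group_size)
}

# internal: all permutations of 1..n, by inserting n into each slot of
# each permutation of 1..(n-1)
all_permutations <- function(n) {
  if (n <= 1) return(list(seq_len(n)))
  sub <- all_permutations(n - 1L)
  out <- vector("list", factorial(n))
  k <- 1L
  for (p in sub) for (pos in seq_len(n)) {
    out[[k]] <- append(p, n, after = pos - 1L)
    k <- k + 1L
  }
  out
}

#' Count automorphisms by brute-force enumeration
#'
#' Independent oracle for [count_automorphisms()]: enumerates all
#' vertex permutations that respect colors (permuting only within
#' color classes) and counts those preserving the directed edge
#' relation. Exact but combinatorial; refuses graphs with more than 10
#' vertices.
#'
#' @param graph A `colored_graph`.
#' @return The automorphism count as a numeric scalar.
#' @export
brute_force_automorphisms <- function(graph) {
  n <- nrow(graph$vertices)
  if (n > 10)
    stop("brute-force enumeration is limited to 10 vertices", call. = FALSE)
  if (n == 0) return(1)
  adj <- matrix(FALSE, n, n, dimnames = list(graph$vertices$id,
                                             graph$vertices$id))
  if (nrow(graph$edges) > 0)
    adj[cbind(graph$edges$from, graph$edges$to)] <- TRUE
  classes <- split(seq_len(n), graph$vertices$color)
  class_perms <- lapply(classes, function(cl) {
    lapply(all_permutations(length(cl)), function(p) cl[p])
  })
  count <- 0L
  recurse <- function(ci, perm) {
    if (ci > length(class_perms)) {
      if (all(adj[perm, perm] == adj)) count <<- count + 1L
      return(invisible(NULL))
    }
    for (p in class_perms[[ci]]) {
      perm[classes[[ci]]] <- p
      recurse(ci + 1L, perm)
    }
  }
  recurse(1L, integer(n))
  as.numeric(count)
}

#' Export a colored graph
#'
#' `write_colored_graph_graphml()` writes GraphML with a `color`
#' vertex attribute; `write_colored_graph_dimacs()` writes a
#' DIMACS-like plain-text format: a `p edge <n> <m>` header, one
#' `n <vertex> <color-index>` line per vertex and one `a <from> <to>`
#' arc line per directed edge.
#'
#' @param graph A `colored_graph`.
#' @param path File path.
#' @export
write_colored_graph_graphml <- function(graph, path) {
  g <- igraph::graph_from_data_frame(
    graph$edges, directed = TRUE, vertices = as.data.frame(graph$vertices))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname write_colored_graph_graphml
#' @export
write_colored_graph_dimacs <- function(graph, path) {
  ci <- as.integer(factor(graph$vertices$color))
  idx <- stats::setNames(seq_len(nrow(graph$vertices)), graph$vertices$id)
  lines <- c(sprintf("p edge %d %d", nrow(graph$vertices), nrow(graph$edges)),
             sprintf("n %d %d", idx[graph$vertices$id], ci),
             if (nrow(graph$edges) > 0)
               sprintf("a %d %d", idx[graph$edges$from], idx[graph$edges$to]))
  writeLines(lines, path)
  invisible(path)
}
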