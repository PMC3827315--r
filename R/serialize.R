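#' Read and write networks as JSON
#'
#' JSON is the canonical on-disk form for networks: neurons,
#' connections (without the derived `plastic` flag, which is recomputed
#' on load) and the model parameters.
#'
#' @param net A `plastic_network`.
#' @param path File path.
#' @return `write_network_json()` returns `path` invisibly;
#'   `read_network_json()` returns a `plastic_network`.
#' @export
write_network_json <- function(net, path) {
  obj <- list(
    neurons = net$neurons,
    connections = net$connections[, c("from", "to", "sign", "weight")],
    params = net$params)
  jsonlite::write_json(obj, path, dataframe = "columns",
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_network_json
#' @export
read_network_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  neurons <- tibble::as_tibble(obj$neurons)
  neurons$label <- as.character(neurons$label)  # all-NA columns read as logical
  plastic_network(
    neurons = neurons,
    connections = tibble::as_tibble(obj$connections),
    lambda = obj$params$lambda, eta = obj$params$eta,
    w_min = obj$params$w_min, w_max = obj$params$w_max)
}

#' Convert a network to an igraph object
#'
#' Vertices carry `role`, `kind` and `bias`; edges carry `sign`,
#' `weight` and `plastic`.
#'
#' @param net A `plastic_network`.
#' @return An `igraph` graph.
#' @export
network_to_igraph <- function(net) {
  igraph::graph_from_data_frame(
    net$connections,
    directed = TRUE,
    vertices = as.data.frame(net$neurons))
}

#' Export a network as GraphML
#'
#' @inheritParams write_network_json
#' @export
write_network_graphml <- function(net, path) {
  igraph::write_graph(network_to_igraph(net), path, format = "graphml")
  invisible(path)
}

#' Export a network in Graphviz DOT format
#'
#' Rendering convention: modulatory neurons are diamonds, standard
#' neurons ellipses; inputs are grey, outputs doubled; excitatory
#' connections are black, inhibitory connections red; plastic
#' connections dashed. Edge width scales with magnitude.
#'
#' @inheritParams write_network_json
#' @export
write_network_dot <- function(net, path) {
  esc <- function(x) gsub('"', '\\"', x, fixed = TRUE)
  lines <- c("digraph plastic_network {", "  rankdir=BT;")
  for (i in seq_len(nrow(net$neurons))) {
    nr <- net$neurons[i, ]
    shape <- if (nr$kind == "modulatory") "diamond" else "ellipse"
    fill <- switch(nr$role, input = "grey85",
                   output = "lightyellow", "white")
    peri <- if (nr$role == "output") 2L else 1L
    lines <- c(lines, sprintf(
      '  "%s" [shape=%s, style=filled, fillcolor=%s, peripheries=%d, label="%s"];',
      esc(nr$id), shape, fill, peri,
      esc(if (is.na(nr$label)) nr$id else nr$label)))
  }
  for (i in seq_len(nrow(net$connections))) {
    cn <- net$connections[i, ]
    col <- if (cn$sign < 0) "red" else "black"
    sty <- if (isTRUE(cn$plastic)) "dashed" else "solid"
    lines <- c(lines, sprintf(
      '  "%s" -> "%s" [color=%s, style=%s, penwidth=%.2f];',
      esc(cn$from), esc(cn$to), col, sty, 0.5 + cn$weight))
  }
  writeLines(c(lines, "}"), path)
  invisible(path)
}
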