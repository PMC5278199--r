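#' Explored transition graph
#'
#' Runs a bounded breadth-first exploration from a ground dish and returns
#' the transition graph: nodes are canonical dish strings, edges are rule
#' applications labeled by rule. Useful for exporting a pathway's state
#' space to Graphviz.
#'
#' @param kb An `ss_kb`.
#' @param start A ground `ss_dish` or the name of a dish in `kb$dishes`.
#' @param max_depth Exploration depth bound.
#' @param max_states Cap on explored states.
#' @return List with `edges` (data frame `from`, `to`, `label`), `nodes`
#'   (character), and `igraph` (an [igraph::graph_from_data_frame()] object).
#' @examples
#' g <- transition_graph(vending_fixture(), "DollarDish", max_depth = 3)
#' g$edges
#' @export
transition_graph <- function(kb, start, max_depth = Inf, max_states = 5000L) {
  res <- forward_search(
    kb, start,
    search_goal(dish(dvar = "anything"), max_solutions = 1,
                max_depth = max_depth, min_steps = Inf),
    graph = TRUE, max_states = max_states
  )
  edges <- res$edges
  nodes <- unique(c(if (is.character(start)) kb$dishes[[start]]$key else start$key,
                    edges$from, edges$to))
  ig <- if (nrow(edges) > 0L) {
    igraph::graph_from_data_frame(edges, directed = TRUE,
                                  vertices = data.frame(name = nodes))
  } else {
    igraph::make_empty_graph(n = length(nodes)) |>
      igraph::set_vertex_attr("name", value = nodes)
  }
  list(edges = edges, nodes = nodes, igraph = ig)
}

#' Write a transition graph in Graphviz DOT format
#'
#' @param g Result of [transition_graph()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_transition_dot <- function(g, path) {
  esc <- function(x) gsub("\"", "\\\\\"", x)
  lines <- c("digraph dishes {",
             "  node [shape=box, fontsize=10];",
             vapply(g$nodes, function(n) sprintf("  \"%s\";", esc(n)), character(1)),
             if (nrow(g$edges) > 0L) {
               vapply(seq_len(nrow(g$edges)), function(i) {
                 sprintf("  \"%s\" -> \"%s\" [label=\"%s\"];",
                         esc(g$edges$from[i]), esc(g$edges$to[i]),
                         esc(g$edges$label[i]))
               }, character(1))
             },
             "}")
  writeLines(lines, path)
  invisible(path)
}
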