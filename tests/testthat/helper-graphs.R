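# shared fixtures: random graphs built in code, igraph conversion

# Erdos-Renyi G(n, p) as a ppin, deterministic under seed
rand_ppin <- function(n, p, seed, connected_only = FALSE) {
  stopifnot(n >= 2)
  set.seed(seed)
  repeat {
    pairs <- t(combn(n, 2))
    keep <- runif(nrow(pairs)) < p
    labels <- sprintf("N%03d", seq_len(n))
    net <- ppin(data.frame(a = labels[pairs[keep, 1]],
                           b = labels[pairs[keep, 2]],
                           stringsAsFactors = FALSE),
                nodes = labels)
    if (!connected_only) return(net)
    st <- summarize_topology(net)
    if (st$n_components == 1L && st$n_edges > 0L) return(net)
  }
}

as_igraph <- function(net) {
  g <- igraph::make_empty_graph(n = n_nodes(net), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = node_names(net))
  e <- net$edges
  if (nrow(e))
    g <- igraph::add_edges(g, rbind(match(e$a, net$nodes),
                                    match(e$b, net$nodes)))
  g
}

clique_keys <- function(cliques) {
  sort(vapply(lapply(cliques, sort), paste, character(1), collapse = ","))
}

# tiny labelled corpus for io tests
toy_corpus <- function(rows) {
  brdnet:::new_corpus(data.frame(
    protein_a = vapply(rows, `[`, character(1), 1),
    protein_b = vapply(rows, `[`, character(1), 2),
    source = rep("custom", length(rows)),
    evidence_count = rep(1L, length(rows)),
    confidence = rep(NA_real_, length(rows)), stringsAsFactors = FALSE))
}
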