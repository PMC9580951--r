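#' Construct a protein-protein interaction network
#'
#' The central container of the package: a simple undirected graph whose
#' nodes are gene symbols and whose edges are physical interactions.
#' Edges are stored canonically (`a <= b` lexicographically) and
#' deduplicated. Self-loops (homo-dimerisation potential) are kept only
#' when `simple = FALSE`.
#'
#' @param edges a data frame with character columns `a` and `b` and an
#'   optional numeric `weight` column (defaults to 1), or `NULL` for an
#'   edgeless network.
#' @param nodes additional isolated node names to include.
#' @param simple logical; if `TRUE` (default) self-loops are dropped.
#' @param weighted logical; whether edge weights are meaningful
#'   (evidence counts in the family-family network).
#' @return an object of class `ppin`.
#' @examples
#' net <- ppin(data.frame(a = c("BRD4", "BRD4"), b = c("TRIM28", "CBP")))
#' net
#' @export
ppin <- function(edges = NULL, nodes = character(), simple = TRUE,
                 weighted = FALSE) {
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(a = character(), b = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
  } else {
    stopifnot(all(c("a", "b") %in% names(edges)))
    a <- toupper(trimws(as.character(edges$a)))
    b <- toupper(trimws(as.character(edges$b)))
    if (any(!nzchar(a)) || any(!nzchar(b)))
      stop("empty node symbol in edge table", call. = FALSE)
    w <- if ("weight" %in% names(edges)) as.numeric(edges$weight) else
      rep(1, length(a))
    swap <- a > b
    tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
    keep <- !duplicated(paste(a, b, sep = "\r"))
    edges <- data.frame(a = a[keep], b = b[keep], weight = w[keep],
                        stringsAsFactors = FALSE)
    if (simple) edges <- edges[edges$a != edges$b, , drop = FALSE]
    rownames(edges) <- NULL
  }
  nodes <- toupper(trimws(as.character(nodes)))
  all_nodes <- sort(unique(c(edges$a, edges$b, nodes[nzchar(nodes)])))
  structure(list(nodes = all_nodes, edges = edges, simple = simple,
                 weighted = weighted),
            class = "ppin")
}

#' @export
print.ppin <- function(x, ...) {
  nl <- sum(x$edges$a == x$edges$b)
  cat(sprintf("<ppin> %d nodes, %d edges%s%s%s\n",
              n_nodes(x), n_edges(x),
              if (nl > 0L) sprintf(" (+%d self-loops)", nl) else "",
              if (x$weighted) ", weighted" else "",
              if (x$simple) "" else ", self-loops allowed"))
  invisible(x)
}

#' Number of nodes in a network
#' @param net a [ppin] object.
#' @return integer count.
#' @export
n_nodes <- function(net) length(net$nodes)

#' Number of edges in a network
#' @param net a [ppin] object.
#' @param self_loops logical; count self-loop edges as well?
#' @return integer count.
#' @export
n_edges <- function(net, self_loops = FALSE) {
  if (self_loops) nrow(net$edges) else sum(net$edges$a != net$edges$b)
}

#' Node names of a network
#' @param net a [ppin] object.
#' @return character vector, sorted.
#' @export
node_names <- function(net) net$nodes

#' Node degrees
#'
#' A self-loop contributes 2 to its node's degree, so the handshake
#' identity sum(degrees) = 2|E| holds with self-loops counted.
#'
#' @param net a [ppin] object.
#' @param self_loops logical; include self-loop contributions?
#' @return named integer vector over all nodes.
#' @export
degrees <- function(net, self_loops = TRUE) {
  d <- integer(n_nodes(net))
  names(d) <- net$nodes
  e <- net$edges
  plain <- e$a != e$b
  tab <- table(factor(c(e$a[plain], e$b[plain]), levels = net$nodes))
  d <- d + as.integer(tab)
  if (self_loops) {
    loops <- table(factor(e$a[!plain], levels = net$nodes))
    d <- d + 2L * as.integer(loops)
  }
  names(d) <- net$nodes
  d
}

# adjacency list of neighbor indices, self-loops excluded
adj_list <- function(net) {
  n <- n_nodes(net)
  e <- net$edges[net$edges$a != net$edges$b, , drop = FALSE]
  ai <- match(e$a, net$nodes)
  bi <- match(e$b, net$nodes)
  from <- c(ai, bi); to <- c(bi, ai)
  ord <- order(from, to)
  unname(split(to[ord], factor(from[ord], levels = seq_len(n))))
}

#' Export a network as an edge-list table
#' @param net a [ppin] object.
#' @param path optional file to write a tab-separated edge list to.
#' @return invisibly, the edge data frame (`a`, `b`, `weight`).
#' @export
edge_table <- function(net, path = NULL) {
  e <- net$edges[order(net$edges$a, net$edges$b), , drop = FALSE]
  rownames(e) <- NULL
  if (!is.null(path))
    utils::write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(e)
}
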