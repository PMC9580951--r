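#' Build a network from an interaction corpus
#'
#' @param corpus an `interaction_corpus` (rows need not be canonical;
#'   unordered duplicates collapse to one edge).
#' @param keep_self_loops keep records with `protein_a == protein_b`?
#' @param weighted carry `evidence_count` as the edge weight?
#' @return a [ppin]. An empty corpus gives an empty network.
#' @export
build_network <- function(corpus, keep_self_loops = FALSE, weighted = FALSE) {
  if (nrow(corpus) == 0L)
    return(ppin(NULL, simple = !keep_self_loops, weighted = weighted))
  merged <- merge_corpora(list(corpus))
  ppin(data.frame(a = merged$protein_a, b = merged$protein_b,
                  weight = merged$evidence_count,
                  stringsAsFactors = FALSE),
       simple = !keep_self_loops, weighted = weighted)
}

check_family <- function(net, family, allow_missing = TRUE) {
  family <- toupper(trimws(as.character(family)))
  family <- unique(family[nzchar(family)])
  if (!length(family)) stop("family set is empty", call. = FALSE)
  missing <- setdiff(family, net$nodes)
  if (length(missing) && !allow_missing)
    stop("family members absent from network: ",
         paste(missing, collapse = ", "), call. = FALSE)
  list(present = intersect(family, net$nodes), missing = missing,
       family = family)
}

#' Extract the family neighborhood subnetwork
#'
#' Returns the subgraph induced on the family members present in the
#' network together with all their direct interactors — including the
#' interactor-interactor edges, which is what makes the family
#' neighborhood network far denser than the edges incident to the family
#' alone.
#'
#' @param net a [ppin] (the global network).
#' @param family character vector of family gene symbols; members absent
#'   from the network are reported via the `missing_family` attribute,
#'   not fatal.
#' @return a [ppin] with attributes `family_present` and `missing_family`.
#' @export
extract_family_subnetwork <- function(net, family) {
  fam <- check_family(net, family)
  adj <- adj_list(net)
  fidx <- match(fam$present, net$nodes)
  keep_idx <- sort(unique(c(fidx, unlist(adj[fidx], use.names = FALSE))))
  keep <- net$nodes[keep_idx]
  e <- net$edges
  sel <- e$a %in% keep & e$b %in% keep
  out <- ppin(e[sel, , drop = FALSE], nodes = keep, simple = net$simple,
              weighted = net$weighted)
  attr(out, "family_present") <- fam$present
  attr(out, "missing_family") <- fam$missing
  out
}

#' Extract the intra-family (family-family) network
#'
#' Keeps only interactions where both partners are family members,
#' weighted by evidence count, with self-loops retained (homo-dimer /
#' oligomer potential). Nodes are the family members with at least one
#' intra-family edge or self-loop.
#'
#' @param net a [ppin]; used to restrict the corpus to pairs actually in
#'   the network when `corpus` lacks some of them (may be `NULL`).
#' @param family character vector of family gene symbols.
#' @param corpus the merged `interaction_corpus` supplying evidence
#'   counts.
#' @return a weighted [ppin] with self-loops.
#' @export
extract_family_family_network <- function(net = NULL, family, corpus) {
  family <- toupper(trimws(as.character(family)))
  merged <- merge_corpora(list(corpus))
  sel <- merged$protein_a %in% family & merged$protein_b %in% family
  e <- as.data.frame(merged)[sel, , drop = FALSE]
  if (nrow(e) == 0L) return(ppin(NULL, simple = FALSE, weighted = TRUE))
  ppin(data.frame(a = e$protein_a, b = e$protein_b,
                  weight = e$evidence_count, stringsAsFactors = FALSE),
       simple = FALSE, weighted = TRUE)
}

#' Graph-level topology summary
#'
#' Density uses the simple-graph formula (self-loops excluded); radius,
#' diameter and eccentricity are computed on the largest connected
#' component; the average shortest path averages over connected node
#' pairs only; the average clustering coefficient averages local
#' coefficients over nodes of degree >= 2 (their coefficient is undefined
#' below that; set `count_low_degree_as_zero` to include them as 0). The
#' compactness rule classifies the graph as dense when E ~ V^k with
#' 1 < k < 2, sparse otherwise.
#'
#' @param net a [ppin].
#' @param count_low_degree_as_zero include degree<2 nodes as 0 in the
#'   clustering mean?
#' @return a list of class `topology_summary`.
#' @export
summarize_topology <- function(net, count_low_degree_as_zero = FALSE) {
  n <- n_nodes(net)
  if (n == 0L) stop("empty network", call. = FALSE)
  m <- n_edges(net, self_loops = FALSE)
  density <- if (n > 1L) 2 * m / (n * (n - 1)) else NA_real_
  adj <- adj_list(net)
  labs <- component_labels(adj, n)
  n_comp <- max(labs)
  comp_sizes <- tabulate(labs)
  giant <- which(labs == which.max(comp_sizes))
  radius <- diameter <- NA_integer_
  avg_path <- NA_real_
  if (n > 1L) {
    path_sum <- 0
    path_n <- 0
    ecc_giant <- rep(NA_integer_, length(giant))
    gi <- 0L
    for (s in seq_len(n)) {
      d <- bfs_distances(adj, s, n)
      reach <- d[!is.na(d) & d > 0L]
      path_sum <- path_sum + sum(reach)
      path_n <- path_n + length(reach)
      if (labs[s] == labs[giant[1L]]) {
        gi <- gi + 1L
        ecc_giant[gi] <- if (length(reach)) max(d[!is.na(d)]) else 0L
      }
    }
    if (path_n > 0) avg_path <- path_sum / path_n  # ordered pairs cancel
    if (length(giant) > 1L) {
      radius <- min(ecc_giant)
      diameter <- max(ecc_giant)
    } else {
      radius <- diameter <- 0L
    }
  }
  cl <- local_clustering(adj, n)
  if (count_low_degree_as_zero) cl[is.na(cl)] <- 0
  avg_clust <- if (all(is.na(cl))) NA_real_ else mean(cl, na.rm = TRUE)
  k_exp <- if (n > 1L && m > 0L) log(m) / log(n) else NA_real_
  compact <- if (!is.na(k_exp) && k_exp > 1 && k_exp < 2) "dense" else "sparse"
  structure(list(n_nodes = n, n_edges = m,
                 n_self_loops = nrow(net$edges) - m,
                 density = density, radius = radius, diameter = diameter,
                 average_shortest_path = avg_path,
                 average_clustering = avg_clust,
                 n_components = n_comp,
                 compactness_exponent = k_exp,
                 compactness_class = compact),
            class = "topology_summary")
}

#' @export
print.topology_summary <- function(x, ...) {
  cat(sprintf(paste0("<topology_summary> V=%d E=%d density=%.4g ",
                     "radius=%s diameter=%s avg_path=%.4g avg_clust=%.4g ",
                     "components=%d (%s)\n"),
              x$n_nodes, x$n_edges, x$density,
              format(x$radius), format(x$diameter),
              x$average_shortest_path, x$average_clustering,
              x$n_components, x$compactness_class))
  invisible(x)
}

#' Per-node centrality and coreness metrics
#'
#' Computes, natively, the node-level quantities used to compare the
#' family against the rest of the network: degree, betweenness (Brandes,
#' unnormalized unordered pair counts, endpoints excluded), closeness
#' (1 / sum of distances, where an unreachable pair contributes distance
#' |V| — the legacy convention that keeps closeness finite and comparable
#' on disconnected graphs), eccentricity within the node's own component,
#' eigenvector centrality (power iteration, max-normalized to 1), local
#' clustering coefficient (NA for degree < 2), and k-core number.
#'
#' @param net a simple [ppin] (no self-loops).
#' @param eigen_tol convergence tolerance for the eigenvector power
#'   iteration.
#' @return a data frame, one row per node: `node`, `degree`,
#'   `betweenness`, `closeness`, `eccentricity`, `eigenvector`,
#'   `clustering`, `core`.
#' @export
node_metrics <- function(net, eigen_tol = 1e-10) {
  n <- n_nodes(net)
  if (n == 0L) stop("empty network", call. = FALSE)
  if (any(net$edges$a == net$edges$b))
    stop("node_metrics requires a simple network; rebuild without self-loops",
         call. = FALSE)
  adj <- adj_list(net)
  deg <- lengths(adj)
  ecc <- integer(n)
  closeness <- numeric(n)
  for (s in seq_len(n)) {
    d <- bfs_distances(adj, s, n)
    finite <- d[!is.na(d)]
    ecc[s] <- max(finite)
    dd <- d[-s]
    dd[is.na(dd)] <- n
    closeness[s] <- if (n > 1L) 1 / sum(dd) else NA_real_
  }
  data.frame(node = net$nodes,
             degree = as.integer(deg),
             betweenness = brandes_betweenness(adj, n),
             closeness = closeness,
             eccentricity = ecc,
             eigenvector = eigenvector_centrality(adj, n, tol = eigen_tol),
             clustering = local_clustering(adj, n),
             core = core_numbers(adj, n),
             stringsAsFactors = FALSE)
}

#' Classify hub nodes and compare the family's hub share
#'
#' A hub is a node whose degree is strictly greater than the network's
#' mean degree. The family-vs-rest hub proportions are compared with a
#' 2x2 Pearson chi-square test.
#'
#' @param metrics a [node_metrics] data frame.
#' @param family character vector of family gene symbols.
#' @return a list of class `hub_report`: `mean_degree`, `hubs` (data
#'   frame: node, degree, is_hub, in_family), `counts` (2x2 table), and
#'   `test` (the chi-square `test_result`).
#' @export
classify_hubs <- function(metrics, family) {
  family <- toupper(trimws(as.character(family)))
  family <- unique(family[nzchar(family)])
  if (!length(family)) stop("family set is empty", call. = FALSE)
  mean_deg <- mean(metrics$degree)
  is_hub <- metrics$degree > mean_deg
  in_fam <- metrics$node %in% family
  counts <- matrix(c(sum(in_fam & is_hub), sum(in_fam & !is_hub),
                     sum(!in_fam & is_hub), sum(!in_fam & !is_hub)),
                   nrow = 2, byrow = TRUE,
                   dimnames = list(c("family", "non_family"),
                                   c("hub", "non_hub")))
  test <- tryCatch(chi_square_2x2(counts),
                   brdnet_degenerate_table = function(e) NULL)
  structure(list(mean_degree = mean_deg,
                 hubs = data.frame(node = metrics$node,
                                   degree = metrics$degree,
                                   is_hub = is_hub, in_family = in_fam,
                                   stringsAsFactors = FALSE),
                 hub_fraction = mean(is_hub),
                 counts = counts, test = test),
            class = "hub_report")
}

#' @export
print.hub_report <- function(x, ...) {
  cat(sprintf("<hub_report> mean degree %.3f; %d/%d hubs; family %d/%d hubs",
              x$mean_degree, sum(x$hubs$is_hub), nrow(x$hubs),
              x$counts["family", "hub"], sum(x$counts["family", ])))
  if (!is.null(x$test)) cat(sprintf("; chi-square p = %.3g", x$test$p_value))
  cat("\n")
  invisible(x)
}

#' Family-vs-rest chi-square at a metric threshold
#'
#' Cross-tabulates family membership against `metric > threshold` and
#' applies the 2x2 Pearson chi-square test (used for, e.g., the k-core
#' threshold comparison).
#'
#' @param metrics a [node_metrics] data frame.
#' @param family character vector of family gene symbols.
#' @param metric_name a numeric column of `metrics`.
#' @param threshold numeric cutoff (strict `>`). There is no default:
#'   the cutoff is a study choice, not a property of the data.
#' @return a `test_result` (see [chi_square_2x2]); a degenerate table
#'   (empty margin) raises a `brdnet_degenerate_table` condition.
#' @export
group_threshold_chisquare <- function(metrics, family, metric_name,
                                      threshold) {
  if (!metric_name %in% names(metrics) ||
      !is.numeric(metrics[[metric_name]]))
    stop("no numeric metric column named '", metric_name, "'",
         call. = FALSE)
  stopifnot(is.numeric(threshold), length(threshold) == 1L)
  family <- toupper(trimws(as.character(family)))
  above <- metrics[[metric_name]] > threshold
  in_fam <- metrics$node %in% family
  counts <- matrix(c(sum(in_fam & above), sum(in_fam & !above),
                     sum(!in_fam & above), sum(!in_fam & !above)),
                   nrow = 2, byrow = TRUE,
                   dimnames = list(c("family", "non_family"),
                                   c("above", "not_above")))
  chi_square_2x2(counts)
}
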