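#' Shortest-path distance matrix between family members
#'
#' BFS from each family member over the whole network, so paths may pass
#' through non-family nodes. Unreachable pairs get the sentinel `Inf`;
#' family members absent from the network are reported and their rows
#' and columns filled with the sentinel.
#'
#' @param net a [ppin].
#' @param family character vector of family gene symbols.
#' @return a symmetric numeric matrix with `Inf` sentinels, dimnames the
#'   sorted family symbols, and attribute `missing_family`.
#' @export
family_distance_matrix <- function(net, family) {
  family <- sort(unique(toupper(trimws(as.character(family)))))
  family <- family[nzchar(family)]
  if (!length(family)) stop("family set is empty", call. = FALSE)
  adj <- adj_list(net)
  n <- n_nodes(net)
  idx <- match(family, net$nodes)
  m <- matrix(Inf, length(family), length(family),
              dimnames = list(family, family))
  for (i in seq_along(family)) {
    if (is.na(idx[i])) next
    d <- bfs_distances(adj, idx[i], n)
    row <- d[idx]
    row[is.na(idx)] <- NA_integer_
    m[i, ] <- ifelse(is.na(row), Inf, row)
  }
  attr(m, "missing_family") <- family[is.na(idx)]
  m
}

#' Nodes at an exact shortest-path distance
#'
#' The radius-`s` neighborhood used by the modified similarity score:
#' nodes whose shortest-path distance from the focal node is exactly `s`
#' (not at most `s`); the focal node itself is never a member.
#'
#' @param net a [ppin].
#' @param node focal gene symbol (must be in the network).
#' @param s exact distance, integer >= 1.
#' @return character vector of node names.
#' @export
neighborhood_at_distance <- function(net, node, s) {
  s <- as.integer(s)
  if (is.na(s) || s < 1L) stop("s must be an integer >= 1", call. = FALSE)
  node <- toupper(trimws(node))
  i <- match(node, net$nodes)
  if (is.na(i)) stop("node '", node, "' not in network", call. = FALSE)
  d <- bfs_distances(adj_list(net), i, n_nodes(net))
  net$nodes[!is.na(d) & d == s]
}

#' Neighborhood similarity matrix at an exact shortest-path radius
#'
#' At `s = 1` this is the classic Jaccard similarity of direct neighbor
#' sets. At `s = 2` or `3` it is the modified similarity for indirect
#' interaction profiles: the number of distinct common partners at exact
#' distance `s`, divided by the number of distinct partners of either
#' protein at that distance (union). With `denominator = "sum"` the
#' denominator is instead the sum of the two neighborhood sizes, which
#' provably caps the score at 0.5 — retained only for comparison. The
#' two focal proteins are removed from each other's neighborhoods before
#' scoring (set `include_focal = TRUE` to keep them). Pairs whose
#' combined neighborhood is empty score 0.
#'
#' @param net a [ppin].
#' @param family character vector of family gene symbols (must be in the
#'   network).
#' @param s radius: 1, 2 or 3.
#' @param denominator `"union"` (default) or `"sum"`.
#' @param include_focal keep the focal pair in the neighborhoods?
#' @return a symmetric numeric matrix in [0,1] with attributes `radius`
#'   and `denominator`.
#' @export
similarity_matrix <- function(net, family, s = 2L,
                              denominator = c("union", "sum"),
                              include_focal = FALSE) {
  denominator <- match.arg(denominator)
  s <- as.integer(s)
  if (is.na(s) || !s %in% 1:3)
    stop("s must be 1, 2 or 3", call. = FALSE)
  family <- sort(unique(toupper(trimws(as.character(family)))))
  family <- family[nzchar(family)]
  idx <- match(family, net$nodes)
  if (anyNA(idx))
    stop("family members absent from network: ",
         paste(family[is.na(idx)], collapse = ", "), call. = FALSE)
  adj <- adj_list(net)
  n <- n_nodes(net)
  hoods <- lapply(idx, function(i) {
    d <- bfs_distances(adj, i, n)
    which(!is.na(d) & d == s)
  })
  k <- length(family)
  m <- matrix(0, k, k, dimnames = list(family, family))
  for (i in seq_len(k)) {
    for (j in i:k) {
      A <- hoods[[i]]
      B <- hoods[[j]]
      if (!include_focal) {
        drop <- c(idx[i], idx[j])
        A <- A[!A %in% drop]
        B <- B[!B %in% drop]
      }
      inter <- sum(A %in% B)
      denom <- if (denominator == "union")
        length(A) + length(B) - inter else length(A) + length(B)
      val <- if (denom == 0) 0 else inter / denom
      m[i, j] <- m[j, i] <- val
    }
  }
  attr(m, "radius") <- s
  attr(m, "denominator") <- denominator
  m
}

#' Leaf ordering from average-linkage hierarchical clustering
#'
#' Orders the rows of a symmetric distance or similarity matrix for
#' heatmap display. Similarity matrices are converted to distance as
#' `1 - S`; `Inf` sentinels in distance matrices are replaced by one
#' more than the largest finite entry. Rows are pre-sorted by label so
#' that tie-breaking is lexicographic and the ordering deterministic.
#'
#' @param m square symmetric numeric matrix with dimnames.
#' @param type `"auto"` (distance if the diagonal is all zero),
#'   `"distance"` or `"similarity"`.
#' @return character vector: the dendrogram leaf order.
#' @export
hierarchical_order <- function(m, type = c("auto", "distance",
                                           "similarity")) {
  type <- match.arg(type)
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop("m must be a square matrix", call. = FALSE)
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8,
                        check.attributes = FALSE)))
    stop("m must be symmetric", call. = FALSE)
  if (is.null(rownames(m))) rownames(m) <- colnames(m) <- seq_len(nrow(m))
  if (type == "auto")
    type <- if (all(diag(m) == 0)) "distance" else "similarity"
  d <- if (type == "similarity") 1 - m else m
  d[!is.finite(d)] <- max(d[is.finite(d)], 0) + 1
  ord <- order(rownames(d))
  d <- d[ord, ord, drop = FALSE]
  if (nrow(d) < 2L) return(rownames(d))
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  rownames(d)[hc$order]
}
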