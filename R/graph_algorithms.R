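# Native unweighted-graph primitives. All routines take an adjacency list
# of integer neighbor indices (self-loops already excluded) plus the node
# count, and are written for the moderate sizes of family subnetworks;
# correctness is cross-checked against igraph and brute force in the tests.

# single-source BFS; returns integer distances, NA when unreachable
bfs_distances <- function(adj, s, n = length(adj)) {
  dist <- rep.int(NA_integer_, n)
  dist[s] <- 0L
  frontier <- s
  d <- 0L
  while (length(frontier)) {
    d <- d + 1L
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- nxt[is.na(dist[nxt])]
    dist[nxt] <- d
    frontier <- nxt
  }
  dist
}

all_pairs_distances <- function(adj, n = length(adj)) {
  vapply(seq_len(n), function(s) bfs_distances(adj, s, n), integer(n))
}

# connected component labels (1-based, by discovery from lowest index)
component_labels <- function(adj, n = length(adj)) {
  lab <- rep.int(0L, n)
  comp <- 0L
  for (s in seq_len(n)) {
    if (lab[s] > 0L) next
    comp <- comp + 1L
    reach <- which(!is.na(bfs_distances(adj, s, n)))
    lab[reach] <- comp
  }
  lab
}

# Brandes' algorithm for unweighted betweenness; returns unnormalized
# scores where each unordered dependency pair is counted once and path
# endpoints are excluded.
brandes_betweenness <- function(adj, n = length(adj)) {
  bc <- numeric(n)
  for (s in seq_len(n)) {
    sigma <- numeric(n); sigma[s] <- 1
    dist <- rep.int(-1L, n); dist[s] <- 0L
    preds <- vector("list", n)
    visited <- integer(0)
    frontier <- s
    while (length(frontier)) {
      visited <- c(visited, frontier)
      nxt <- integer(0)
      for (v in frontier) {
        for (w in adj[[v]]) {
          if (dist[w] < 0L) {
            dist[w] <- dist[v] + 1L
            nxt <- c(nxt, w)
          }
          if (dist[w] == dist[v] + 1L) {
            sigma[w] <- sigma[w] + sigma[v]
            preds[[w]] <- c(preds[[w]], v)
          }
        }
      }
      frontier <- unique(nxt)
    }
    delta <- numeric(n)
    for (w in rev(visited)) {
      for (v in preds[[w]])
        delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
      if (w != s) bc[w] <- bc[w] + delta[w]
    }
  }
  bc / 2
}

# k-core numbers by iterative minimum-degree peeling
core_numbers <- function(adj, n = length(adj)) {
  deg <- lengths(adj)
  core <- integer(n)
  alive <- rep.int(TRUE, n)
  k <- 0L
  for (i in seq_len(n)) {
    cand <- which(alive)
    v <- cand[which.min(deg[cand])]
    k <- max(k, deg[v])
    core[v] <- k
    alive[v] <- FALSE
    nb <- adj[[v]]
    nb <- nb[alive[nb]]
    deg[nb] <- deg[nb] - 1L
  }
  core
}

# principal-eigenvector centrality by power iteration on A + I (the shift
# removes bipartite period-2 oscillation without changing eigenvectors),
# max-normalized so the top node scores 1
eigenvector_centrality <- function(adj, n = length(adj), tol = 1e-10,
                                   max_iter = 100000L) {
  if (n == 0L) stop("eigenvector centrality undefined on an empty graph",
                    call. = FALSE)
  if (all(lengths(adj) == 0L)) return(rep(0, n))
  x <- rep(1 / sqrt(n), n)
  for (it in seq_len(max_iter)) {
    x_new <- vapply(seq_len(n), function(i) sum(x[adj[[i]]]), numeric(1)) + x
    x_new <- x_new / sqrt(sum(x_new^2))
    if (max(abs(x_new - x)) < tol) {
      x <- x_new
      break
    }
    x <- x_new
  }
  x / max(x)
}

# local clustering coefficient: triangles / choose(degree, 2); NA when
# degree < 2 (undefined)
local_clustering <- function(adj, n = length(adj)) {
  vapply(seq_len(n), function(i) {
    nb <- adj[[i]]
    k <- length(nb)
    if (k < 2L) return(NA_real_)
    links <- sum(vapply(nb, function(v) sum(adj[[v]] %in% nb), integer(1)))
    (links / 2) / (k * (k - 1) / 2)
  }, numeric(1))
}
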