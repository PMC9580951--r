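test_that("build_network collapses duplicates and controls self-loops", {
  corp <- toy_corpus(list(c("A", "B"), c("B", "A"), c("A", "A")))
  net <- build_network(corp, keep_self_loops = FALSE)
  expect_equal(n_nodes(net), 2L)
  expect_equal(n_edges(net), 1L)

  net_l <- build_network(corp, keep_self_loops = TRUE)
  expect_equal(n_nodes(net_l), 2L)
  expect_equal(n_edges(net_l), 1L)
  expect_equal(n_edges(net_l, self_loops = TRUE), 2L)

  empty <- build_network(toy_corpus(list())[0, ])
  expect_equal(n_nodes(empty), 0L)
})

test_that("degree sum identity holds with and without self-loops", {
  set.seed(3)
  for (i in 1:10) {
    net <- rand_ppin(20, 0.25, seed = 100 + i)
    expect_equal(sum(degrees(net)), 2L * n_edges(net))
  }
  corp <- toy_corpus(list(c("A", "B"), c("A", "A")))
  net <- build_network(corp, keep_self_loops = TRUE)
  expect_equal(sum(degrees(net)), 2L * n_edges(net, self_loops = TRUE))
})

test_that("family subnetwork is the induced closure on family + neighbors", {
  # star: family = center -> whole star
  star <- ppin(data.frame(a = "C", b = c("L1", "L2", "L3")))
  sub <- extract_family_subnetwork(star, "C")
  expect_equal(n_nodes(sub), 4L)
  expect_equal(n_edges(sub), 3L)

  # triangle with family = one vertex includes the opposite edge
  tri <- ppin(data.frame(a = c("A", "A", "B"), b = c("B", "C", "C")))
  sub <- extract_family_subnetwork(tri, "A")
  expect_equal(n_edges(sub), 3L)

  # brute-force induced-subgraph oracle on random graphs
  for (i in 1:15) {
    net <- rand_ppin(30, 0.15, seed = 200 + i)
    fam <- sample(node_names(net), 4)
    sub <- extract_family_subnetwork(net, fam)
    e <- net$edges
    nbrs <- unique(c(e$b[e$a %in% fam], e$a[e$b %in% fam]))
    keep <- union(fam, nbrs)
    brute <- e[e$a %in% keep & e$b %in% keep, ]
    expect_setequal(node_names(sub), keep)
    expect_equal(sort(paste(sub$edges$a, sub$edges$b)),
                 sort(paste(brute$a, brute$b)))
    # node count relation: |V(sub)| - family = distinct non-family interactors
    expect_equal(n_nodes(sub) - length(fam),
                 length(setdiff(nbrs, fam)))
  }
  expect_error(extract_family_subnetwork(star, character(0)), "empty")
})

test_that("family-family network keeps weights and self-loops", {
  corp <- toy_corpus(list(c("A", "B"), c("B", "A"), c("A", "A"),
                          c("A", "X"), c("X", "Y")))
  ff <- extract_family_family_network(NULL, c("A", "B", "C"), corp)
  expect_equal(sort(node_names(ff)), c("A", "B"))
  e <- ff$edges
  expect_equal(e$weight[e$a == "A" & e$b == "B"], 2)
  expect_equal(nrow(e[e$a == e$b, ]), 1L)

  none <- extract_family_family_network(NULL, c("P", "Q"), corp)
  expect_equal(n_nodes(none), 0L)
})

test_that("topology summary matches closed forms on a path graph", {
  p3 <- ppin(data.frame(a = c("A", "B"), b = c("B", "C")))
  st <- summarize_topology(p3)
  expect_equal(round(st$density, 3), 0.667)
  expect_equal(st$radius, 1L)
  expect_equal(st$diameter, 2L)
  expect_equal(round(st$average_shortest_path, 3), 1.333)
  expect_equal(st$average_clustering, 0)
  expect_equal(st$n_components, 1L)
  expect_equal(st$compactness_class, "sparse")
})

test_that("node metrics match closed forms on stars and cliques", {
  star <- ppin(data.frame(a = "C", b = c("L1", "L2", "L3", "L4")))
  m <- node_metrics(star)
  center <- m[m$node == "C", ]
  expect_equal(center$degree, 4L)
  expect_equal(center$betweenness, 6)
  expect_equal(center$eccentricity, 1L)
  expect_equal(center$eigenvector, 1)
  leaves <- m[m$node != "C", ]
  expect_true(all(leaves$betweenness == 0))
  expect_true(all(leaves$eccentricity == 2L))
  expect_true(all(is.na(leaves$clustering)))

  pairs <- t(combn(c("A", "B", "C", "D"), 2))
  k4 <- ppin(data.frame(a = pairs[, 1], b = pairs[, 2]))
  m4 <- node_metrics(k4)
  expect_true(all(m4$core == 3L))
  expect_true(all(m4$clustering == 1))
  expect_true(all(abs(m4$eigenvector - 1) < 1e-8))
})

test_that("all node metrics equal brute-force values on tiny graphs", {
  # exhaustive oracles: path enumeration for betweenness, peeling
  # simulation for cores, BFS matrix for distance-derived metrics
  brute_force_check <- function(net) {
    n <- n_nodes(net)
    e <- net$edges
    A <- matrix(0L, n, n, dimnames = list(net$nodes, net$nodes))
    A[cbind(e$a, e$b)] <- 1L
    A <- A + t(A)
    # BFS distances via repeated boolean matrix products
    D <- matrix(Inf, n, n); diag(D) <- 0
    reach <- diag(n) == 1
    P <- diag(n)
    for (d in 1:n) {
      P <- (P %*% A) > 0
      new <- P & !reach
      D[new] <- d
      reach <- reach | new
      if (all(reach) || !any(new)) break
    }
    m <- node_metrics(net)
    # degree / eccentricity / closeness
    expect_equal(m$degree, unname(rowSums(A)))
    finite_max <- apply(D, 1, function(r) max(r[is.finite(r)]))
    expect_equal(m$eccentricity, unname(as.integer(finite_max)))
    Dp <- D; Dp[!is.finite(Dp)] <- n
    expect_equal(m$closeness, unname(1 / (rowSums(Dp))))
    # betweenness by exhaustive shortest-path enumeration
    paths_through <- numeric(n)
    count_paths <- function(s, t) {
      # all shortest s-t paths by BFS layer expansion
      if (!is.finite(D[s, t]) || s == t) return(NULL)
      paths <- list(s)
      for (step in seq_len(D[s, t])) {
        paths <- do.call(c, lapply(paths, function(p) {
          last <- p[length(p)]
          nxt <- which(A[last, ] == 1 & D[s, ] == step & D[, t] == D[s, t] - step)
          lapply(nxt, function(v) c(p, v))
        }))
      }
      paths
    }
    for (s in 1:(n - 1)) for (t in (s + 1):n) {
      paths <- count_paths(s, t)
      if (is.null(paths)) next
      inner <- unlist(lapply(paths, function(p) p[-c(1, length(p))]))
      if (length(inner))
        for (v in inner) paths_through[v] <-
          paths_through[v] + 1 / length(paths)
    }
    expect_equal(m$betweenness, paths_through, tolerance = 1e-10)
    # cores by simulated peeling at increasing k
    core_oracle <- integer(n)
    for (k in 1:n) {
      alive <- rep(TRUE, n)
      repeat {
        dg <- rowSums(A[, alive, drop = FALSE])
        drop_ <- alive & dg < k
        if (!any(drop_)) break
        alive[drop_] <- FALSE
      }
      core_oracle[alive] <- k
      if (!any(alive)) break
    }
    expect_equal(m$core, core_oracle)
    # clustering from triangle counts
    tri <- diag(A %*% A %*% A) / 2
    kdeg <- rowSums(A)
    cl_oracle <- ifelse(kdeg < 2, NA_real_, tri / (kdeg * (kdeg - 1) / 2))
    expect_equal(m$clustering, unname(cl_oracle))
  }
  for (i in 1:25) brute_force_check(rand_ppin(sample(4:10, 1), 0.4,
                                              seed = 300 + i))
})

test_that("hub classification uses a strict mean-degree rule", {
  met <- data.frame(node = c("A", "B", "F1"), degree = c(1L, 1L, 4L))
  hr <- classify_hubs(met, "F1")
  expect_equal(hr$mean_degree, 2)
  expect_identical(hr$hubs$node[hr$hubs$is_hub], "F1")

  flat <- data.frame(node = c("A", "B", "F1"), degree = c(2L, 2L, 2L))
  hr2 <- classify_hubs(flat, "F1")
  expect_equal(sum(hr2$hubs$is_hub), 0L)
  expect_error(classify_hubs(met, character(0)), "empty")
})

test_that("threshold chi-square is null-calibrated and matches the 2x2 test", {
  set.seed(77)
  # identical distributions in both groups -> p far from significant
  metrics <- data.frame(node = sprintf("N%04d", 1:4000),
                        degree = rpois(4000, 20))
  fam <- sample(metrics$node, 500)
  res <- group_threshold_chisquare(metrics, fam, "degree", 20)
  expect_gt(res$p_value, 0.05)

  # hand table cross-check against chi_square_2x2
  above <- metrics$degree > 20
  in_fam <- metrics$node %in% fam
  tab <- matrix(c(sum(in_fam & above), sum(in_fam & !above),
                  sum(!in_fam & above), sum(!in_fam & !above)),
                2, byrow = TRUE)
  expect_equal(res$p_value, chi_square_2x2(tab)$p_value)
  expect_equal(res$statistic, chi_square_2x2(tab)$statistic)

  # planted shift detected
  metrics$degree[in_fam] <- metrics$degree[in_fam] + 15L
  res2 <- group_threshold_chisquare(metrics, fam, "degree", 20)
  expect_lt(res2$p_value, 0.01)

  # degenerate margin signals a typed condition
  expect_error(group_threshold_chisquare(metrics, fam, "degree", 1e6),
               class = "brdnet_degenerate_table")
})

test_that("topology and metrics agree with igraph on random graphs", {
  skip_if_not_installed("igraph")
  set.seed(42)
  for (i in 1:20) {
    net <- rand_ppin(sample(20:60, 1), runif(1, 0.05, 0.2), seed = 400 + i)
    g <- as_igraph(net)
    st <- summarize_topology(net)
    expect_equal(st$n_edges, igraph::ecount(g))
    expect_equal(st$density, igraph::edge_density(g))
    expect_equal(st$n_components, igraph::components(g)$no)
    dist_ref <- igraph::distances(g)
    fin <- dist_ref[upper.tri(dist_ref)]
    expect_equal(st$average_shortest_path,
                 mean(fin[is.finite(fin) & fin > 0]))
    m <- node_metrics(net)
    expect_equal(m$degree, unname(igraph::degree(g)))
    expect_equal(m$betweenness,
                 unname(igraph::betweenness(g, directed = FALSE)),
                 tolerance = 1e-10)
    expect_equal(m$core, unname(igraph::coreness(g)))
    expect_equal(m$eccentricity,
                 unname(as.integer(apply(dist_ref, 1, function(r)
                   max(r[is.finite(r)])))))
    dpen <- dist_ref
    dpen[!is.finite(dpen)] <- n_nodes(net)
    expect_equal(m$closeness, unname(1 / (rowSums(dpen))))
    cl_ref <- unname(igraph::transitivity(g, type = "localundirected",
                                          isolates = "NaN"))
    expect_equal(is.na(m$clustering), is.nan(cl_ref))
    expect_equal(m$clustering[!is.na(m$clustering)],
                 cl_ref[!is.nan(cl_ref)])
  }
})

test_that("eigenvector centrality matches igraph on connected graphs", {
  skip_if_not_installed("igraph")
  for (i in 1:10) {
    net <- rand_ppin(30, 0.15, seed = 500 + i, connected_only = TRUE)
    m <- node_metrics(net)
    ref <- igraph::eigen_centrality(as_igraph(net))$vector
    expect_equal(m$eigenvector, unname(ref), tolerance = 1e-6)
  }
})

test_that("core numbers are relabeling-invariant and monotone under deletion", {
  net <- rand_ppin(25, 0.2, seed = 600)
  m <- node_metrics(net)
  # permute labels
  set.seed(601)
  perm <- setNames(sample(node_names(net)), node_names(net))
  pnet <- ppin(data.frame(a = unname(perm[net$edges$a]),
                          b = unname(perm[net$edges$b])),
               nodes = unname(perm))
  mp <- node_metrics(pnet)
  mp_core <- setNames(mp$core, mp$node)
  expect_equal(unname(mp_core[unname(perm[m$node])]), m$core)
  # removing a node never raises another node's core number
  drop <- node_names(net)[5]
  e <- net$edges
  reduced <- ppin(e[e$a != drop & e$b != drop, ],
                  nodes = setdiff(node_names(net), drop))
  mr <- node_metrics(reduced)
  joined <- merge(m, mr, by = "node")
  expect_true(all(joined$core.y <= joined$core.x))
})
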