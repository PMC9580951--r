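test_that("family distances traverse non-family nodes and flag gaps", {
  # A - X - B with family {A, B}: distance 2 through the outsider
  net <- ppin(data.frame(a = c("A", "X"), b = c("X", "B")))
  d <- family_distance_matrix(net, c("A", "B"))
  expect_equal(d["A", "B"], 2)
  expect_equal(diag(d), c(A = 0, B = 0))

  # two components -> sentinel
  net2 <- ppin(data.frame(a = c("A", "C"), b = c("B", "D")))
  d2 <- family_distance_matrix(net2, c("A", "C"))
  expect_true(is.infinite(d2["A", "C"]))

  # absent member -> row of sentinels, reported
  d3 <- family_distance_matrix(net, c("A", "ZZ"))
  expect_equal(attr(d3, "missing_family"), "ZZ")
  expect_true(all(is.infinite(d3["ZZ", ])))
})

test_that("distance matrices equal igraph all-pairs BFS on random graphs", {
  skip_if_not_installed("igraph")
  for (i in 1:20) {
    net <- rand_ppin(sample(10:40, 1), runif(1, 0.08, 0.3), seed = 1100 + i)
    fam <- sort(sample(node_names(net), 5))
    d <- family_distance_matrix(net, fam)
    ref <- igraph::distances(as_igraph(net))[fam, fam]
    expect_equal(unclass(d)[fam, fam], ref)
  }
})

test_that("exact-distance neighborhoods are BFS levels", {
  net <- ppin(data.frame(a = c("A", "B"), b = c("B", "C")))
  expect_equal(neighborhood_at_distance(net, "A", 2), "C")
  expect_equal(neighborhood_at_distance(net, "A", 5), character(0))
  expect_error(neighborhood_at_distance(net, "A", 0), ">= 1")

  skip_if_not_installed("igraph")
  for (i in 1:10) {
    net <- rand_ppin(25, 0.12, seed = 1200 + i)
    g <- as_igraph(net)
    dref <- igraph::distances(g)
    for (s in 1:3) {
      v <- sample(node_names(net), 1)
      expect_setequal(neighborhood_at_distance(net, v, s),
                      names(which(dref[v, ] == s)))
    }
  }
})

test_that("similarity extremes: identical neighborhoods 1, disjoint 0", {
  # F1 and F2 both link only to X, Y: identical radius-1 neighborhoods
  net <- ppin(data.frame(a = c("F1", "F1", "F2", "F2", "F3"),
                         b = c("X", "Y", "X", "Y", "Z")))
  s1 <- similarity_matrix(net, c("F1", "F2", "F3"), s = 1)
  expect_equal(s1["F1", "F2"], 1)
  expect_equal(s1["F1", "F3"], 0)
  expect_true(all(s1 >= 0 & s1 <= 1))
  expect_equal(s1, t(s1))
})

test_that("similarity equals set-arithmetic brute force at radii 1-3", {
  # hand-built 7-node graph
  net <- ppin(data.frame(
    a = c("F1", "F1", "F2", "F2", "X1", "X2", "X3", "F3"),
    b = c("X1", "X2", "X2", "X3", "X3", "X4", "X4", "X4")))
  fam <- c("F1", "F2", "F3")
  brute <- function(s, denominator = "union") {
    hood <- function(v) neighborhood_at_distance(net, v, s)
    m <- matrix(0, 3, 3, dimnames = list(fam, fam))
    for (i in fam) for (j in fam) {
      A <- setdiff(hood(i), c(i, j))
      B <- setdiff(hood(j), c(i, j))
      inter <- length(intersect(A, B))
      den <- if (denominator == "union") length(union(A, B)) else
        length(A) + length(B)
      m[i, j] <- if (den == 0) 0 else inter / den
    }
    m
  }
  for (s in 1:3) {
    ours <- similarity_matrix(net, fam, s = s)
    expect_equal(unclass(ours)[fam, fam], brute(s), info = paste("s =", s))
    sums <- similarity_matrix(net, fam, s = s, denominator = "sum")
    expect_equal(unclass(sums)[fam, fam], brute(s, "sum"))
  }
})

test_that("radius-1 similarity is classic neighbor-set Jaccard", {
  skip_if_not_installed("igraph")
  for (i in 1:10) {
    net <- rand_ppin(20, 0.2, seed = 1300 + i)
    fam <- sort(sample(node_names(net), 4))
    ours <- similarity_matrix(net, fam, s = 1, include_focal = TRUE)
    ref <- igraph::similarity(as_igraph(net), method = "jaccard",
                              loops = FALSE)
    dimnames(ref) <- list(node_names(net), node_names(net))
    off <- ours[fam, fam]; diag(off) <- NA
    refm <- ref[fam, fam]; diag(refm) <- NA
    # igraph's jaccard keeps focal nodes in the neighbor sets, as does
    # include_focal = TRUE
    expect_equal(off, refm)
  }
})

test_that("similarity is invariant under node relabeling", {
  net <- rand_ppin(20, 0.2, seed = 1400)
  fam <- sort(sample(node_names(net), 4))
  set.seed(1401)
  perm <- setNames(sample(node_names(net)), node_names(net))
  pnet <- ppin(data.frame(a = unname(perm[net$edges$a]),
                          b = unname(perm[net$edges$b])),
               nodes = unname(perm))
  for (s in 1:2) {
    ours <- similarity_matrix(net, fam, s = s)
    theirs <- similarity_matrix(pnet, unname(perm[fam]), s = s)
    expect_equal(unclass(theirs)[perm[fam], perm[fam]],
                 matrix(unclass(ours)[fam, fam], 4, 4,
                        dimnames = list(unname(perm[fam]),
                                        unname(perm[fam]))))
  }
})

test_that("indirect similarity exceeds direct similarity on planted families", {
  # the qualitative radius effect: common indirect partners dominate
  wins <- 0L
  for (s in 1:10) {
    spec <- synthetic_spec(n_nodes = 600, family_size = 15,
                           family_degree_boost = 3, seed = 1500 + s)
    gen <- generate_network(spec)
    m1 <- similarity_matrix(gen$network, gen$family, s = 1)
    m2 <- similarity_matrix(gen$network, gen$family, s = 2)
    if (mean(m2[upper.tri(m2)]) > mean(m1[upper.tri(m1)])) wins <- wins + 1L
  }
  expect_gte(wins, 9L)
})

test_that("hierarchical leaf order groups identical and blocked rows", {
  m <- matrix(c(0, 0.1, 5, 5,
                0.1, 0, 5, 5,
                5, 5, 0, 0.2,
                5, 5, 0.2, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"),
                              c("A", "B", "C", "D")))
  ord <- hierarchical_order(m, type = "distance")
  expect_true(which(ord == "A") %in%
                c(which(ord == "B") - 1, which(ord == "B") + 1))
  # block contiguity
  expect_true(all(diff(sort(match(c("A", "B"), ord))) == 1))
  expect_true(all(diff(sort(match(c("C", "D"), ord))) == 1))

  # label invariance: permuting rows/cols leaves the partition intact
  p <- c(3, 1, 4, 2)
  mp <- m[p, p]
  ordp <- hierarchical_order(mp, type = "distance")
  expect_true(all(diff(sort(match(c("A", "B"), ordp))) == 1))
  expect_true(all(diff(sort(match(c("C", "D"), ordp))) == 1))
  expect_error(hierarchical_order(matrix(c(0, 1, 2, 0), 2, 2)),
               "symmetric")
})
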