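#' Enumerate maximal cliques (Bron-Kerbosch)
#'
#' Maximal cliques are the package's proxy for protein complexes:
#' complete subgraphs that cannot be extended by any adjacent vertex.
#' Enumeration uses Bron-Kerbosch with pivoting, seeded at the top level
#' in degeneracy order. Self-loops are ignored. Output is fully
#' deterministic: members sorted within each clique, cliques sorted
#' lexicographically.
#'
#' @param net a [ppin].
#' @param min_size smallest clique size to report (>= 2).
#' @return a `clique_set`: list with `cliques` (list of sorted character
#'   vectors), `min_size`, `maximal = TRUE`.
#' @export
maximal_cliques <- function(net, min_size = 3L) {
  min_size <- as.integer(min_size)
  if (is.na(min_size) || min_size < 2L)
    stop("min_size must be an integer >= 2", call. = FALSE)
  adj <- lapply(adj_list(net), sort)
  n <- n_nodes(net)
  out <- vector("list", 0L)
  if (n > 0L) {
    # degeneracy order by minimum-degree peeling
    deg <- lengths(adj)
    alive <- rep.int(TRUE, n)
    order_d <- integer(n)
    for (i in seq_len(n)) {
      cand <- which(alive)
      v <- cand[which.min(deg[cand])]
      order_d[i] <- v
      alive[v] <- FALSE
      nb <- adj[[v]]; nb <- nb[alive[nb]]
      deg[nb] <- deg[nb] - 1L
    }
    pos <- integer(n); pos[order_d] <- seq_len(n)
    res <- new.env(parent = emptyenv())
    res$cl <- vector("list", 256L); res$k <- 0L
    bk <- function(R, P, X) {
      if (!length(P) && !length(X)) {
        if (length(R) >= min_size) {
          res$k <- res$k + 1L
          if (res$k > length(res$cl)) res$cl <- c(res$cl, vector("list", length(res$cl)))
          res$cl[[res$k]] <- R
        }
        return(invisible(NULL))
      }
      PX <- c(P, X)
      # pivot: vertex of P union X covering most of P
      cover <- vapply(PX, function(u) sum(P %in% adj[[u]]), integer(1))
      u <- PX[which.max(cover)]
      for (v in P[!(P %in% adj[[u]])]) {
        nb <- adj[[v]]
        bk(c(R, v), P[P %in% nb], X[X %in% nb])
        P <- P[P != v]
        X <- c(X, v)
      }
      invisible(NULL)
    }
    for (i in seq_len(n)) {
      v <- order_d[i]
      nb <- adj[[v]]
      bk(v, nb[pos[nb] > i], nb[pos[nb] < i])
    }
    out <- res$cl[seq_len(res$k)]
  }
  cliques_out(lapply(out, function(idx) sort(net$nodes[idx])),
              min_size, maximal = TRUE)
}

cliques_out <- function(cl, min_size, maximal) {
  keys <- vapply(cl, paste, character(1), collapse = ",")
  cl <- cl[order(keys)]
  structure(list(cliques = cl, min_size = min_size, maximal = maximal),
            class = "clique_set")
}

#' @export
print.clique_set <- function(x, ...) {
  sz <- lengths(x$cliques)
  cat(sprintf("<clique_set> %d %scliques of size >= %d%s\n",
              length(x$cliques), if (x$maximal) "maximal " else "",
              x$min_size,
              if (length(sz)) sprintf(" (sizes %d-%d)", min(sz), max(sz))
              else ""))
  invisible(x)
}

#' Enumerate all cliques of a minimum size
#'
#' Returns every complete subgraph with at least `min_size` vertices —
#' not only the maximal ones — by expanding the subsets of each maximal
#' clique and deduplicating.
#'
#' @inheritParams maximal_cliques
#' @return a `clique_set` with `maximal = FALSE`.
#' @export
enumerate_cliques <- function(net, min_size = 3L) {
  min_size <- as.integer(min_size)
  if (is.na(min_size) || min_size < 2L)
    stop("min_size must be an integer >= 2", call. = FALSE)
  maximal <- maximal_cliques(net, min_size = min_size)
  seen <- new.env(parent = emptyenv())
  for (cl in maximal$cliques) {
    s <- length(cl)
    for (k in seq.int(min_size, s)) {
      subs <- utils::combn(cl, k, simplify = FALSE)
      for (sub in subs)
        assign(paste(sub, collapse = ","), TRUE, envir = seen)
    }
  }
  keys <- ls(seen)
  cliques_out(lapply(keys, function(k) strsplit(k, ",", fixed = TRUE)[[1L]]),
              min_size, maximal = FALSE)
}

#' Rebuild a network from a clique list
#'
#' The edge set is the union of all within-set pairs; repeating a set
#' changes nothing. This is the fixed-point harness for validating a
#' published maximal-clique table: running [maximal_cliques] on the
#' reconstruction must return exactly the input sets.
#'
#' @param clique_list list of character vectors, each with >= 2 members.
#' @return a simple [ppin].
#' @export
reconstruct_from_cliques <- function(clique_list) {
  if (!length(clique_list)) stop("empty clique list", call. = FALSE)
  if (any(lengths(clique_list) < 2L))
    stop("clique sets must have at least 2 members", call. = FALSE)
  pairs <- do.call(rbind, lapply(clique_list, function(s) {
    s <- sort(unique(toupper(trimws(s))))
    t(utils::combn(s, 2L))
  }))
  ppin(data.frame(a = pairs[, 1L], b = pairs[, 2L],
                  stringsAsFactors = FALSE))
}

#' Reference maximal cliques of the bromodomain family-family network
#'
#' The published list of 39 maximal cliques (size >= 3) formed by
#' bromodomain proteins among themselves, shipped as a plain-text
#' fixture: one clique per line, comma-separated gene symbols.
#'
#' @return list of character vectors.
#' @export
brd_reference_cliques <- function() {
  path <- system.file("extdata", "brd_maximal_cliques.csv",
                      package = "brdnet", mustWork = TRUE)
  lapply(strsplit(readLines(path, warn = FALSE), ",", fixed = TRUE),
         function(x) toupper(trimws(x)))
}

#' The 42 bromodomain-family gene symbols
#' @return character vector of length 42.
#' @export
brd_family <- function() {
  path <- system.file("extdata", "brd_family.txt",
                      package = "brdnet", mustWork = TRUE)
  toupper(trimws(readLines(path, warn = FALSE)))
}

#' Export a clique set as a table
#' @param cliques a `clique_set`.
#' @param path optional TSV output path.
#' @return data frame with columns `clique_id`, `size`, `members`.
#' @export
clique_table <- function(cliques, path = NULL) {
  df <- data.frame(clique_id = seq_along(cliques$cliques),
                   size = lengths(cliques$cliques),
                   members = vapply(cliques$cliques, paste, character(1),
                                    collapse = ","),
                   stringsAsFactors = FALSE)
  if (!is.null(path))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  df
}
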