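#' Specification for synthetic study data
#'
#' Bundles the knobs of the synthetic-data generator. The defaults
#' emulate the study conditions this package was built around: a
#' scale-free interactome carrying a planted family of 42 high-degree
#' proteins (the size of the human bromodomain family), and a
#' 50-set gene-set collection (the size of the MSigDB Hallmark
#' collection) with set sizes spanning the 32-200 range seen there.
#'
#' @param n_nodes number of proteins in the global network.
#' @param m preferential-attachment edges added per new node.
#' @param family_size number of planted family members.
#' @param family_degree_boost multiplier (>= 1) on the mean degree:
#'   after growth, each family node receives extra uniform edges until
#'   its degree reaches `boost * mean degree`.
#' @param n_sets number of gene sets to generate.
#' @param set_size_range integer range of set sizes.
#' @param planted_enrichment_fraction fraction of the designated set's
#'   members drawn from the signature.
#' @param seed RNG seed; identical spec + seed gives byte-identical
#'   outputs.
#' @return a list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_nodes = 2000L, m = 3L, family_size = 42L,
                           family_degree_boost = 3,
                           n_sets = 50L, set_size_range = c(32L, 200L),
                           planted_enrichment_fraction = 0.8,
                           seed = 1L) {
  stopifnot(n_nodes > family_size, m >= 1L, family_size >= 1L,
            family_degree_boost >= 1,
            n_sets >= 1L, length(set_size_range) == 2L,
            set_size_range[1] >= 1L,
            set_size_range[1] <= set_size_range[2],
            planted_enrichment_fraction >= 0,
            planted_enrichment_fraction <= 1)
  structure(list(n_nodes = as.integer(n_nodes), m = as.integer(m),
                 family_size = as.integer(family_size),
                 family_degree_boost = family_degree_boost,
                 n_sets = as.integer(n_sets),
                 set_size_range = as.integer(set_size_range),
                 planted_enrichment_fraction = planted_enrichment_fraction,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a scale-free network with a planted high-degree family
#'
#' Grows a preferential-attachment (Barabasi-Albert) graph — giving the
#' heavy-tailed degree distribution real interactomes display — then
#' plants the family: `family_size` nodes are chosen uniformly and
#' wired to extra uniformly-chosen partners until each reaches
#' `family_degree_boost` times the post-growth mean degree. Family
#' nodes are labelled `FAMxx`, the rest `GENExxxxx`.
#'
#' @param spec a [synthetic_spec].
#' @return list: `network` (a simple [ppin]) and `family` (character
#'   vector of the planted labels).
#' @export
generate_network <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_nodes; m <- spec$m
  if (m >= n) stop("m must be smaller than n_nodes", call. = FALSE)
  with_seed(spec$seed, {
    # seed graph: complete on m+1 nodes, then preferential attachment
    m0 <- m + 1L
    init <- utils::combn(m0, 2L)
    n_extra <- (n - m0) * m
    ea <- integer(ncol(init) + n_extra)
    eb <- integer(ncol(init) + n_extra)
    ea[seq_len(ncol(init))] <- init[1L, ]
    eb[seq_len(ncol(init))] <- init[2L, ]
    n_e <- ncol(init)
    # endpoint multiset for degree-proportional sampling
    ends <- integer(2L * (n_e + n_extra))
    ends[seq_len(2L * n_e)] <- c(init[1L, ], init[2L, ])
    n_ends <- 2L * n_e
    for (v in seq.int(m0 + 1L, n)) {
      targets <- integer(0)
      while (length(targets) < m) {
        cand <- ends[sample.int(n_ends, m)]
        targets <- unique(c(targets, cand))
      }
      targets <- targets[seq_len(m)]
      for (t in targets) {
        n_e <- n_e + 1L
        ea[n_e] <- v; eb[n_e] <- t
        ends[n_ends + 1L] <- v; ends[n_ends + 2L] <- t
        n_ends <- n_ends + 2L
      }
    }
    ea <- ea[seq_len(n_e)]; eb <- eb[seq_len(n_e)]
    deg <- tabulate(c(ea, eb), nbins = n)
    mean_deg <- 2 * n_e / n
    target <- ceiling(spec$family_degree_boost * mean_deg)
    if (target > n - 1L)
      stop("infeasible family_degree_boost: target degree exceeds ",
           "simple-graph capacity", call. = FALSE)
    fam_idx <- sort(sample.int(n, spec$family_size))
    # neighbor sets for duplicate avoidance during boosting
    nb <- vector("list", n)
    for (i in seq_along(ea)) {
      nb[[ea[i]]] <- c(nb[[ea[i]]], eb[i])
      nb[[eb[i]]] <- c(nb[[eb[i]]], ea[i])
    }
    extra_a <- integer(0); extra_b <- integer(0)
    for (f in fam_idx) {
      while (deg[f] < target) {
        cand <- sample.int(n, 1L)
        if (cand == f || cand %in% nb[[f]]) next
        nb[[f]] <- c(nb[[f]], cand)
        nb[[cand]] <- c(nb[[cand]], f)
        deg[f] <- deg[f] + 1L
        deg[cand] <- deg[cand] + 1L
        extra_a <- c(extra_a, f); extra_b <- c(extra_b, cand)
      }
    }
    labels <- sprintf("GENE%05d", seq_len(n))
    labels[fam_idx] <- sprintf("FAM%02d", seq_along(fam_idx))
    net <- ppin(data.frame(a = labels[c(ea, extra_a)],
                           b = labels[c(eb, extra_b)],
                           stringsAsFactors = FALSE))
    list(network = net, family = labels[fam_idx])
  })
}

#' Generate a gene-set collection with one planted enriched set
#'
#' Produces `n_sets` sets with sizes uniform in `set_size_range`; the
#' first set (`SET001`) is the designated planted set and draws
#' `planted_enrichment_fraction` of its members from the signature, the
#' remainder (and all other sets) uniformly from the universe outside
#' the signature (other sets: from the whole universe). The declared
#' background is the universe size.
#'
#' @param universe character vector of all gene symbols.
#' @param spec a [synthetic_spec].
#' @param signature character vector of symbols the planted set is
#'   enriched in (subset of the universe).
#' @return a `gene_set_collection` with attribute `planted_set`.
#' @export
generate_gene_sets <- function(universe, spec, signature) {
  stopifnot(inherits(spec, "synthetic_spec"))
  universe <- unique(as.character(universe))
  signature <- unique(as.character(signature))
  if (!all(signature %in% universe))
    stop("signature must be a subset of the universe", call. = FALSE)
  if (spec$set_size_range[2] > length(universe))
    stop("set size range exceeds universe size", call. = FALSE)
  with_seed(spec$seed + 1L, {
    sizes <- sample.int(spec$set_size_range[2] - spec$set_size_range[1] + 1L,
                        spec$n_sets, replace = TRUE) +
      spec$set_size_range[1] - 1L
    non_sig <- setdiff(universe, signature)
    sets <- vector("list", spec$n_sets)
    for (i in seq_len(spec$n_sets)) {
      if (i == 1L) {
        k_sig <- min(round(spec$planted_enrichment_fraction * sizes[i]),
                     length(signature))
        members <- c(sample(signature, k_sig),
                     sample(non_sig, sizes[i] - k_sig))
      } else {
        members <- sample(universe, sizes[i])
      }
      sets[[i]] <- sort(members)
    }
    names(sets) <- sprintf("SET%03d", seq_len(spec$n_sets))
    coll <- gene_set_collection(
      sets,
      descriptions = setNames(
        c("planted", rep("random", spec$n_sets - 1L))[seq_len(spec$n_sets)],
        names(sets)),
      background = length(universe))
    attr(coll, "planted_set") <- names(sets)[1L]
    coll
  })
}

#' Write a network as a dialect-faithful interaction table
#'
#' Emits a file that [parse_interactions] reads back losslessly (pair
#' for pair). The HIPPIE dialect carries a deterministic synthetic
#' confidence score in [0,1] derived from the edge's symbols, so
#' identical networks always produce identical bytes.
#'
#' @param net a [ppin].
#' @param dialect `"biogrid"`, `"hippie"` or `"tsv2col"`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_interaction_table <- function(net,
                                    dialect = c("biogrid", "hippie",
                                                "tsv2col"),
                                    path) {
  dialect <- match.arg(dialect)
  e <- edge_table(net)
  if (dialect == "biogrid") {
    out <- data.frame(`#BioGRID Interaction ID` = seq_len(nrow(e)),
                      `Official Symbol Interactor A` = e$a,
                      `Official Symbol Interactor B` = e$b,
                      `Experimental System` = "synthetic",
                      check.names = FALSE, stringsAsFactors = FALSE)
  } else if (dialect == "hippie") {
    out <- data.frame(`Gene Name Interactor A` = e$a,
                      `Gene Name Interactor B` = e$b,
                      `Confidence Value` = synthetic_confidence(e$a, e$b),
                      check.names = FALSE, stringsAsFactors = FALSE)
  } else {
    out <- data.frame(symbol_a = e$a, symbol_b = e$b,
                      stringsAsFactors = FALSE)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# deterministic pseudo-confidence in [0.01, 0.99] from the symbol pair
synthetic_confidence <- function(a, b) {
  h <- vapply(paste(a, b, sep = "|"), function(s) {
    sum(utf8ToInt(s) * seq_len(nchar(s)) * 131) %% 9901
  }, numeric(1), USE.NAMES = FALSE)
  round(0.01 + 0.98 * h / 9900, 4)
}

#' Write a family-membership list
#' @param family character vector of symbols.
#' @param path output file (one symbol per line).
#' @return invisibly, `path`.
#' @export
write_family_list <- function(family, path) {
  writeLines(family, path)
  invisible(path)
}

#' Generate a complete synthetic input bundle
#'
#' One call producing everything the pipeline ingests: an interaction
#' table (chosen dialect), a family list, a GMT collection planted with
#' enrichment among the family's direct interactors, and a JSON
#' manifest of the spec.
#'
#' @param spec a [synthetic_spec].
#' @param out_dir output directory (created if needed).
#' @param dialect interaction-table dialect to emit.
#' @return list of written paths plus the generated `network`, `family`
#'   and `collection`.
#' @export
generate_bundle <- function(spec, out_dir,
                            dialect = c("hippie", "biogrid", "tsv2col")) {
  dialect <- match.arg(dialect)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gen <- generate_network(spec)
  adj <- adj_list(gen$network)
  fam_idx <- match(gen$family, gen$network$nodes)
  interactors <- setdiff(
    gen$network$nodes[unique(unlist(adj[fam_idx], use.names = FALSE))],
    gen$family)
  coll <- generate_gene_sets(gen$network$nodes, spec, interactors)
  paths <- list(
    edges = file.path(out_dir, paste0("edges_", dialect, ".tsv")),
    family = file.path(out_dir, "family.txt"),
    gmt = file.path(out_dir, "gene_sets.gmt"),
    manifest = file.path(out_dir, "manifest.json"))
  write_interaction_table(gen$network, dialect, paths$edges)
  write_family_list(gen$family, paths$family)
  write_gmt(coll, paths$gmt)
  jsonlite::write_json(unclass(spec), paths$manifest, auto_unbox = TRUE)
  c(paths, list(network = gen$network, family = gen$family,
                collection = coll))
}
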