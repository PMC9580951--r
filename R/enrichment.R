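#' Hypergeometric gene-set enrichment
#'
#' For each set in the collection, the overlap with the signature is
#' scored by the hypergeometric upper-tail probability on the declared
#' background, and Benjamini-Hochberg q-values are computed across the
#' whole collection. Rows are sorted ascending by (fdr, p, name) so the
#' output is byte-stable.
#'
#' @param signature character vector of gene symbols (non-empty).
#' @param collection a `gene_set_collection`.
#' @param background optional override of the collection's background N.
#' @return data frame of class `enrichment_rows`: `pathway`, `size`,
#'   `overlap`, `hits` (comma-joined sorted symbols), `p_value`, `fdr`.
#' @export
enrich <- function(signature, collection, background = NULL) {
  signature <- unique(toupper(trimws(as.character(signature))))
  signature <- signature[nzchar(signature)]
  if (!length(signature)) stop("signature is empty", call. = FALSE)
  N <- as.integer(background %||% collection$background)
  sizes <- lengths(collection$sets)
  if (N < length(signature) || N < max(sizes))
    stop("background N must be at least the signature size and every ",
         "set size", call. = FALSE)
  rows <- lapply(names(collection$sets), function(nm) {
    set <- collection$sets[[nm]]
    hits <- sort(intersect(signature, set))
    k <- length(hits)
    data.frame(pathway = nm, size = length(set), overlap = k,
               hits = paste(hits, collapse = ","),
               p_value = hypergeometric_tail(N, length(set),
                                             length(signature), k),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- benjamini_hochberg(out$p_value)
  out <- out[order(out$fdr, out$p_value, out$pathway), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "background") <- N
  attr(out, "signature_size") <- length(signature)
  class(out) <- c("enrichment_rows", "data.frame")
  out
}

#' Select the top enriched pathways
#'
#' @param rows an `enrichment_rows` data frame as returned by [enrich]
#'   (already sorted).
#' @param max_n maximum number of pathways to return.
#' @param fdr_cut FDR significance cutoff (strict `<`).
#' @return character vector of pathway names, possibly shorter than
#'   `max_n`.
#' @export
select_top_pathways <- function(rows, max_n = 25L, fdr_cut = 0.05) {
  passing <- rows$pathway[rows$fdr < fdr_cut]
  utils::head(passing, max_n)
}

#' Family-member pathway-involvement profile
#'
#' For each family protein, counts its direct non-family interactors in
#' the global network that belong to each selected pathway set; each row
#' of the normalized copy is divided by that protein's total count
#' across the selected pathways, so rows sum to 1 for proteins with at
#' least one counted interactor. Zero-total rows stay zero and are
#' flagged.
#'
#' @param net a [ppin] (the global network).
#' @param family character vector of family gene symbols.
#' @param collection a `gene_set_collection`.
#' @param selected character vector of pathway names (subset of the
#'   collection's names).
#' @return list of class `involvement_profile`: `raw` and `normalized`
#'   (family x pathway matrices) and `zero_rows` (family members with no
#'   counted interactor).
#' @export
involvement_profile <- function(net, family, collection, selected) {
  family <- sort(unique(toupper(trimws(as.character(family)))))
  family <- family[nzchar(family)]
  if (!all(selected %in% names(collection$sets)))
    stop("selected pathways not all present in collection", call. = FALSE)
  adj <- adj_list(net)
  raw <- matrix(0L, length(family), length(selected),
                dimnames = list(family, selected))
  for (f in family) {
    i <- match(f, net$nodes)
    if (is.na(i)) next
    partners <- setdiff(net$nodes[adj[[i]]], family)
    for (p in selected)
      raw[f, p] <- sum(partners %in% collection$sets[[p]])
  }
  totals <- rowSums(raw)
  normalized <- raw / ifelse(totals > 0, totals, 1)
  structure(list(raw = raw, normalized = normalized,
                 zero_rows = family[totals == 0]),
            class = "involvement_profile")
}

#' @export
print.involvement_profile <- function(x, ...) {
  cat(sprintf("<involvement_profile> %d family proteins x %d pathways (%d empty rows)\n",
              nrow(x$raw), ncol(x$raw), length(x$zero_rows)))
  invisible(x)
}

#' Family-to-pathway bipartite sub-network
#'
#' Keeps the family nodes having at least one direct non-family
#' interactor inside the pathway set, those interactors, and only the
#' family-interactor edges (interactor-interactor edges are dropped, as
#' in a bipartite pathway diagram).
#'
#' @param net a [ppin].
#' @param family character vector of family gene symbols.
#' @param pathway_set character vector of pathway member symbols.
#' @return a [ppin] with attribute `n_family_retained`.
#' @export
pathway_subnetwork <- function(net, family, pathway_set) {
  family <- unique(toupper(trimws(as.character(family))))
  pathway_set <- unique(toupper(trimws(as.character(pathway_set))))
  adj <- adj_list(net)
  edges <- list()
  retained <- character(0)
  for (f in intersect(family, net$nodes)) {
    i <- match(f, net$nodes)
    partners <- setdiff(net$nodes[adj[[i]]], family)
    partners <- intersect(partners, pathway_set)
    if (length(partners)) {
      retained <- c(retained, f)
      edges[[f]] <- data.frame(a = f, b = partners,
                               stringsAsFactors = FALSE)
    }
  }
  out <- if (length(edges)) ppin(do.call(rbind, edges)) else ppin(NULL)
  attr(out, "n_family_retained") <- length(retained)
  out
}

#' Pathway membership of the family itself
#'
#' Specialization of [enrich] with the family as the signature: for each
#' gene set, which family members are themselves curated pathway
#' members, with the corresponding hypergeometric p-value.
#'
#' @param family character vector of family gene symbols.
#' @param collection a `gene_set_collection`.
#' @param background optional override of the collection's background N.
#' @return an `enrichment_rows` data frame.
#' @export
membership_pvalues <- function(family, collection, background = NULL) {
  enrich(family, collection, background = background)
}
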