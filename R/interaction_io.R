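#' Parse an interaction table
#'
#' Reads one of three tab-delimited dialects of curated physical-interaction
#' tables into an interaction corpus. Gene symbols are upper-cased and
#' whitespace-stripped; no alias resolution is attempted. Rows with missing
#' or placeholder (`-`) symbols are skipped and counted, never fatal.
#'
#' Dialects:
#' \describe{
#'   \item{biogrid}{BioGRID TAB-style: header row containing the columns
#'     `Official Symbol Interactor A` and `Official Symbol Interactor B`
#'     (other columns ignored). One row per supporting publication or
#'     technique, so duplicated pairs are genuine evidence items.}
#'   \item{hippie}{HIPPIE-style: header row with `Gene Name Interactor A`,
#'     `Gene Name Interactor B` and a numeric `Confidence Value` in [0,1].}
#'   \item{tsv2col}{Generic supplemental edge list: header row, two symbol
#'     columns, optional third numeric confidence column.}
#' }
#'
#' @param path file path.
#' @param dialect one of `"biogrid"`, `"hippie"`, `"tsv2col"`.
#' @return an `interaction_corpus`: a data frame with columns `protein_a`,
#'   `protein_b`, `source`, `evidence_count`, `confidence`, plus attributes
#'   `n_skipped` (malformed rows) and `dialect`. Row order follows the file.
#' @export
parse_interactions <- function(path,
                               dialect = c("biogrid", "hippie", "tsv2col")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("cannot read interaction file: ", path,
                               call. = FALSE)
  tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "")
  cols <- names(tab)
  find_col <- function(name) {
    hit <- which(tolower(cols) == tolower(name))
    if (!length(hit))
      stop(sprintf("dialect '%s': required column '%s' missing",
                   dialect, name), call. = FALSE)
    hit[1L]
  }
  if (dialect == "biogrid") {
    ia <- find_col("Official Symbol Interactor A")
    ib <- find_col("Official Symbol Interactor B")
    conf <- rep(NA_real_, nrow(tab))
  } else if (dialect == "hippie") {
    ia <- find_col("Gene Name Interactor A")
    ib <- find_col("Gene Name Interactor B")
    conf <- suppressWarnings(as.numeric(tab[[find_col("Confidence Value")]]))
  } else {
    if (ncol(tab) < 2L)
      stop("dialect 'tsv2col': need at least two symbol columns",
           call. = FALSE)
    ia <- 1L; ib <- 2L
    conf <- if (ncol(tab) >= 3L)
      suppressWarnings(as.numeric(tab[[3L]])) else rep(NA_real_, nrow(tab))
  }
  a <- toupper(trimws(as.character(tab[[ia]])))
  b <- toupper(trimws(as.character(tab[[ib]])))
  ok <- nzchar(a) & nzchar(b) & !is.na(tab[[ia]]) & !is.na(tab[[ib]]) &
    a != "-" & b != "-"
  ok <- ok & (is.na(conf) | (conf >= 0 & conf <= 1))
  corpus <- data.frame(protein_a = a[ok], protein_b = b[ok],
                       source = rep(dialect, sum(ok)),
                       evidence_count = rep(1L, sum(ok)),
                       confidence = conf[ok],
                       stringsAsFactors = FALSE)
  new_corpus(corpus, n_skipped = sum(!ok), dialect = dialect)
}

new_corpus <- function(df, n_skipped = 0L, dialect = NA_character_) {
  rownames(df) <- NULL
  structure(df, n_skipped = as.integer(n_skipped), dialect = dialect,
            class = c("interaction_corpus", "data.frame"))
}

#' Canonical unordered pair keys of a corpus
#' @param corpus an `interaction_corpus`.
#' @return character vector, one `A|B` key (lexicographically ordered) per
#'   record.
#' @export
canonical_pairs <- function(corpus) {
  paste(pmin(corpus$protein_a, corpus$protein_b),
        pmax(corpus$protein_a, corpus$protein_b), sep = "|")
}

#' Merge interaction corpora into a deduplicated edge corpus
#'
#' Takes the union over canonical unordered pairs. The merged evidence
#' count of a pair is the total number of contributing evidence items
#' (duplicate rows within one source are genuine separate evidence); the
#' maximum confidence seen for the pair is retained. Output rows are
#' sorted by canonical pair, so merging is deterministic, commutative and
#' associative at the pair level.
#'
#' @param corpora a list of `interaction_corpus` objects (or a single one).
#' @return a merged `interaction_corpus` with one row per unordered pair,
#'   `protein_a <= protein_b`.
#' @export
merge_corpora <- function(corpora) {
  if (inherits(corpora, "interaction_corpus")) corpora <- list(corpora)
  if (!length(corpora)) stop("need at least one corpus", call. = FALSE)
  all <- do.call(rbind, lapply(corpora, function(x) as.data.frame(x)))
  if (nrow(all) == 0L) return(new_corpus(all))
  a <- pmin(all$protein_a, all$protein_b)
  b <- pmax(all$protein_a, all$protein_b)
  key <- paste(a, b, sep = "|")
  grp <- factor(key, levels = sort(unique(key)))
  idx <- split(seq_along(key), grp)
  first <- vapply(idx, `[`, integer(1), 1L)
  conf <- vapply(idx, function(i) {
    v <- all$confidence[i]
    if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
  }, numeric(1))
  merged <- data.frame(
    protein_a = a[first],
    protein_b = b[first],
    source = vapply(idx, function(i)
      paste(sort(unique(all$source[i])), collapse = ","), character(1)),
    evidence_count = vapply(idx, function(i)
      sum(all$evidence_count[i]), integer(1)),
    confidence = conf,
    stringsAsFactors = FALSE)
  new_corpus(merged,
             n_skipped = sum(vapply(corpora, function(x)
               attr(x, "n_skipped") %||% 0L, integer(1))))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Report how many records fall below a confidence threshold
#'
#' Records without a confidence score are counted separately and never
#' as "below threshold" (the corpus bookkeeping behind the 0.63 HIPPIE
#' cutoff accounting).
#'
#' @param corpus an `interaction_corpus`.
#' @param threshold confidence cutoff in [0,1].
#' @return a one-row data frame: `n_total`, `n_with_confidence`,
#'   `n_missing_confidence`, `n_below`, `fraction_below` (of scored
#'   records; `NA` when none are scored).
#' @export
confidence_report <- function(corpus, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      is.na(threshold) || threshold < 0 || threshold > 1)
    stop("threshold must be a single value in [0,1]", call. = FALSE)
  has <- !is.na(corpus$confidence)
  n_below <- sum(has & corpus$confidence < threshold)
  data.frame(n_total = nrow(corpus),
             n_with_confidence = sum(has),
             n_missing_confidence = sum(!has),
             n_below = n_below,
             fraction_below = if (any(has)) n_below / sum(has) else NA_real_)
}

#' Apply an explicit confidence filter
#'
#' The default pipeline keeps all records regardless of evidence level
#' (records without a score are always kept); filtering is strictly
#' opt-in.
#'
#' @param corpus an `interaction_corpus`.
#' @param min_confidence minimum confidence to keep a scored record.
#' @return the filtered corpus.
#' @export
filter_confidence <- function(corpus, min_confidence) {
  keep <- is.na(corpus$confidence) | corpus$confidence >= min_confidence
  new_corpus(as.data.frame(corpus)[keep, , drop = FALSE],
             n_skipped = attr(corpus, "n_skipped") %||% 0L)
}

#' Write a corpus as a canonical edge-list TSV
#' @param corpus an `interaction_corpus`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_corpus <- function(corpus, path) {
  df <- as.data.frame(corpus)
  df$symbol_a <- pmin(df$protein_a, df$protein_b)
  df$symbol_b <- pmax(df$protein_a, df$protein_b)
  out <- df[, c("symbol_a", "symbol_b", "evidence_count", "confidence")]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line — name, description, then member
#' symbols, tab-separated.
#'
#' @param path GMT file.
#' @param background declared background population size N for
#'   hypergeometric tests. The default, 23467, is the whole-genome
#'   background commonly used by enrichment tools for human symbols;
#'   override it to the universe actually sampled from.
#' @return a `gene_set_collection`: list with elements `sets` (named list
#'   of character vectors), `descriptions`, `background`.
#' @export
read_gmt <- function(path, background = 23467) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) < 3L
  if (any(bad)) stop("GMT line with fewer than 3 fields", call. = FALSE)
  names_ <- vapply(parts, `[`, character(1), 1L)
  if (anyDuplicated(names_)) stop("duplicate gene-set names in GMT",
                                  call. = FALSE)
  sets <- lapply(parts, function(p) {
    g <- toupper(trimws(p[-(1:2)]))
    unique(g[nzchar(g)])
  })
  names(sets) <- names_
  desc <- vapply(parts, `[`, character(1), 2L)
  names(desc) <- names_
  gene_set_collection(sets, desc, background)
}

#' Construct a gene-set collection
#' @param sets named list of character vectors (unique names, non-empty
#'   sets).
#' @param descriptions optional named character vector of descriptions.
#' @param background population size N used as the hypergeometric
#'   background.
#' @return a `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL, background) {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("sets must have unique names", call. = FALSE)
  if (any(lengths(sets) == 0L)) stop("empty gene set", call. = FALSE)
  if (!is.numeric(background) || background < 1)
    stop("background must be a positive count", call. = FALSE)
  if (is.null(descriptions)) {
    descriptions <- setNames(rep("", length(sets)), names(sets))
  }
  structure(list(sets = sets, descriptions = descriptions,
                 background = as.integer(background)),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d sets, sizes %d-%d, background N=%d\n",
              length(x$sets), min(lengths(x$sets)), max(lengths(x$sets)),
              x$background))
  invisible(x)
}

#' Write a gene-set collection to GMT
#' @param collection a `gene_set_collection`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$descriptions[[nm]], collection$sets[[nm]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
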