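#' Assemble and validate a pipeline configuration
#'
#' @param edge_files list of `list(path =, dialect =)` entries naming
#'   the interaction tables to ingest.
#' @param family_path one-symbol-per-line family membership file.
#' @param gmt_path GMT gene-set collection.
#' @param out_dir output directory for the report and per-stage tables.
#' @param background hypergeometric background N (`NULL`: the GMT
#'   reader's default).
#' @param keep_self_loops keep self-loops in the global network?
#' @param confidence_threshold optional opt-in confidence filter; the
#'   default keeps every record regardless of evidence level.
#' @param top_n_pathways,fdr_cut top-pathway selection parameters.
#' @param similarity_radii radii at which to compute similarity
#'   matrices (subset of 1:3).
#' @param min_clique_size minimum clique size for complex prediction.
#' @param seed RNG seed recorded in the provenance block.
#' @return a validated list of class `pipeline_config`. Validation
#'   reports every violation at once.
#' @export
pipeline_config <- function(edge_files, family_path, gmt_path, out_dir,
                            background = NULL,
                            keep_self_loops = FALSE,
                            confidence_threshold = NULL,
                            top_n_pathways = 25L, fdr_cut = 0.05,
                            similarity_radii = c(1L, 2L, 3L),
                            min_clique_size = 3L,
                            seed = 1L) {
  problems <- character(0)
  if (!is.list(edge_files) || !length(edge_files)) {
    problems <- c(problems, "edge_files must be a non-empty list")
  } else {
    for (i in seq_along(edge_files)) {
      ef <- edge_files[[i]]
      if (!is.list(ef) || is.null(ef$path) || is.null(ef$dialect))
        problems <- c(problems, sprintf(
          "edge_files[[%d]] needs $path and $dialect", i))
      else {
        if (!file.exists(ef$path))
          problems <- c(problems, sprintf(
            "edge_files[[%d]]$path does not exist: %s", i, ef$path))
        if (!ef$dialect %in% c("biogrid", "hippie", "tsv2col"))
          problems <- c(problems, sprintf(
            "edge_files[[%d]]$dialect unknown: %s", i, ef$dialect))
      }
    }
  }
  if (!file.exists(family_path))
    problems <- c(problems, paste("family_path does not exist:",
                                  family_path))
  if (!file.exists(gmt_path))
    problems <- c(problems, paste("gmt_path does not exist:", gmt_path))
  if (!is.null(confidence_threshold) &&
      (confidence_threshold < 0 || confidence_threshold > 1))
    problems <- c(problems, "confidence_threshold must be in [0,1]")
  if (fdr_cut <= 0 || fdr_cut > 1)
    problems <- c(problems, "fdr_cut must be in (0,1]")
  if (!all(similarity_radii %in% 1:3))
    problems <- c(problems, "similarity_radii must be a subset of 1:3")
  if (top_n_pathways < 1)
    problems <- c(problems, "top_n_pathways must be >= 1")
  if (min_clique_size < 2)
    problems <- c(problems, "min_clique_size must be >= 2")
  if (length(problems))
    stop("invalid pipeline config:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  structure(list(edge_files = edge_files, family_path = family_path,
                 gmt_path = gmt_path, out_dir = out_dir,
                 background = background,
                 keep_self_loops = keep_self_loops,
                 confidence_threshold = confidence_threshold,
                 top_n_pathways = as.integer(top_n_pathways),
                 fdr_cut = fdr_cut,
                 similarity_radii = as.integer(similarity_radii),
                 min_clique_size = as.integer(min_clique_size),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys mirror [pipeline_config] arguments.
#' @return a validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

stage_log <- function(verbose, stage, fmt, ...) {
  if (verbose) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full analysis pipeline
#'
#' Fixed stage order: ingest -> build (global, family-neighborhood and
#' family-family networks) -> topology summaries -> node metrics and
#' hub / threshold tests -> power-law fit -> clique enumeration ->
#' similarity matrices -> enrichment, top-pathway selection and
#' involvement profiles. Writes one TSV per table plus a single
#' machine-readable JSON report; identical config and inputs give an
#' identical report body.
#'
#' @param config a `pipeline_config`.
#' @param verbose log per-stage record counts?
#' @return the report, invisibly (also written to
#'   `out_dir/report.json`).
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE))
  }

  # -- ingest ---------------------------------------------------------
  corpus <- run_stage("ingest", {
    corpora <- lapply(config$edge_files, function(ef)
      parse_interactions(ef$path, ef$dialect))
    merged <- merge_corpora(corpora)
    if (!is.null(config$confidence_threshold))
      merged <- filter_confidence(merged, config$confidence_threshold)
    merged
  })
  conf_report <- confidence_report(corpus, 0.63)
  stage_log(verbose, "ingest", "%d unique pairs (%d below 0.63 of %d scored)",
            nrow(corpus), conf_report$n_below,
            conf_report$n_with_confidence)
  family <- toupper(trimws(readLines(config$family_path, warn = FALSE)))
  family <- unique(family[nzchar(family)])

  # -- build ----------------------------------------------------------
  nets <- run_stage("build", {
    global <- build_network(corpus,
                            keep_self_loops = config$keep_self_loops)
    list(global = global,
         family = extract_family_subnetwork(global, family),
         family_family = extract_family_family_network(global, family,
                                                       corpus))
  })
  stage_log(verbose, "build", "global %d/%d, family %d/%d, family-family %d/%d",
            n_nodes(nets$global), n_edges(nets$global),
            n_nodes(nets$family), n_edges(nets$family),
            n_nodes(nets$family_family), n_edges(nets$family_family))

  # -- topology -------------------------------------------------------
  topo <- run_stage("topology", lapply(nets, function(nt)
    if (n_nodes(nt) > 0L) unclass(summarize_topology(nt)) else NULL))

  # -- node metrics + group tests ------------------------------------
  metrics <- run_stage("node_metrics", node_metrics(nets$global))
  hub_rep <- run_stage("hubs", classify_hubs(metrics, family))
  fam_deg <- metrics$degree[metrics$node %in% family]
  rest_deg <- metrics$degree[!metrics$node %in% family]
  degree_test <- run_stage("hubs", wilcoxon_rank_sum(fam_deg, rest_deg))

  # -- power law ------------------------------------------------------
  plfit <- run_stage("powerlaw", tryCatch(
    unclass(fit_power_law(metrics$degree)),
    error = function(e) NULL))

  # -- cliques --------------------------------------------------------
  cl <- run_stage("cliques", {
    maximal <- maximal_cliques(nets$family_family,
                               config$min_clique_size)
    all_cl <- enumerate_cliques(nets$family_family,
                                config$min_clique_size)
    list(maximal = maximal, all = all_cl)
  })
  stage_log(verbose, "cliques", "%d maximal / %d total (size >= %d)",
            length(cl$maximal$cliques), length(cl$all$cliques),
            config$min_clique_size)

  # -- similarity -----------------------------------------------------
  fam_present <- intersect(family, node_names(nets$global))
  dist_m <- run_stage("similarity",
                      family_distance_matrix(nets$global, family))
  sims <- run_stage("similarity", {
    out <- lapply(config$similarity_radii, function(s)
      similarity_matrix(nets$global, fam_present, s))
    names(out) <- paste0("s", config$similarity_radii)
    out
  })

  # -- enrichment -----------------------------------------------------
  collection <- run_stage("enrichment",
                          read_gmt(config$gmt_path,
                                   background = config$background %||%
                                     23467))
  signature <- setdiff(node_names(nets$family), family)
  enr <- run_stage("enrichment", enrich(signature, collection))
  top <- select_top_pathways(enr, config$top_n_pathways, config$fdr_cut)
  profile <- run_stage("enrichment",
                       involvement_profile(nets$global, fam_present,
                                           collection, top))
  memb <- run_stage("enrichment", membership_pvalues(family, collection))
  stage_log(verbose, "enrichment", "%d/%d sets below FDR %.2f",
            sum(enr$fdr < config$fdr_cut), nrow(enr), config$fdr_cut)

  # -- artifacts ------------------------------------------------------
  out <- config$out_dir
  write_corpus(corpus, file.path(out, "edges.tsv"))
  topo_df <- do.call(rbind, lapply(names(topo), function(nm) {
    t <- topo[[nm]]
    if (is.null(t)) return(NULL)
    data.frame(network = nm, as.data.frame(t), stringsAsFactors = FALSE)
  }))
  utils::write.table(topo_df, file.path(out, "topology.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(metrics, file.path(out, "node_metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  clique_table(cl$maximal, file.path(out, "cliques.tsv"))
  for (nm in names(sims))
    utils::write.table(sims[[nm]],
                       file.path(out, sprintf("similarity_%s.tsv", nm)),
                       sep = "\t", quote = FALSE)
  utils::write.table(as.data.frame(enr), file.path(out, "enrichment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(profile$normalized, file.path(out, "profile.tsv"),
                     sep = "\t", quote = FALSE)

  report <- list(
    provenance = list(package = "brdnet",
                      version = as.character(utils::packageVersion("brdnet")),
                      seed = config$seed,
                      config = config_echo(config)),
    ingest = list(n_pairs = nrow(corpus),
                  n_skipped = attr(corpus, "n_skipped"),
                  confidence_report = as.list(conf_report)),
    topology = topo,
    hub_report = list(mean_degree = hub_rep$mean_degree,
                      hub_fraction = hub_rep$hub_fraction,
                      counts = as.vector(hub_rep$counts),
                      chi_square_p = if (!is.null(hub_rep$test))
                        hub_rep$test$p_value else NA,
                      degree_wilcoxon_p = degree_test$p_value),
    power_law = plfit,
    cliques = list(n_maximal = length(cl$maximal$cliques),
                   n_total = length(cl$all$cliques),
                   min_size = config$min_clique_size),
    similarity = lapply(sims, function(m)
      list(radius = attr(m, "radius"),
           mean_off_diagonal = mean(m[upper.tri(m)]))),
    enrichment = list(n_sets = nrow(enr),
                      n_significant = sum(enr$fdr < config$fdr_cut),
                      top_pathways = as.list(top),
                      background = attr(enr, "background")),
    involvement = list(n_family = nrow(profile$raw),
                       n_pathways = ncol(profile$raw),
                       zero_rows = as.list(profile$zero_rows)))
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(report)
}

config_echo <- function(config) {
  cfg <- unclass(config)
  cfg$edge_files <- lapply(cfg$edge_files, function(ef)
    list(path = basename(ef$path), dialect = ef$dialect))
  cfg$family_path <- basename(cfg$family_path)
  cfg$gmt_path <- basename(cfg$gmt_path)
  cfg$out_dir <- NULL
  cfg
}
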