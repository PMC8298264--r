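#' Run the full regulome-shift pipeline
#'
#' Orchestrates differential expression, per-condition bipartite network
#' construction, centrality rate-of-change classification and the
#' interacting-protein coverage analysis from a single configuration.
#' On a stage failure the run aborts with the stage name and cause, and
#' any outputs already written are renamed with a `.partial` suffix.
#'
#' @param cfg Path to a YAML file or a list with elements:
#'   `expr` (expression TSV), `conditions` (YAML sample -> condition map),
#'   `ann` (annotation TSV), `ip_ann` (interacting-protein TSV),
#'   `out_dir`, and optional `alpha` (0.05), `lfc_cut` (2),
#'   `increase_threshold` (1000), `reduced_threshold` (1),
#'   `min_weight` (0), `equal_variance` (TRUE), `seed` (1).
#' @return The run summary: stage counts and the output-file manifest
#'   (also written as `summary.json` in `out_dir`).
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- yaml::read_yaml(cfg)
  defaults <- list(alpha = 0.05, lfc_cut = 2, increase_threshold = 1000,
                   reduced_threshold = 1, min_weight = 0,
                   equal_variance = TRUE, seed = 1L)
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  for (k in c("expr", "conditions", "ann", "ip_ann"))
    if (!is.null(cfg[[k]]) && !file.exists(cfg[[k]]))
      stop("input file not found: ", cfg[[k]])
  stopifnot(!is.null(cfg$out_dir))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- character()
  stage <- "setup"
  emit <- function(path) { manifest <<- c(manifest, path); path }

  res <- tryCatch({
    stage <- "diffexpr"
    cond <- unlist(yaml::read_yaml(cfg$conditions))
    m <- read_expression(cfg$expr, cond)
    de <- de_table(m, alpha = cfg$alpha, lfc_cut = cfg$lfc_cut,
                   equal_variance = cfg$equal_variance)
    utils::write.table(de, emit(file.path(cfg$out_dir, "de.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    selected <- select_de_genes(de, alpha = cfg$alpha, lfc_cut = cfg$lfc_cut)

    stage <- "bpnet"
    ann <- read_annotations(cfg$ann, fmt = "tsv")
    cm <- condition_means(m)
    wt_net <- build_network(cm, ann, "WT", min_weight = cfg$min_weight)
    ko_net <- build_network(cm, ann, "KO", min_weight = cfg$min_weight)
    write_graphml(wt_net, emit(file.path(cfg$out_dir, "wt.graphml")))
    write_graphml(ko_net, emit(file.path(cfg$out_dir, "ko.graphml")))
    wt_c <- eigenvector_centrality(wt_net)
    ko_c <- eigenvector_centrality(ko_net)
    report <- centrality_rate_of_change(wt_c, ko_c)
    complements <- classify_functional_complements(
      report, de, increase_threshold = cfg$increase_threshold)
    reduced <- classify_reduced_importance(
      ko_c, threshold_pct = cfg$reduced_threshold)
    report$label[report$gene_id %in% complements &
                   report$label == "unclassified"] <- "functional_complement"
    report$label[report$gene_id %in% reduced &
                   report$label == "unclassified"] <- "reduced_importance"
    write_report(report, emit(file.path(cfg$out_dir, "centrality.tsv")))
    writeLines(complements,
               emit(file.path(cfg$out_dir, "complements.txt")))
    writeLines(reduced, emit(file.path(cfg$out_dir, "reduced.txt")))
    louvain <- louvain_communities(ko_net, seed = cfg$seed)

    stage <- "ipsets"
    ip_ann <- read_ip_annotations(cfg$ip_ann)
    de_ann <- ann[ann$gene_id %in% selected$gene_id, , drop = FALSE]
    summary_ip <- NULL
    if (nrow(de_ann)) {
      coverage <- akirin2_only_bps(de_ann, ip_ann)
      utils::write.table(coverage[setdiff(names(coverage), "covering_ips")],
                         emit(file.path(cfg$out_dir, "coverage.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      only <- coverage$bp_id[coverage$akirin2_only]
      part <- if (length(only))
        membership_partition(de_ann, only) else NULL
      summary_ip <- list(
        bps_annotated = nrow(coverage),
        bps_akirin2_only = length(only),
        genes_in_only_bps = if (is.null(part)) 0L else part$total)
    } else {
      summary_ip <- list(bps_annotated = 0L, bps_akirin2_only = 0L,
                         genes_in_only_bps = 0L)
    }

    stage <- "summary"
    summary <- c(list(
      genes_tested = nrow(de),
      genes_significant = sum(de$significant),
      genes_selected = nrow(selected),
      wt_nodes = length(wt_net$gene_nodes) + length(wt_net$bp_nodes),
      wt_edges = nrow(wt_net$edges),
      ko_nodes = length(ko_net$gene_nodes) + length(ko_net$bp_nodes),
      ko_edges = nrow(ko_net$edges),
      n_complements = length(complements),
      n_reduced = length(reduced),
      ko_communities = louvain$n_communities,
      ko_modularity = louvain$modularity),
      summary_ip)
    summary$outputs <- manifest
    jsonlite::write_json(summary,
                         emit(file.path(cfg$out_dir, "summary.json")),
                         auto_unbox = TRUE, digits = NA)
    summary
  }, error = function(e) {
    for (f in manifest)
      if (file.exists(f)) file.rename(f, paste0(f, ".partial"))
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  res
}
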