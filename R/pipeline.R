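## End-to-end pipeline over synthetic inputs: simulate -> DE filter ->
## enrichment -> evolutionary profiling -> cross-species classification ->
## network overlay, with a single structured, reproducible report.

#' Assemble a pipeline configuration
#'
#' All stage parameters in one validated list. Every source of randomness
#' derives from `seed`.
#'
#' @param seed master seed.
#' @param sim a [SimConfig-class]; defaults to `simConfig(seed = seed)`.
#' @param criteria default DE criteria (FDR < 0.1, fold >= 2, reads >= 50).
#' @param relaxed_criteria the relaxed variant (fold >= 1.8).
#' @param band_halfwidth little-variation band for the behavior classifier.
#' @param enrichment_fdr,ic_min enrichment stage thresholds.
#' @param n_terms,n_enriched_terms,fold_enrichment annotation-generator
#'   settings.
#' @param n_pairs,pair_length sequence-pair generator settings.
#' @param pair_identity_high,pair_identity_low,low_identity_fraction per-pair
#'   identity targets are drawn uniformly from `pair_identity_high` except
#'   for a `low_identity_fraction` of pairs drawn from `pair_identity_low`,
#'   emulating a genome where most orthologs are nearly identical but a
#'   minority diverge beyond what is mappable.
#' @param n_presence_genes presence-matrix generator size.
#' @param network_min_score confidence threshold for interaction edges.
#' @param n_network_nodes,n_communities,p_in,p_out interaction-network
#'   generator settings.
#' @return list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(seed = 1,
                           sim = simConfig(seed = seed),
                           criteria = deCriteria(),
                           relaxed_criteria = deCriteria(min_fold = 1.8),
                           band_halfwidth = 0.4,
                           enrichment_fdr = 0.05, ic_min = 2,
                           n_terms = 200, n_enriched_terms = 5,
                           fold_enrichment = 5,
                           n_pairs = 500, pair_length = 1000,
                           pair_identity_high = c(99, 100),
                           pair_identity_low = c(85, 97),
                           low_identity_fraction = 0.08,
                           n_presence_genes = 500,
                           network_min_score = 0.7,
                           n_network_nodes = 400, n_communities = 8,
                           p_in = 0.3, p_out = 0.005) {
  validObject(sim); validObject(criteria); validObject(relaxed_criteria)
  stopifnot(band_halfwidth > 0, enrichment_fdr > 0, enrichment_fdr <= 1,
            network_min_score >= 0, network_min_score <= 1)
  structure(list(seed = seed, sim = sim, criteria = criteria,
                 relaxed_criteria = relaxed_criteria,
                 band_halfwidth = band_halfwidth,
                 enrichment_fdr = enrichment_fdr, ic_min = ic_min,
                 n_terms = n_terms, n_enriched_terms = n_enriched_terms,
                 fold_enrichment = fold_enrichment,
                 n_pairs = n_pairs, pair_length = pair_length,
                 pair_identity_high = pair_identity_high,
                 pair_identity_low = pair_identity_low,
                 low_identity_fraction = low_identity_fraction,
                 n_presence_genes = n_presence_genes,
                 network_min_score = network_min_score,
                 n_network_nodes = n_network_nodes,
                 n_communities = n_communities, p_in = p_in, p_out = p_out),
            class = c("PipelineConfig", "list"))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
}

#' Run the full pipeline on synthetic inputs
#'
#' Executes simulate -> DE filter -> term enrichment -> ortholog
#' identity/presence profiling -> cross-species behavior classification ->
#' interaction-network clustering and overlay, and returns a structured
#' report. With a fixed seed the report (and the files written under
#' `out_dir`) are byte-identical across runs.
#'
#' @param config a [pipelineConfig()] list.
#' @param out_dir optional directory; when given, the report is written as
#'   `report.json` and `report.txt`, plus the main intermediate tables.
#' @return the report, a nested list (thresholds, DE counts, per-comparison
#'   behavior summaries, overlay counts, identity summary, presence
#'   categories and resolutions, enriched terms, network metrics).
#' @examples
#' \donttest{
#' rep <- runPipeline(pipelineConfig(seed = 1,
#'                                   sim = simConfig(n_genes = 2000, seed = 1),
#'                                   n_pairs = 20, pair_length = 200))
#' rep$de
#' }
#' @export
runPipeline <- function(config = pipelineConfig(), out_dir = NULL) {
  stopifnot(inherits(config, "PipelineConfig"))
  report <- list(
    seed = config$seed,
    thresholds = list(
      fdr_max = config$criteria@fdr_max,
      min_fold = config$criteria@min_fold,
      min_reads = config$criteria@min_reads,
      relaxed_min_fold = config$relaxed_criteria@min_fold,
      band_halfwidth = config$band_halfwidth,
      enrichment_fdr = config$enrichment_fdr,
      ic_min = config$ic_min,
      network_min_score = config$network_min_score))

  sim <- .stage("simulate", genDETables(config$sim))

  ## --- DE filter -----------------------------------------------------------
  focal <- .stage("de_filter", applyDECriteria(sim$tables$focal,
                                               config$criteria))
  de_sum <- summarizeDE(focal)
  relaxed <- applyDECriteria(sim$tables$focal, config$relaxed_criteria)
  report$de <- list(n_de = de_sum$n_de, n_up = de_sum$n_up,
                    n_down = de_sum$n_down,
                    n_de_relaxed = summarizeDE(relaxed)$n_de)
  de_calls <- setNames(focal$status, focal$gene_id)
  de_calls <- de_calls[de_calls %in% c("up", "down")]

  ## --- enrichment ----------------------------------------------------------
  up_set <- names(de_calls)[de_calls == "up"]
  ann <- .stage("enrichment", genAnnotation(
    gene_ids = focal$gene_id, n_terms = config$n_terms,
    n_enriched = config$n_enriched_terms,
    fold_enrichment = config$fold_enrichment,
    test_genes = up_set, seed = config$seed))
  enr <- enrich(up_set, focal$gene_id, ann$annotation,
                fdr_max = config$enrichment_fdr)
  enr_f <- filterMostSpecific(enr, ic_min = config$ic_min)
  planted <- ann$truth$term_id[ann$truth$enriched]
  report$enrichment <- list(
    n_terms_tested = nrow(enr),
    n_enriched = sum(enr$enriched),
    n_enriched_specific = sum(enr_f$enriched),
    n_planted = length(planted),
    n_planted_detected = sum(enr$term_id[enr$enriched] %in% planted),
    top_terms = head(enr_f[enr_f$enriched,
                           c("term_id", "k", "K", "fdr", "ic")], 5))

  ## --- ortholog identity ---------------------------------------------------
  targets <- withSeed(facetSeed(config$seed, "pair_targets"), {
    n_low <- round(config$low_identity_fraction * config$n_pairs)
    t <- runif(config$n_pairs, config$pair_identity_high[1],
               config$pair_identity_high[2])
    if (n_low > 0) {
      low <- sample.int(config$n_pairs, n_low)
      t[low] <- runif(n_low, config$pair_identity_low[1],
                      config$pair_identity_low[2])
    }
    t
  })
  pairs <- .stage("ortho_identity", genSequencePairs(
    config$n_pairs, config$pair_length, targets, seed = config$seed))
  idist <- identityDistribution(pairs$seq_a, pairs$seq_b)
  report$identity <- list(n_pairs = config$n_pairs,
                          mean_identity = mean(idist$identities),
                          fraction_above_98 = fractionAbove(idist, 98))

  ## --- phylogenetic profiling ----------------------------------------------
  pmx <- .stage("ortho_presence",
                genPresenceMatrix(config$n_presence_genes,
                                  seed = config$seed))
  calls <- classifyPresence(pmx$matrix)
  calls <- rescueCheck(calls, pmx$truth$confirm_presence)
  calls <- resolveFishOutgroups(calls, pmx$truth$outgroup_presence)
  report$presence <- list(
    categories = as.list(table(calls$category)),
    rescue = as.list(table(calls$resolution[
      calls$category == "single_species_absence"])),
    outgroup = as.list(table(calls$resolution[
      calls$category == "tetrapod_innovation_candidate"])))

  ## --- cross-species behavior ----------------------------------------------
  comps <- names(sim$tables$comparisons)
  beh_calls <- list(); beh_sum <- list()
  for (comp in comps) {
    cls <- .stage(paste0("classify_", comp), classifyComparison(
      de_calls, sim$tables$comparisons[[comp]], sim$ortholog_maps[[comp]],
      band_halfwidth = config$band_halfwidth))
    beh_calls[[comp]] <- cls
    beh_sum[[comp]] <- summarizeComparison(cls)
  }
  report$comparisons <- beh_sum
  overlay <- suppressMessages(doubleBehaviorOverlay(
    beh_calls[[comps[1]]], beh_calls[[comps[length(comps)]]], de_calls))
  report$overlay <- list(
    comparisons = c(comps[1], comps[length(comps)]),
    categories = as.list(table(overlay)))

  ## --- interaction network -------------------------------------------------
  net_nodes <- head(sort(names(de_calls)), config$n_network_nodes)
  sbm <- .stage("network", genNetwork(
    length(net_nodes), config$n_communities, config$p_in, config$p_out,
    seed = config$seed, node_ids = net_nodes))
  net <- filterEdges(sbm$network, config$network_min_score)
  part <- louvainCluster(net, seed = config$seed)
  net <- setClusters(net, part)
  net <- overlayBehavior(net, overlay)
  clu_ann <- annotateClusters(net, ann$annotation, focal$gene_id,
                              fdr_max = config$enrichment_fdr)
  report$network <- list(
    n_nodes = length(nodeIds(net)),
    n_edges_kept = nrow(edgeTable(net)),
    n_clusters = length(unique(part)),
    modularity = as.numeric(attr(part, "modularity")),
    ari_vs_planted = mclust::adjustedRandIndex(part[net_nodes],
                                               sbm$truth[net_nodes]),
    n_annotated_clusters = length(unique(clu_ann$cluster)),
    overlay_by_cluster = as.data.frame.matrix(overlayCrossTab(net)))

  if (!is.null(out_dir)) .writeReport(report, focal, beh_calls, net, out_dir)
  report
}

.writeReport <- function(report, focal, beh_calls, net, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeDETable(focal, file.path(out_dir, "focal_called.tsv"))
  for (comp in names(beh_calls))
    .writeTsv(beh_calls[[comp]],
              file.path(out_dir, sprintf("behavior_%s.tsv", comp)))
  writeGraphML(net, file.path(out_dir, "network.graphml"))
  txt <- c("Cross-species SCI pipeline report",
           sprintf("seed: %s", report$seed),
           sprintf("thresholds: FDR<%g fold>=%g reads>=%g band=%g net>=%g",
                   report$thresholds$fdr_max, report$thresholds$min_fold,
                   report$thresholds$min_reads,
                   report$thresholds$band_halfwidth,
                   report$thresholds$network_min_score),
           sprintf("DE: %d (%d up / %d down); relaxed fold %g: %d",
                   report$de$n_de, report$de$n_up, report$de$n_down,
                   report$thresholds$relaxed_min_fold,
                   report$de$n_de_relaxed),
           vapply(names(report$comparisons), function(cc) {
             s <- report$comparisons[[cc]]
             sprintf("%s: departing %.1f%% / coincident %.1f%% / ambiguous %.1f%% (n=%d)",
                     cc, s$pct_departing_both, s$pct_coincident_both,
                     s$pct_ambiguous, s$n_comparable)
           }, character(1)),
           sprintf("identity: mean %.2f%%, fraction >98%%: %.3f",
                   report$identity$mean_identity,
                   report$identity$fraction_above_98),
           sprintf("network: %d clusters, Q=%.3f, ARI=%.3f",
                   report$network$n_clusters, report$network$modularity,
                   report$network$ari_vs_planted))
  writeLines(txt, file.path(out_dir, "report.txt"))
  invisible(out_dir)
}
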