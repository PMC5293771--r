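## Cross-species expression-behavior classification. A focal DE gene is
## compared, through its ortholog, with a second species sampled at two
## post-injury timepoints; the per-timepoint calls combine into a consensus
## of departing, coincident or ambiguous behavior.

.TP_LEVELS <- c("differing", "coincident", "indeterminate")
.CONSENSUS <- c("departing", "coincident", "ambiguous")

#' Classify cross-species behavior at one timepoint
#'
#' A focal DE gene *differs* from its ortholog when the other species is not
#' DE and its log2 fold change lies strictly inside the little-variation band
#' `(-band, band)`, or when both species are DE in opposite directions. It is
#' *coincident* when both are DE in the same direction. Genes hit by neither
#' rule (other species not DE but outside the band) are *indeterminate*.
#'
#' @param focal_status `"up"` or `"down"` (only focal DE genes are
#'   classified); vectorized.
#' @param other_status comparison-species status (`up`/`down`/`not_de`).
#' @param other_log2fc comparison-species log2 fold change.
#' @param band_halfwidth half-width of the open little-variation band on the
#'   log2 scale (default 0.4).
#' @return character vector over `differing` / `coincident` /
#'   `indeterminate`.
#' @examples
#' classifyAtTimepoint("up", "not_de", 0.1)   # differing
#' classifyAtTimepoint("up", "up", 2.0)       # coincident
#' classifyAtTimepoint("up", "not_de", 0.8)   # indeterminate
#' @export
classifyAtTimepoint <- function(focal_status, other_status, other_log2fc,
                                band_halfwidth = 0.4) {
  stopifnot(band_halfwidth > 0)
  if (any(!focal_status %in% c("up", "down")))
    stopf("classifyAtTimepoint: focal_status must be 'up' or 'down'")
  if (any(!other_status %in% c("up", "down", "not_de")))
    stopf("classifyAtTimepoint: invalid other_status")
  focal_sign <- ifelse(focal_status == "up", 1, -1)
  other_de <- other_status != "not_de"
  other_sign <- ifelse(other_status == "up", 1,
                       ifelse(other_status == "down", -1, 0))
  in_band <- other_log2fc > -band_halfwidth & other_log2fc < band_halfwidth
  differing <- (!other_de & in_band) | (other_de & other_sign != focal_sign)
  coincident <- other_de & other_sign == focal_sign
  ifelse(differing, "differing",
         ifelse(coincident, "coincident", "indeterminate"))
}

#' Combine two timepoint calls into a consensus behavior
#'
#' Departing iff differing at both timepoints; coincident iff coincident at
#' both; every other combination is ambiguous. The three classes partition
#' the comparable genes.
#'
#' @param status_t1,status_t2 per-timepoint calls from
#'   [classifyAtTimepoint()]; vectorized.
#' @return character vector over `departing` / `coincident` / `ambiguous`.
#' @examples
#' classifyGene("differing", "differing")    # departing
#' classifyGene("coincident", "differing")   # ambiguous
#' @export
classifyGene <- function(status_t1, status_t2) {
  if (any(!c(status_t1, status_t2) %in% .TP_LEVELS))
    stopf("classifyGene: timepoint statuses must be one of %s",
          paste(.TP_LEVELS, collapse = "/"))
  ifelse(status_t1 == "differing" & status_t2 == "differing", "departing",
         ifelse(status_t1 == "coincident" & status_t2 == "coincident",
                "coincident", "ambiguous"))
}

#' Classify a full comparison
#'
#' Joins the focal DE calls to a comparison species' two timepoint tables via
#' an ortholog map and classifies every focal DE gene. Genes without an
#' ortholog, or whose ortholog is missing from either timepoint table, are
#' flagged non-comparable and carry no consensus.
#'
#' @param focal_calls named character vector (gene id -> `up`/`down`) of
#'   focal DE genes, or a called DE table (rows with status `up`/`down` are
#'   used).
#' @param other_tables list of exactly two data.frames (one per timepoint)
#'   with columns `gene_id`, `log2fc`, `status`.
#' @param ortholog_map data.frame with columns `focal_id`, `other_id`.
#' @param band_halfwidth see [classifyAtTimepoint()].
#' @return data.frame: `gene_id`, `other_id`, `focal_status`, `status_t1`,
#'   `status_t2`, `consensus`, `comparable`.
#' @export
classifyComparison <- function(focal_calls, other_tables, ortholog_map,
                               band_halfwidth = 0.4) {
  if (is.data.frame(focal_calls)) {
    de <- focal_calls[focal_calls$status %in% c("up", "down"), ]
    focal_calls <- setNames(de$status, de$gene_id)
  }
  if (length(other_tables) != 2)
    stopf("classifyComparison: exactly two timepoint tables are required")
  for (t in other_tables)
    if (!all(c("gene_id", "log2fc", "status") %in% names(t)))
      stopf("classifyComparison: timepoint tables need gene_id, log2fc, status")
  genes <- names(focal_calls)
  other <- ortholog_map$other_id[match(genes, ortholog_map$focal_id)]
  i1 <- match(other, other_tables[[1]]$gene_id)
  i2 <- match(other, other_tables[[2]]$gene_id)
  comparable <- !is.na(other) & !is.na(i1) & !is.na(i2)
  st1 <- st2 <- cons <- rep(NA_character_, length(genes))
  if (any(comparable)) {
    st1[comparable] <- classifyAtTimepoint(
      focal_calls[comparable], other_tables[[1]]$status[i1[comparable]],
      other_tables[[1]]$log2fc[i1[comparable]], band_halfwidth)
    st2[comparable] <- classifyAtTimepoint(
      focal_calls[comparable], other_tables[[2]]$status[i2[comparable]],
      other_tables[[2]]$log2fc[i2[comparable]], band_halfwidth)
    cons[comparable] <- classifyGene(st1[comparable], st2[comparable])
  }
  data.frame(gene_id = genes, other_id = other,
             focal_status = unname(focal_calls),
             status_t1 = st1, status_t2 = st2, consensus = cons,
             comparable = comparable, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Summarize a comparison into a Table-1-style row
#'
#' Percentages are over comparable genes only. The three consensus
#' percentages sum to 100 (up to floating point); per-timepoint differing
#' percentages are computed independently.
#'
#' @param calls output of [classifyComparison()].
#' @return one-row data.frame: `n_comparable`, `pct_differing_t1`,
#'   `pct_differing_t2`, `pct_departing_both`, `pct_coincident_both`,
#'   `pct_ambiguous`. With zero comparable genes, `n_comparable = 0` and the
#'   percentages are `NA` (no division error).
#' @export
summarizeComparison <- function(calls) {
  cc <- calls[calls$comparable, , drop = FALSE]
  n <- nrow(cc)
  if (n == 0)
    return(data.frame(n_comparable = 0L, pct_differing_t1 = NA_real_,
                      pct_differing_t2 = NA_real_,
                      pct_departing_both = NA_real_,
                      pct_coincident_both = NA_real_,
                      pct_ambiguous = NA_real_))
  data.frame(
    n_comparable = n,
    pct_differing_t1 = 100 * mean(cc$status_t1 == "differing"),
    pct_differing_t2 = 100 * mean(cc$status_t2 == "differing"),
    pct_departing_both = 100 * mean(cc$consensus == "departing"),
    pct_coincident_both = 100 * mean(cc$consensus == "coincident"),
    pct_ambiguous = 100 * mean(cc$consensus == "ambiguous"))
}

#' Overlay two comparisons into double-behavior categories
#'
#' A focal DE gene is `double_coincident_(up|down)` when its consensus is
#' coincident in both comparisons, `double_departing_(up|down)` when
#' departing in both (direction from the focal call); ambiguous or
#' one-comparison-only genes are `excluded`.
#'
#' @param callsA,callsB outputs of [classifyComparison()] over the same focal
#'   DE set.
#' @param focal_calls named character vector gene id -> `up`/`down`.
#' @return named character vector of categories over the union of gene ids.
#' @export
doubleBehaviorOverlay <- function(callsA, callsB, focal_calls) {
  genes <- union(callsA$gene_id, callsB$gene_id)
  consA <- callsA$consensus[match(genes, callsA$gene_id)]
  consA[!genes %in% callsA$gene_id[callsA$comparable]] <- NA
  consB <- callsB$consensus[match(genes, callsB$gene_id)]
  consB[!genes %in% callsB$gene_id[callsB$comparable]] <- NA
  dir <- ifelse(unname(focal_calls[genes]) == "up", "up", "down")
  out <- rep("excluded", length(genes))
  both <- !is.na(consA) & !is.na(consB)
  dc <- both & consA == "coincident" & consB == "coincident"
  dd <- both & consA == "departing" & consB == "departing"
  out[dc] <- paste0("double_coincident_", dir[dc])
  out[dd] <- paste0("double_departing_", dir[dd])
  n_dropped <- sum(!both)
  if (n_dropped > 0)
    message(sprintf("doubleBehaviorOverlay: %d gene(s) not comparable in both comparisons, excluded",
                    n_dropped))
  setNames(out, genes)
}
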