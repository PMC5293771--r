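## Term-enrichment testing: isoform collapsing, one-sided Fisher's exact
## test, BH FDR and information-content filtering. The same machinery serves
## GO terms, pathway labels, or any other gene -> term annotation.

#' Collapse isoform-level annotations to gene level
#'
#' A gene's term set is the union over its isoforms; duplicate (gene, term)
#' pairs are removed. Ids absent from the map pass through unchanged (they
#' are assumed to already be gene-level) with a message.
#'
#' @param annotation data.frame with columns `gene_id`, `term_id` (gene_id
#'   may hold isoform ids).
#' @param isoform_map data.frame with columns `isoform_id`, `gene_id`.
#' @return gene-level annotation data.frame, no duplicates.
#' @examples
#' ann <- data.frame(gene_id = c("G1.1", "G1.2"), term_id = c("T1", "T2"))
#' map <- data.frame(isoform_id = c("G1.1", "G1.2"), gene_id = "G1")
#' collapseIsoforms(ann, map)
#' @export
collapseIsoforms <- function(annotation, isoform_map) {
  stopifnot(all(c("gene_id", "term_id") %in% names(annotation)),
            all(c("isoform_id", "gene_id") %in% names(isoform_map)))
  idx <- match(annotation$gene_id, isoform_map$isoform_id)
  unmapped <- sum(is.na(idx) & !annotation$gene_id %in% isoform_map$gene_id)
  if (unmapped > 0)
    message(sprintf("collapseIsoforms: %d association(s) with unmapped ids passed through as gene-level",
                    unmapped))
  gene <- ifelse(is.na(idx), annotation$gene_id, isoform_map$gene_id[idx])
  out <- unique(data.frame(gene_id = gene, term_id = annotation$term_id,
                           stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' One-sided (over-representation) Fisher's exact test
#'
#' Upper-tail hypergeometric probability `P(X >= k)` for
#' `X ~ Hypergeom(N, K, n)`: the chance of seeing at least `k` annotated
#' genes in a test set of size `n` drawn from a reference of `N` genes of
#' which `K` carry the term.
#'
#' @param k test-set genes with the term.
#' @param n test-set size.
#' @param K reference genes with the term.
#' @param N reference size.
#' @return p-value. Vectorized over its arguments.
#' @examples
#' fisherOneSided(4, 4, 5, 10)  # 5/210
#' @export
fisherOneSided <- function(k, n, K, N) {
  bad <- k < 0 | K < 0 | n < 0 | N < 1 | k > n | k > K | n > N | K > N
  if (any(bad))
    stopf("fisherOneSided: inconsistent counts (need 0 <= k <= min(n, K), n <= N, K <= N)")
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Term enrichment of a test gene set against a reference
#'
#' One row per term occurring in the reference annotation; one-sided Fisher
#' p-values, BH FDR across all tested terms, information content
#' `-log2(K / N)` in bits, and an `enriched` flag at `fdr < fdr_max`.
#'
#' @param test_genes character vector (must be a subset of
#'   `reference_genes`).
#' @param reference_genes character vector defining the testing universe.
#' @param annotation gene-level annotation data.frame (`gene_id`, `term_id`);
#'   associations outside the reference are ignored.
#' @param fdr_max enrichment threshold (default 0.05).
#' @return data.frame: `term_id`, `k`, `n`, `K`, `N`, `pvalue`, `fdr`, `ic`,
#'   `enriched`, ordered by p-value. Empty test set returns an empty table
#'   with a warning.
#' @export
enrich <- function(test_genes, reference_genes, annotation, fdr_max = 0.05) {
  test_genes <- unique(test_genes)
  reference_genes <- unique(reference_genes)
  if (!all(test_genes %in% reference_genes))
    stopf("enrich: test set must be a subset of the reference")
  empty <- data.frame(term_id = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(), pvalue = numeric(),
                      fdr = numeric(), ic = numeric(), enriched = logical())
  if (length(test_genes) == 0) {
    warning("enrich: empty test set")
    return(empty)
  }
  ann <- unique(annotation[annotation$gene_id %in% reference_genes,
                           c("gene_id", "term_id")])
  if (nrow(ann) == 0) return(empty)
  N <- length(reference_genes)
  n <- length(test_genes)
  Kv <- table(ann$term_id)
  kt <- table(ann$term_id[ann$gene_id %in% test_genes])
  terms <- sort(names(Kv))
  K <- as.integer(Kv[terms])
  k <- as.integer(kt[terms]); k[is.na(k)] <- 0L
  p <- fisherOneSided(k, n, K, N)
  fdr <- benjaminiHochberg(p)
  out <- data.frame(term_id = terms, k = k, n = n, K = K, N = N,
                    pvalue = p, fdr = fdr, ic = -log2(K / N),
                    enriched = fdr < fdr_max, stringsAsFactors = FALSE)
  out <- out[order(out$pvalue, out$term_id), ]
  rownames(out) <- NULL
  out
}

# descendants of each term under a term -> parent table; errors on cycles
.descendants <- function(parents) {
  kids <- split(parents$term_id, parents$parent_id)
  memo <- new.env(parent = emptyenv())
  visiting <- new.env(parent = emptyenv())
  rec <- function(t) {
    if (!is.null(memo[[t]])) return(memo[[t]])
    if (isTRUE(visiting[[t]]))
      stopf("filterMostSpecific: cycle detected in term-parent table at '%s'", t)
    visiting[[t]] <- TRUE
    ch <- kids[[t]]
    res <- character()
    for (c in ch) res <- union(res, c(c, rec(c)))
    visiting[[t]] <- FALSE
    memo[[t]] <- res
    res
  }
  all_terms <- union(parents$term_id, parents$parent_id)
  setNames(lapply(all_terms, rec), all_terms)
}

#' Keep only the most specific enriched terms
#'
#' Drops rows whose information content is below `ic_min` (a term annotated
#' to every reference gene has IC 0 and is never specific). If a term ->
#' parent table is supplied, additionally drops any enriched term that has an
#' enriched descendant of equal or higher IC — the descendant carries the
#' more specific signal.
#'
#' @param rows enrichment table from [enrich()].
#' @param ic_min minimum information content in bits (default 2, i.e. the
#'   term covers less than a quarter of the reference).
#' @param parents optional data.frame (`term_id`, `parent_id`); cycles raise
#'   an error.
#' @return filtered enrichment table.
#' @export
filterMostSpecific <- function(rows, ic_min = 2, parents = NULL) {
  keep <- rows$ic >= ic_min
  out <- rows[keep, , drop = FALSE]
  if (!is.null(parents) && nrow(out)) {
    stopifnot(all(c("term_id", "parent_id") %in% names(parents)))
    desc <- .descendants(parents)
    enr <- out$term_id[out$enriched]
    icof <- setNames(out$ic, out$term_id)
    drop <- vapply(out$term_id, function(t) {
      if (!t %in% enr) return(FALSE)
      d <- intersect(desc[[t]], enr)
      any(icof[d] >= icof[t])
    }, logical(1))
    out <- out[!drop, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}
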