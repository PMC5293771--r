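#' @import methods
#' @importFrom stats p.adjust phyper pnorm rbinom rexp rnorm runif setNames
#' @importFrom utils read.delim write.table head
#' @useDynLib crossSCI, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## ---------------------------------------------------------------------------
## SimConfig
## ---------------------------------------------------------------------------

#' Simulation configuration for the synthetic-data generators
#'
#' Holds every knob of the synthetic differential-expression study: the number
#' of genes, the planted up/down DE fractions, the effect-size and noise model
#' on the log2 fold-change scale, the per-comparison behavior-category
#' fractions, the ortholog-missingness rate and the per-species timepoint
#' labels. Defaults emulate a study design with one focal timepoint (4 days
#' post injury) against two comparison timepoints per species.
#'
#' @slot n_genes number of genes simulated.
#' @slot seed integer master seed; every generator substream derives from it.
#' @slot de_fraction_up,de_fraction_down planted proportions of up- and
#'   down-regulated genes.
#' @slot effect_mu mean |log2FC| for DE genes (an Exponential(1) draw is added
#'   on top, so `effect_mu` is also the minimum planted effect).
#' @slot null_sigma standard deviation of non-DE log2FC noise.
#' @slot low_count_fraction fraction of DE genes forced below the 50-read
#'   floor, to exercise that filter.
#' @slot behavior_fractions named list; one numeric vector
#'   `c(departing=, coincident=, ambiguous=)` per comparison, each summing
#'   to 1.
#' @slot missing_fraction per-comparison probability that a focal gene has no
#'   ortholog.
#' @slot timepoints named list of timepoint labels: entry `"focal"` has length
#'   one, every comparison entry length two.
#' @export
setClass("SimConfig", representation(
  n_genes = "numeric",
  seed = "numeric",
  de_fraction_up = "numeric",
  de_fraction_down = "numeric",
  effect_mu = "numeric",
  null_sigma = "numeric",
  low_count_fraction = "numeric",
  behavior_fractions = "list",
  missing_fraction = "numeric",
  timepoints = "list"
))

setValidity("SimConfig", function(object) {
  msg <- character()
  prop <- function(x) length(x) == 1 && is.finite(x) && x >= 0 && x <= 1
  if (length(object@n_genes) != 1 || object@n_genes < 1 ||
      object@n_genes != round(object@n_genes))
    msg <- c(msg, "n_genes must be a positive integer")
  if (!prop(object@de_fraction_up) || !prop(object@de_fraction_down))
    msg <- c(msg, "de fractions must lie in [0, 1]")
  if (prop(object@de_fraction_up) && prop(object@de_fraction_down) &&
      object@de_fraction_up + object@de_fraction_down > 1)
    msg <- c(msg, "de_fraction_up + de_fraction_down must not exceed 1")
  if (!prop(object@low_count_fraction))
    msg <- c(msg, "low_count_fraction must lie in [0, 1]")
  if (!prop(object@missing_fraction))
    msg <- c(msg, "missing_fraction must lie in [0, 1]")
  if (object@null_sigma <= 0) msg <- c(msg, "null_sigma must be positive")
  if (object@effect_mu < 0) msg <- c(msg, "effect_mu must be non-negative")
  for (nm in names(object@behavior_fractions)) {
    f <- object@behavior_fractions[[nm]]
    if (!is.numeric(f) || length(f) != 3 || any(f < 0) || any(f > 1) ||
        abs(sum(f) - 1) > 1e-9)
      msg <- c(msg, sprintf(
        "behavior_fractions[['%s']] must be 3 proportions summing to 1", nm))
    if (!identical(sort(names(f)),
                   sort(c("departing", "coincident", "ambiguous"))))
      msg <- c(msg, sprintf(
        "behavior_fractions[['%s']] must be named departing/coincident/ambiguous",
        nm))
  }
  if (!"focal" %in% names(object@timepoints) ||
      length(object@timepoints$focal) != 1)
    msg <- c(msg, "timepoints must contain a length-1 'focal' entry")
  comps <- setdiff(names(object@timepoints), "focal")
  if (!setequal(comps, names(object@behavior_fractions)))
    msg <- c(msg, "comparison names must match between timepoints and behavior_fractions")
  for (nm in comps)
    if (length(object@timepoints[[nm]]) != 2)
      msg <- c(msg, sprintf("timepoints[['%s']] must have two labels", nm))
  if (length(msg)) msg else TRUE
})

#' Create a simulation configuration
#'
#' Defaults mirror a vertebrate spinal-cord-injury comparison: ~20,000 genes
#' with roughly 4% up- and 1.3% down-regulated, a mouse comparison planted at
#' (departing, coincident, ambiguous) = (0.26, 0.58, 0.16) and two Xenopus
#' stages at (0.47, 0.13, 0.40) and (0.31, 0.37, 0.32).
#'
#' @param n_genes number of genes.
#' @param seed master seed.
#' @param de_fraction_up,de_fraction_down planted DE fractions.
#' @param effect_mu mean |log2FC| of DE genes (log2 units). The default,
#'   `log2(1.8)`, places the planted effect floor at the relaxed fold
#'   threshold so the strict (fold 2) and relaxed (fold 1.8) criteria call
#'   different gene sets, as with real data.
#' @param null_sigma sd of null log2FC noise (log2 units).
#' @param low_count_fraction fraction of DE genes forced below the read floor.
#' @param behavior_fractions named list of 3-vectors summing to 1.
#' @param missing_fraction ortholog-absence probability per comparison.
#' @param timepoints named list of timepoint labels (see class docs).
#' @return A validated [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(n_genes = 1000, seed = 7)
#' cfg
#' @export
simConfig <- function(n_genes = 20000,
                      seed = 1,
                      de_fraction_up = 0.04,
                      de_fraction_down = 0.013,
                      effect_mu = log2(1.8),
                      null_sigma = 0.25,
                      low_count_fraction = 0.05,
                      behavior_fractions = list(
                        mouse = c(departing = 0.26, coincident = 0.58,
                                  ambiguous = 0.16),
                        xenopus_regenerative = c(departing = 0.47,
                                                 coincident = 0.13,
                                                 ambiguous = 0.40),
                        xenopus_nonregenerative = c(departing = 0.31,
                                                    coincident = 0.37,
                                                    ambiguous = 0.32)),
                      missing_fraction = 0.1,
                      timepoints = NULL) {
  if (is.null(timepoints)) {
    timepoints <- c(list(focal = "4d"),
                    lapply(behavior_fractions, function(x) c("2d", "7d")))
    for (nm in grep("^xenopus", names(timepoints), value = TRUE))
      timepoints[[nm]] <- c("2d", "6d")
  }
  new("SimConfig", n_genes = n_genes, seed = seed,
      de_fraction_up = de_fraction_up, de_fraction_down = de_fraction_down,
      effect_mu = effect_mu, null_sigma = null_sigma,
      low_count_fraction = low_count_fraction,
      behavior_fractions = behavior_fractions,
      missing_fraction = missing_fraction, timepoints = timepoints)
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@n_genes, "genes, seed", object@seed, "\n")
  cat("  DE fractions: up", object@de_fraction_up,
      "down", object@de_fraction_down, "\n")
  cat("  comparisons:", paste(names(object@behavior_fractions),
                              collapse = ", "), "\n")
})

## ---------------------------------------------------------------------------
## DECriteria
## ---------------------------------------------------------------------------

#' Differential-expression calling criteria
#'
#' The triple criterion used to call a gene differentially expressed: FDR
#' strictly below `fdr_max`, linear fold change of at least `min_fold` in
#' either direction, and at least `min_reads` mean mapped reads in one of the
#' two conditions. The read floor can alternatively be applied to the sum of
#' the two condition means (`read_basis = "sum"`).
#'
#' @slot fdr_max FDR threshold (strict; default 0.1).
#' @slot min_fold linear fold-change threshold (inclusive; default 2; a
#'   relaxed variant uses 1.8).
#' @slot min_reads read floor (inclusive; default 50).
#' @slot read_basis `"max"` (floor on the larger condition mean, the default
#'   reading of "in at least one of the conditions") or `"sum"`.
#' @export
setClass("DECriteria", representation(
  fdr_max = "numeric", min_fold = "numeric", min_reads = "numeric",
  read_basis = "character"
))

setValidity("DECriteria", function(object) {
  msg <- character()
  if (!(object@fdr_max > 0 && object@fdr_max <= 1))
    msg <- c(msg, "fdr_max must lie in (0, 1]")
  if (object@min_fold <= 1) msg <- c(msg, "min_fold must exceed 1")
  if (object@min_reads < 0) msg <- c(msg, "min_reads must be >= 0")
  if (!object@read_basis %in% c("max", "sum"))
    msg <- c(msg, "read_basis must be 'max' or 'sum'")
  if (length(msg)) msg else TRUE
})

#' Create DE-calling criteria
#'
#' @param fdr_max FDR threshold (strict inequality).
#' @param min_fold linear fold-change threshold (inclusive).
#' @param min_reads minimum mean reads in at least one condition (inclusive).
#' @param read_basis `"max"` or `"sum"`; see [DECriteria-class].
#' @return A validated [DECriteria-class] object.
#' @examples
#' deCriteria()                 # FDR < 0.1, fold >= 2, >= 50 reads
#' deCriteria(min_fold = 1.8)   # the relaxed variant
#' @export
deCriteria <- function(fdr_max = 0.1, min_fold = 2, min_reads = 50,
                       read_basis = "max") {
  new("DECriteria", fdr_max = fdr_max, min_fold = min_fold,
      min_reads = min_reads, read_basis = read_basis)
}

setMethod("show", "DECriteria", function(object) {
  cat(sprintf("DECriteria: FDR < %g, fold >= %g, reads(%s) >= %g\n",
              object@fdr_max, object@min_fold, object@read_basis,
              object@min_reads))
})

## ---------------------------------------------------------------------------
## PresenceMatrix
## ---------------------------------------------------------------------------

#' Gene-by-species presence/identity matrix
#'
#' A phylogenetic profile of a gene set: for each gene and species the
#' ortholog is `present` (with a percent identity versus the focal species),
#' `absent`, or `ambiguous` (an ortholog could not be unambiguously
#' identified). Species are grouped into named clades (e.g. mammals,
#' amniotes, tetrapods, fish) used by [classifyPresence()].
#'
#' @slot status character matrix (genes x species) over
#'   `{"present","absent","ambiguous"}`.
#' @slot identity numeric matrix (genes x species), percent identity in
#'   `[0, 100]` where present, `NA` otherwise.
#' @slot clades named list of character vectors of species names.
#' @slot focal name of the focal species (always present, identity 100).
#' @export
setClass("PresenceMatrix", representation(
  status = "matrix", identity = "matrix", clades = "list", focal = "character"
))

setValidity("PresenceMatrix", function(object) {
  msg <- character()
  st <- object@status; id <- object@identity
  if (!identical(dim(st), dim(id)))
    msg <- c(msg, "status and identity matrices must share dimensions")
  if (is.null(rownames(st)) || is.null(colnames(st)))
    msg <- c(msg, "status matrix must carry gene and species dimnames")
  if (!all(st %in% c("present", "absent", "ambiguous")))
    msg <- c(msg, "status cells must be present/absent/ambiguous")
  pres <- st == "present"
  if (any(is.na(id[pres])) || any(id[pres] < 0) || any(id[pres] > 100))
    msg <- c(msg, "identity must lie in [0, 100] wherever present")
  if (!all(unlist(object@clades) %in% colnames(st)))
    msg <- c(msg, "clades reference species absent from the matrix")
  if (!all(colnames(st) %in% c(unlist(object@clades), object@focal)))
    msg <- c(msg, "every species must belong to at least one clade")
  if (length(object@focal) == 1 && object@focal %in% colnames(st)) {
    if (!all(st[, object@focal] == "present") ||
        !all(id[, object@focal] == 100))
      msg <- c(msg, "focal species must be present with identity 100")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PresenceMatrix
#'
#' @param status character matrix over present/absent/ambiguous with gene row
#'   names and species column names.
#' @param identity numeric matrix of percent identities (NA where not
#'   present).
#' @param clades named list of species groupings.
#' @param focal focal species name.
#' @return A validated [PresenceMatrix-class].
#' @export
presenceMatrix <- function(status, identity, clades, focal) {
  new("PresenceMatrix", status = status, identity = identity,
      clades = clades, focal = focal)
}

setMethod("show", "PresenceMatrix", function(object) {
  cat("PresenceMatrix:", nrow(object@status), "genes x",
      ncol(object@status), "species (focal:", object@focal, ")\n")
  tab <- table(factor(object@status,
                      levels = c("present", "absent", "ambiguous")))
  cat("  cells:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  cat("  clades:", paste(names(object@clades), collapse = ", "), "\n")
})

#' @describeIn presenceMatrix Gene identifiers of a PresenceMatrix.
#' @param x a `PresenceMatrix`.
#' @export
geneIds <- function(x) rownames(x@status)

#' @describeIn presenceMatrix Species names of a PresenceMatrix.
#' @export
speciesNames <- function(x) colnames(x@status)

#' @describeIn presenceMatrix Clade configuration of a PresenceMatrix.
#' @export
cladeConfig <- function(x) x@clades

## ---------------------------------------------------------------------------
## GeneNetwork
## ---------------------------------------------------------------------------

#' Weighted undirected gene-interaction network
#'
#' Nodes are genes; edges carry an interaction confidence score in `[0, 1]`
#' (STRING-style). After clustering, each node has a cluster id; after a
#' behavior overlay, a category label.
#'
#' @slot nodes character vector of gene ids.
#' @slot edges data.frame with columns `node_a`, `node_b`, `score`;
#'   canonicalized so `node_a < node_b`, no self-loops, no duplicates.
#' @slot clusters named integer vector (may be empty before clustering).
#' @slot overlay named character vector of behavior categories (may be
#'   empty).
#' @export
setClass("GeneNetwork", representation(
  nodes = "character", edges = "data.frame",
  clusters = "integer", overlay = "character"
))

setValidity("GeneNetwork", function(object) {
  msg <- character()
  e <- object@edges
  if (!all(c("node_a", "node_b", "score") %in% names(e)))
    msg <- c(msg, "edges must have columns node_a, node_b, score")
  else {
    if (anyDuplicated(object@nodes)) msg <- c(msg, "duplicate node ids")
    if (any(e$node_a == e$node_b)) msg <- c(msg, "self-loops are not allowed")
    if (!all(c(e$node_a, e$node_b) %in% object@nodes))
      msg <- c(msg, "edge endpoints must be declared nodes")
    if (any(e$score < 0 | e$score > 1) || any(!is.finite(e$score)))
      msg <- c(msg, "scores must lie in [0, 1]")
    key <- paste(pmin(e$node_a, e$node_b), pmax(e$node_a, e$node_b))
    if (anyDuplicated(key)) msg <- c(msg, "duplicate edges are not allowed")
  }
  if (length(object@clusters) &&
      !all(names(object@clusters) %in% object@nodes))
    msg <- c(msg, "cluster ids assigned to unknown nodes")
  if (length(msg)) msg else TRUE
})

#' Construct a GeneNetwork from an edge list
#'
#' Edge endpoints are canonicalized (lexicographically smaller id first);
#' isolated nodes can be declared through `nodes`.
#'
#' @param edges data.frame with columns `node_a`, `node_b`, `score`.
#' @param nodes optional character vector of node ids (defaults to the union
#'   of edge endpoints; ids not in any edge become isolated nodes).
#' @return A validated [GeneNetwork-class].
#' @examples
#' gn <- geneNetwork(data.frame(node_a = "g1", node_b = "g2", score = 0.9))
#' gn
#' @export
geneNetwork <- function(edges, nodes = NULL) {
  edges <- as.data.frame(edges)
  stopifnot(all(c("node_a", "node_b", "score") %in% names(edges)))
  edges$node_a <- as.character(edges$node_a)
  edges$node_b <- as.character(edges$node_b)
  a <- pmin(edges$node_a, edges$node_b)
  b <- pmax(edges$node_a, edges$node_b)
  edges$node_a <- a; edges$node_b <- b
  edges <- edges[order(edges$node_a, edges$node_b), , drop = FALSE]
  rownames(edges) <- NULL
  if (is.null(nodes)) nodes <- sort(unique(c(edges$node_a, edges$node_b)))
  else nodes <- sort(unique(c(nodes, edges$node_a, edges$node_b)))
  new("GeneNetwork", nodes = nodes, edges = edges,
      clusters = integer(), overlay = character())
}

setMethod("show", "GeneNetwork", function(object) {
  cat("GeneNetwork:", length(object@nodes), "nodes,",
      nrow(object@edges), "edges\n")
  if (length(object@clusters))
    cat("  clusters:", length(unique(object@clusters)), "\n")
  if (length(object@overlay))
    cat("  overlay categories:",
        paste(sort(unique(object@overlay)), collapse = ", "), "\n")
})

#' @describeIn geneNetwork Node ids.
#' @param x a `GeneNetwork`.
#' @export
nodeIds <- function(x) x@nodes

#' @describeIn geneNetwork Edge table (node_a, node_b, score).
#' @export
edgeTable <- function(x) x@edges

#' @describeIn geneNetwork Named integer cluster assignment (empty before
#'   clustering).
#' @export
clusterIds <- function(x) x@clusters

#' @describeIn geneNetwork Named character overlay categories (empty before
#'   overlay).
#' @export
overlayCategories <- function(x) x@overlay
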