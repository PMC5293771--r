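## Synthetic-data generators with planted ground truth. Every input the
## pipeline consumes (DE tables, ortholog maps, presence matrices, sequence
## pairs, annotations, interaction networks) can be emulated here, so the full
## analysis is testable without any external download.

#' Default vertebrate species panel
#'
#' A nine-species panel spanning the vertebrate taxonomic diversity used for
#' phylogenetic profiling: the focal turtle, three mammals, two sauropsids, a
#' second turtle, an amphibian and a teleost fish.
#' @return Character vector of species labels.
#' @export
defaultSpeciesPanel <- function() {
  c("T_scripta", "human", "mouse", "opossum", "chicken", "anole",
    "P_sinensis", "X_tropicalis", "D_rerio")
}

#' Default clade configuration for the species panel
#'
#' Named species groupings used by [classifyPresence()]: `amniotes`,
#' `tetrapods` and `fish` are required by the classifier; `mammals` and
#' `turtles` additionally support clade-wide-absence calls.
#' @return Named list of character vectors.
#' @export
defaultClades <- function() {
  amniotes <- c("T_scripta", "human", "mouse", "opossum", "chicken",
                "anole", "P_sinensis")
  list(turtles = c("T_scripta", "P_sinensis"),
       mammals = c("human", "mouse", "opossum"),
       amniotes = amniotes,
       tetrapods = c(amniotes, "X_tropicalis"),
       fish = "D_rerio")
}

## draw helpers used when planting comparison-species behavior ----------------

# Coincident at a timepoint: DE in the comparison species, same direction.
.drawCoincident <- function(sgn) {
  fc <- sgn * (1 + rexp(1))
  list(fc = fc, status = if (sgn > 0) "up" else "down",
       p = runif(1, 1e-8, 1e-3))
}

# Differing at a timepoint: either flat (inside the +/-0.4 band; rejection-
# sampled within (-0.35, 0.35) to keep planted labels away from the boundary)
# or DE in the opposite direction.
.drawDiffering <- function(sgn) {
  if (runif(1) < 0.5) {
    list(fc = runif(1, -0.35, 0.35), status = "not_de", p = runif(1, 0.2, 1))
  } else {
    fc <- -sgn * (1 + rexp(1))
    list(fc = fc, status = if (fc > 0) "up" else "down",
         p = runif(1, 1e-8, 1e-3))
  }
}

#' Generate DE summary tables with planted truth
#'
#' Simulates the focal species' per-gene differential-expression summary (one
#' timepoint) plus, for every configured comparison species, an ortholog map
#' and two-timepoint DE tables whose rows are planted to exhibit a chosen
#' cross-species behavior category (departing / coincident / ambiguous).
#'
#' Non-DE genes draw `log2fc ~ Normal(0, null_sigma)` and `p ~ Uniform(0,1)`.
#' DE genes draw `|log2fc| = effect_mu + Exponential(1)` with the planted sign
#' and a two-sided normal-tail p-value of `z = log2fc / null_sigma`, floored
#' at 1e-300. Condition means are log-uniform on `[1, 1e4]`; a configurable
#' fraction of DE genes is forced below the 50-read floor to exercise that
#' filter. Behavior categories are apportioned over comparable focal DE genes
#' by deterministic largest-remainder allocation of the configured fractions,
#' then assigned in seeded-shuffled order.
#'
#' @param config a [SimConfig-class] object.
#' @return A list with elements
#'   \describe{
#'     \item{tables}{`focal` data.frame plus `comparisons`, a named list of
#'       per-timepoint data.frames (columns gene_id, mean_ctrl, mean_case,
#'       log2fc, pvalue, status).}
#'     \item{ortholog_maps}{named list of data.frames (focal_id, other_id).}
#'     \item{truth}{planted labels: `status` (named character),
#'       `behavior` (per comparison, named over comparable focal DE genes),
#'       `low_count_genes`.}
#'   }
#' @examples
#' sim <- genDETables(simConfig(n_genes = 500, seed = 42))
#' head(sim$tables$focal)
#' table(sim$truth$status)
#' @export
genDETables <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  n <- config@n_genes
  ids <- sprintf("g%05d", seq_len(n))

  focal <- withSeed(facetSeed(config@seed, "de_focal"), {
    status <- sample(c("up", "down", "not_de"), n, replace = TRUE,
                     prob = c(config@de_fraction_up, config@de_fraction_down,
                              1 - config@de_fraction_up - config@de_fraction_down))
    log2fc <- rnorm(n, 0, config@null_sigma)
    pvalue <- runif(n)
    de <- status != "not_de"
    if (any(de)) {
      sgn <- ifelse(status[de] == "up", 1, -1)
      log2fc[de] <- sgn * (config@effect_mu + rexp(sum(de)))
      pvalue[de] <- pmax(2 * pnorm(-abs(log2fc[de]) / config@null_sigma),
                         1e-300)
    }
    mean_ctrl <- 10^runif(n, 0, 4)
    mean_case <- mean_ctrl * 2^log2fc
    low <- character()
    n_low <- floor(config@low_count_fraction * sum(de))
    if (n_low > 0) {
      pick <- sample(which(de), n_low)
      target <- runif(n_low, 5, 49.5)
      fac <- target / pmax(mean_ctrl[pick], mean_case[pick])
      mean_ctrl[pick] <- mean_ctrl[pick] * fac
      mean_case[pick] <- mean_case[pick] * fac
      low <- ids[pick]
    }
    list(table = data.frame(gene_id = ids, mean_ctrl = mean_ctrl,
                            mean_case = mean_case, log2fc = log2fc,
                            pvalue = pvalue, stringsAsFactors = FALSE),
         status = setNames(status, ids), low_count = low)
  })

  comps <- names(config@behavior_fractions)
  comparisons <- list(); maps <- list(); behavior <- list()
  for (comp in comps) {
    res <- withSeed(facetSeed(config@seed, paste0("cmp_", comp)), {
      has <- runif(n) >= config@missing_fraction
      other_ids <- paste0(comp, "_", ids)
      map <- data.frame(focal_id = ids[has], other_id = other_ids[has],
                        stringsAsFactors = FALSE)
      midx <- which(has)
      nm <- length(midx)
      # baseline (focal not-DE orthologs): null noise, called not_de upstream
      mk_tp <- function() {
        fc <- rnorm(nm, 0, config@null_sigma)
        data.frame(gene_id = other_ids[midx],
                   mean_ctrl = 10^runif(nm, 0, 4),
                   mean_case = NA_real_, log2fc = fc, pvalue = runif(nm),
                   status = rep("not_de", nm), stringsAsFactors = FALSE)
      }
      t1 <- mk_tp(); t2 <- mk_tp()
      de_loc <- which(focal$status[midx] != "not_de")
      frac <- config@behavior_fractions[[comp]][
        c("departing", "coincident", "ambiguous")]
      counts <- largestRemainder(length(de_loc), frac)
      cat_vec <- rep(c("departing", "coincident", "ambiguous"), counts)
      de_loc <- de_loc[sample.int(length(de_loc))]  # seeded shuffle
      beh <- setNames(cat_vec, ids[midx][de_loc])
      for (j in seq_along(de_loc)) {
        i <- de_loc[j]
        sgn <- if (focal$status[midx][i] == "up") 1 else -1
        d <- switch(cat_vec[j],
          coincident = list(.drawCoincident(sgn), .drawCoincident(sgn)),
          departing  = list(.drawDiffering(sgn), .drawDiffering(sgn)),
          ambiguous  = if (runif(1) < 0.5)
            list(.drawCoincident(sgn), .drawDiffering(sgn))
          else list(.drawDiffering(sgn), .drawCoincident(sgn)))
        t1$log2fc[i] <- d[[1]]$fc; t1$pvalue[i] <- d[[1]]$p
        t1$status[i] <- d[[1]]$status
        t2$log2fc[i] <- d[[2]]$fc; t2$pvalue[i] <- d[[2]]$p
        t2$status[i] <- d[[2]]$status
      }
      t1$mean_case <- t1$mean_ctrl * 2^t1$log2fc
      t2$mean_case <- t2$mean_ctrl * 2^t2$log2fc
      tps <- config@timepoints[[comp]]
      list(tables = setNames(list(t1, t2), tps), map = map, behavior = beh)
    })
    comparisons[[comp]] <- res$tables
    maps[[comp]] <- res$map
    behavior[[comp]] <- res$behavior
  }

  list(tables = list(focal = focal$table, comparisons = comparisons),
       ortholog_maps = maps,
       truth = list(status = focal$status, behavior = behavior,
                    low_count_genes = focal$low_count),
       config = config)
}

#' Generate a presence/identity matrix with planted phylogenetic categories
#'
#' Plants genes in six distribution categories: universal presence,
#' single-species absences (with or without support from a confirm species),
#' clade-wide absence (all mammals), amniote-specific profiles (absent in both
#' anamniotes), tetrapod-innovation candidates (absent only in the fish) and
#' scattered absences. Identity values for present cells are Uniform(60, 100);
#' the focal species is always present at 100. For single-species absences a
#' confirm-species presence flag is drawn (`rescue_fraction` present, i.e.
#' annotation gaps); for innovation candidates, presence in two outgroup fish
#' is drawn (`outgroup_loss_fraction` of candidates are present in at least
#' one outgroup, i.e. lineage losses).
#'
#' @param n_genes number of genes.
#' @param seed integer seed.
#' @param species species panel (first element must be the focal species).
#' @param clades named clade list covering the panel.
#' @param category_fractions named proportions over the six categories,
#'   summing to 1 (largest-remainder apportioned, so planted counts are
#'   deterministic).
#' @param rescue_fraction probability a single-species absence is present in
#'   the confirm species.
#' @param outgroup_loss_fraction probability an innovation candidate is
#'   present in at least one outgroup fish.
#' @return list with `matrix` (a [PresenceMatrix-class]), and `truth`
#'   (per-gene `category`, `confirm_presence` for single-absence genes,
#'   `outgroup_presence` logical matrix for innovation candidates).
#' @examples
#' pm <- genPresenceMatrix(n_genes = 100, seed = 3)
#' pm$matrix
#' @export
genPresenceMatrix <- function(n_genes = 500, seed = 1,
                              species = defaultSpeciesPanel(),
                              clades = defaultClades(),
                              category_fractions = c(
                                universal = 0.80,
                                single_species_absence = 0.08,
                                clade_absence = 0.03,
                                amniote_specific = 0.02,
                                tetrapod_innovation_candidate = 0.04,
                                other_scattered = 0.03),
                              rescue_fraction = 0.8,
                              outgroup_loss_fraction = 0.15) {
  stopifnot(n_genes >= 1, abs(sum(category_fractions) - 1) < 1e-9)
  focal <- species[1]
  withSeed(facetSeed(seed, "presence"), {
    ids <- sprintf("g%05d", seq_len(n_genes))
    cats <- c("universal", "single_species_absence", "clade_absence",
              "amniote_specific", "tetrapod_innovation_candidate",
              "other_scattered")
    counts <- largestRemainder(n_genes, category_fractions[cats])
    category <- setNames(sample(rep(cats, counts)), ids)

    status <- matrix("present", n_genes, length(species),
                     dimnames = list(ids, species))
    fish <- clades$fish
    anamniotes <- setdiff(species, clades$amniotes)
    single_pool <- setdiff(species, c(focal, fish))
    confirm <- logical(0); outgrp <- NULL
    for (i in seq_len(n_genes)) {
      g <- ids[i]
      switch(category[g],
        universal = NULL,
        single_species_absence = {
          sp <- sample(single_pool, 1)
          status[i, sp] <- "absent"
          confirm[g] <- runif(1) < rescue_fraction
        },
        clade_absence = { status[i, clades$mammals] <- "absent" },
        amniote_specific = { status[i, anamniotes] <- "absent" },
        tetrapod_innovation_candidate = {
          status[i, fish] <- "absent"
          if (runif(1) < outgroup_loss_fraction) {
            pres <- sample(list(c(TRUE, FALSE), c(FALSE, TRUE),
                                c(TRUE, TRUE)), 1)[[1]]
          } else pres <- c(FALSE, FALSE)
          outgrp <- rbind(outgrp, setNames(pres, c("fugu", "medaka")))
          rownames(outgrp)[nrow(outgrp)] <- g
        },
        other_scattered = {
          status[i, c(sample(clades$mammals, 1),
                      sample(c("chicken", "anole"), 1))] <- "absent"
        })
    }
    identity <- matrix(NA_real_, n_genes, length(species),
                       dimnames = list(ids, species))
    pres <- status == "present"
    identity[pres] <- runif(sum(pres), 60, 100)
    identity[, focal] <- 100
    pm <- presenceMatrix(status, identity, clades, focal)
    list(matrix = pm,
         truth = list(category = category, confirm_presence = confirm,
                      outgroup_presence = outgrp))
  })
}

#' Generate orthologous sequence pairs at a target percent identity
#'
#' The second sequence of each pair is the first with per-base substitution
#' probability `(100 - identity) / 100`, substitutions drawn uniformly over
#' the three alternative bases. No indels unless `indel_rate > 0`, in which
#' case bases of the copy are additionally deleted independently at that rate.
#'
#' @param n number of pairs.
#' @param length sequence length in bases.
#' @param identity target percent identity in `[0, 100]`; a scalar, or a
#'   length-`n` vector of per-pair targets.
#' @param seed integer seed.
#' @param indel_rate per-base deletion probability in the copy (default 0).
#' @return list with `seq_a` and `seq_b` ([Biostrings::DNAStringSet]s, names
#'   `pair0001` ...) and `target_identity`.
#' @examples
#' p <- genSequencePairs(3, 50, identity = 90, seed = 1)
#' p$seq_a
#' @export
genSequencePairs <- function(n, length, identity = 98, seed = 1,
                             indel_rate = 0) {
  stopifnot(n >= 1, length >= 1, all(identity >= 0), all(identity <= 100),
            length(identity) %in% c(1, n), indel_rate >= 0, indel_rate < 1)
  identity <- rep(identity, length.out = n)
  bases <- c("A", "C", "G", "T")
  withSeed(facetSeed(seed, "seqpairs"), {
    a <- matrix(sample.int(4L, n * length, replace = TRUE), n, length)
    # per-row substitution probability; matrix-vector comparison recycles
    # down columns, i.e. per pair
    sub <- matrix(runif(n * length), n, length) < (100 - identity) / 100
    shift <- matrix(sample.int(3L, n * length, replace = TRUE), n, length)
    b <- a
    b[sub] <- ((a[sub] - 1L + shift[sub]) %% 4L) + 1L
    seq_a <- apply(a, 1, function(r) paste(bases[r], collapse = ""))
    seq_b <- apply(b, 1, function(r) paste(bases[r], collapse = ""))
    if (indel_rate > 0)
      seq_b <- vapply(seq_b, function(s) {
        ch <- strsplit(s, "")[[1]]
        paste(ch[runif(base::length(ch)) >= indel_rate], collapse = "")
      }, character(1), USE.NAMES = FALSE)
    nm <- sprintf("pair%04d", seq_len(n))
    list(seq_a = setNames(Biostrings::DNAStringSet(seq_a), nm),
         seq_b = setNames(Biostrings::DNAStringSet(seq_b), nm),
         target_identity = identity)
  })
}

#' Generate a gene-term annotation table with planted enrichment
#'
#' Background term frequencies follow a Zipf-like law (`p_max / rank`, floored
#' at `p_min`). A designated test set of genes receives each planted term at
#' `fold_enrichment` times its background frequency (capped at 1), so the
#' enrichment stage can be validated against known positives.
#'
#' @param n_genes number of genes (ignored when `gene_ids` given).
#' @param n_terms number of annotation terms.
#' @param n_enriched number of planted enriched terms.
#' @param fold_enrichment over-assignment fold in the test set (1 = no
#'   signal).
#' @param seed integer seed.
#' @param gene_ids optional explicit gene universe.
#' @param test_genes optional explicit test set (default: the first
#'   `ceiling(test_fraction * n)` genes).
#' @param test_fraction fraction of genes in the default test set.
#' @param p_max,p_min Zipf frequency bounds.
#' @return list with `annotation` (data.frame gene_id, term_id),
#'   `test_genes`, and `truth` (data.frame term_id, enriched, base_p).
#' @examples
#' ann <- genAnnotation(n_genes = 200, n_terms = 20, seed = 5)
#' head(ann$annotation)
#' @export
genAnnotation <- function(n_genes = 5000, n_terms = 200, n_enriched = 5,
                          fold_enrichment = 5, seed = 1, gene_ids = NULL,
                          test_genes = NULL, test_fraction = 0.05,
                          p_max = 0.2, p_min = 0.002) {
  if (is.null(gene_ids)) gene_ids <- sprintf("g%05d", seq_len(n_genes))
  n <- length(gene_ids)
  if (is.null(test_genes)) test_genes <- gene_ids[seq_len(ceiling(test_fraction * n))]
  stopifnot(all(test_genes %in% gene_ids), n_enriched <= n_terms,
            fold_enrichment >= 1)
  terms <- sprintf("T%04d", seq_len(n_terms))
  base_p <- pmax(p_max / seq_len(n_terms), p_min)
  # plant mid-frequency terms so the signal is detectable but not trivial
  # fold 1 means no planted signal, so nothing is flagged as enriched
  enriched <- if (n_enriched > 0 && fold_enrichment > 1)
    terms[seq.int(3, length.out = n_enriched)] else character()
  is_test <- gene_ids %in% test_genes
  withSeed(facetSeed(seed, "annotation"), {
    rows <- vector("list", n_terms)
    for (t in seq_len(n_terms)) {
      p <- rep(base_p[t], n)
      if (terms[t] %in% enriched)
        p[is_test] <- pmin(1, fold_enrichment * base_p[t])
      hit <- runif(n) < p
      if (any(hit))
        rows[[t]] <- data.frame(gene_id = gene_ids[hit],
                                term_id = terms[t],
                                stringsAsFactors = FALSE)
    }
    list(annotation = do.call(rbind, rows[!vapply(rows, is.null, TRUE)]),
         test_genes = test_genes,
         truth = data.frame(term_id = terms,
                            enriched = terms %in% enriched,
                            base_p = base_p, stringsAsFactors = FALSE))
  })
}

#' Generate a planted-community interaction network (stochastic block model)
#'
#' Nodes are split into `n_communities` near-equal blocks; within-block pairs
#' are connected with probability `p_in`, between-block pairs with `p_out`.
#' Within-community edges receive confidence scores Uniform(0.7, 1),
#' between-community edges Uniform(0.3, 0.9), unless overridden.
#'
#' @param n_nodes number of nodes.
#' @param n_communities number of planted blocks.
#' @param p_in,p_out edge probabilities within / between blocks.
#' @param seed integer seed.
#' @param score_within,score_between length-2 score ranges.
#' @param node_ids optional node labels (default `n0001` ...).
#' @return list with `network` (a [GeneNetwork-class]) and `truth` (named
#'   integer community ids).
#' @examples
#' sbm <- genNetwork(60, 3, 0.4, 0.01, seed = 2)
#' sbm$network
#' @export
genNetwork <- function(n_nodes, n_communities, p_in, p_out, seed = 1,
                       score_within = c(0.7, 1),
                       score_between = c(0.3, 0.9), node_ids = NULL) {
  stopifnot(n_nodes >= 2, n_communities >= 1, p_in >= 0, p_in <= 1,
            p_out >= 0, p_out <= 1)
  if (is.null(node_ids)) node_ids <- sprintf("n%04d", seq_len(n_nodes))
  sizes <- largestRemainder(n_nodes, rep(1 / n_communities, n_communities))
  membership <- setNames(rep(seq_len(n_communities), sizes), node_ids)
  withSeed(facetSeed(seed, "network"), {
    idx <- which(upper.tri(matrix(0, n_nodes, n_nodes)), arr.ind = TRUE)
    same <- membership[idx[, 1]] == membership[idx[, 2]]
    keep <- runif(nrow(idx)) < ifelse(same, p_in, p_out)
    idx <- idx[keep, , drop = FALSE]; same <- same[keep]
    score <- numeric(nrow(idx))
    score[same] <- runif(sum(same), score_within[1], score_within[2])
    score[!same] <- runif(sum(!same), score_between[1], score_between[2])
    edges <- data.frame(node_a = node_ids[idx[, 1]],
                        node_b = node_ids[idx[, 2]],
                        score = score, stringsAsFactors = FALSE)
    list(network = geneNetwork(edges, nodes = node_ids), truth = membership)
  })
}
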