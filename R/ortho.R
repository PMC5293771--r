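## Ortholog-pair identity distributions and phylogenetic presence/absence
## classification, including the annotation-gap rescue and fish-outgroup
## innovation tests.

#' Global (Needleman-Wunsch) alignment of two nucleotide sequences
#'
#' Optimal global alignment under a linear gap scheme, with deterministic
#' tie-breaking (diagonal, then up, then left). `N` bases never match.
#'
#' @param seq_a,seq_b non-empty nucleotide sequences over `{A,C,G,T,N}`
#'   (character strings or [Biostrings::DNAString]s).
#' @param match,mismatch,gap scoring parameters (defaults 1 / -1 / -2).
#' @return list of class `alignedPair` with `aligned_a`, `aligned_b` (gapped
#'   strings) and `score`.
#' @examples
#' globalAlign("ACGT", "AGT")
#' @export
globalAlign <- function(seq_a, seq_b, match = 1, mismatch = -1, gap = -2) {
  seq_a <- toupper(as.character(seq_a))
  seq_b <- toupper(as.character(seq_b))
  if (nchar(seq_a) == 0 || nchar(seq_b) == 0)
    stopf("globalAlign: sequences must be non-empty")
  ok <- function(s) grepl("^[ACGTN]+$", s)
  if (!ok(seq_a) || !ok(seq_b))
    stopf("globalAlign: sequences must be over the alphabet {A,C,G,T,N}")
  res <- .nwAlignCpp(seq_a, seq_b, match, mismatch, gap)
  structure(res, class = "alignedPair")
}

#' @export
print.alignedPair <- function(x, ...) {
  cat("Global alignment (score ", x$score, "):\n", sep = "")
  cat(" ", x$aligned_a, "\n ", x$aligned_b, "\n", sep = "")
  invisible(x)
}

#' Percent identity of an aligned pair
#'
#' `100 * matches / alignment columns`, with terminal gap columns excluded
#' from the denominator: contigs are often partial transcripts, so end
#' overhangs are not evidence of divergence.
#'
#' @param alignment an `alignedPair` from [globalAlign()].
#' @return percent identity in `[0, 100]`.
#' @examples
#' percentIdentity(globalAlign("ACGT", "ACGA"))  # 75
#' @export
percentIdentity <- function(alignment) {
  a <- strsplit(alignment$aligned_a, "")[[1]]
  b <- strsplit(alignment$aligned_b, "")[[1]]
  gap <- a == "-" | b == "-"
  # trim terminal gap runs (leading/trailing columns where either side gaps)
  first <- 1L
  while (first <= length(a) && gap[first]) first <- first + 1L
  last <- length(a)
  while (last >= 1L && gap[last]) last <- last - 1L
  if (first > last)
    stopf("percentIdentity: no non-terminal alignment columns; identity undefined")
  keep <- first:last
  100 * sum(a[keep] == b[keep] & a[keep] != "-") / length(keep)
}

#' Identity distribution of a set of ortholog pairs
#'
#' Aligns each pair (unless precomputed identities are supplied) and
#' summarizes the distribution of percent identities.
#'
#' @param seq_a,seq_b parallel [Biostrings::DNAStringSet]s of ortholog pairs,
#'   or `seq_a` may be a numeric vector of precomputed identities (then
#'   `seq_b` is ignored).
#' @param breaks histogram bin edges in percent (default 2-point bins).
#' @param ... scoring parameters passed to [globalAlign()].
#' @return list of class `identitySummary`: `identities`, `breaks`, `counts`.
#' @seealso [fractionAbove()]
#' @export
identityDistribution <- function(seq_a, seq_b = NULL,
                                 breaks = seq(0, 100, by = 2), ...) {
  if (is.numeric(seq_a)) identities <- seq_a
  else {
    stopifnot(length(seq_a) == length(seq_b), length(seq_a) >= 1)
    identities <- vapply(seq_along(seq_a), function(i)
      percentIdentity(globalAlign(seq_a[[i]], seq_b[[i]], ...)), numeric(1))
  }
  if (length(identities) < 1) stopf("identityDistribution: no pairs")
  h <- hist(identities, breaks = breaks, plot = FALSE, right = TRUE,
            include.lowest = TRUE)
  structure(list(identities = identities, breaks = h$breaks,
                 counts = h$counts), class = "identitySummary")
}

#' @export
print.identitySummary <- function(x, ...) {
  cat("Identity distribution over", length(x$identities), "pairs\n")
  cat(sprintf("  mean %.2f%%, fraction above 98%%: %.3f\n",
              mean(x$identities), fractionAbove(x, 98)))
  invisible(x)
}

#' Fraction of pairs above an identity threshold
#'
#' Strictly greater than the threshold; non-increasing in the threshold.
#'
#' @param summary an `identitySummary` (or numeric identities).
#' @param threshold percent identity threshold.
#' @return fraction in `[0, 1]`.
#' @examples
#' fractionAbove(c(99, 99.5, 90), 98)  # 2/3
#' @export
fractionAbove <- function(summary, threshold) {
  ids <- if (is.numeric(summary)) summary else summary$identities
  mean(ids > threshold)
}

#' @importFrom graphics hist
NULL

#' Classify the phylogenetic distribution of each gene
#'
#' Categories, in decreasing precedence:
#' \describe{
#'   \item{universal}{present in every species.}
#'   \item{amniote_specific}{present in all amniotes, absent in every
#'     anamniote (species outside the `amniotes` clade).}
#'   \item{tetrapod_innovation_candidate}{present in all tetrapods, absent in
#'     every configured fish.}
#'   \item{clade_absence}{the absent set equals exactly one configured
#'     clade.}
#'   \item{single_species_absence}{absent in exactly one species.}
#'   \item{other_scattered}{anything else.}
#' }
#' Ambiguous cells count as present for categorization but are flagged.
#'
#' @param pm a [PresenceMatrix-class]; its clades must include `amniotes`,
#'   `tetrapods` and `fish`.
#' @return data.frame: `gene_id`, `category`, `resolution` (`NA` until a
#'   secondary check runs), `n_absent`, `has_ambiguous`.
#' @seealso [rescueCheck()], [resolveFishOutgroups()]
#' @export
classifyPresence <- function(pm) {
  stopifnot(is(pm, "PresenceMatrix"))
  clades <- pm@clades
  need <- c("amniotes", "tetrapods", "fish")
  miss <- setdiff(need, names(clades))
  if (length(miss))
    stopf("classifyPresence: clade config lacks %s", paste(miss, collapse = ", "))
  species <- speciesNames(pm)
  for (nm in names(clades))
    if (!all(clades[[nm]] %in% species))
      stopf("classifyPresence: clade '%s' names species not in the matrix", nm)
  pres <- pm@status != "absent"  # ambiguous treated as present, flagged
  amn <- species %in% clades$amniotes
  tet <- species %in% clades$tetrapods
  fish <- species %in% clades$fish
  category <- character(nrow(pres))
  for (i in seq_len(nrow(pres))) {
    p <- pres[i, ]
    absent <- species[!p]
    category[i] <-
      if (all(p)) "universal"
      else if (all(p[amn]) && !any(p[!amn])) "amniote_specific"
      else if (all(p[tet]) && !any(p[fish])) "tetrapod_innovation_candidate"
      else if (any(vapply(clades, function(cl) setequal(absent, cl), TRUE)))
        "clade_absence"
      else if (length(absent) == 1) "single_species_absence"
      else "other_scattered"
  }
  data.frame(gene_id = geneIds(pm), category = category,
             resolution = NA_character_,
             n_absent = rowSums(!pres),
             has_ambiguous = apply(pm@status == "ambiguous", 1, any),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Annotation-gap rescue check for single-species absences
#'
#' An apparent absence in one species may reflect an incomplete assembly
#' rather than a true loss. Presence in a closely related confirm species
#' resolves it as an `annotation_gap`; absence there supports a real loss
#' (`supported_absence`). With no confirm species configured the call stays
#' `unresolved`.
#'
#' @param calls data.frame from [classifyPresence()].
#' @param confirm_presence named logical vector: is the gene present in the
#'   confirm species? `NULL` when no confirm species is configured.
#' @return `calls` with `resolution` filled for `single_species_absence`
#'   genes.
#' @export
rescueCheck <- function(calls, confirm_presence = NULL) {
  sel <- calls$category == "single_species_absence"
  if (!any(sel)) return(calls)
  if (is.null(confirm_presence)) {
    calls$resolution[sel] <- "unresolved"
    return(calls)
  }
  pr <- confirm_presence[calls$gene_id[sel]]
  calls$resolution[sel] <- ifelse(is.na(pr), "unresolved",
                                  ifelse(pr, "annotation_gap",
                                         "supported_absence"))
  calls
}

#' Resolve tetrapod-innovation candidates against outgroup fish
#'
#' A gene present in all tetrapods but absent in the configured fish is
#' either a tetrapod innovation or a fish-lineage loss. Absence in *all*
#' outgroup fish confirms the innovation; presence in any outgroup means the
#' focal fish lost it.
#'
#' @param calls data.frame from [classifyPresence()].
#' @param outgroup_presence logical matrix (genes x outgroup species), `TRUE`
#'   where present; rows for at least the candidate genes.
#' @return `calls` with `resolution` filled for
#'   `tetrapod_innovation_candidate` genes.
#' @export
resolveFishOutgroups <- function(calls, outgroup_presence) {
  sel <- which(calls$category == "tetrapod_innovation_candidate")
  if (!length(sel)) return(calls)
  for (i in sel) {
    g <- calls$gene_id[i]
    if (!g %in% rownames(outgroup_presence)) {
      calls$resolution[i] <- "unresolved"
    } else {
      calls$resolution[i] <-
        if (any(outgroup_presence[g, ])) "lineage_loss"
        else "innovation_confirmed"
    }
  }
  calls
}
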