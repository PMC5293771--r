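## Readers/writers for the pipeline's tabular dialects. All tables are
## tab-separated with a mandatory header; '#' comment lines are ignored.
## Gene identifiers are opaque, case-sensitive strings.

# read a TSV as character columns; returns df plus the file line number of
# each data row, for precise parse errors
.readTsv <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  keep <- which(!grepl("^#", lines) & nzchar(lines))
  if (!length(keep)) stopf("%s: no header line found", path)
  split_row <- function(x) strsplit(x, "\t", fixed = TRUE)[[1]]
  header <- split_row(lines[keep[1]])
  rows <- keep[-1]
  if (!length(rows)) {
    df <- as.data.frame(setNames(replicate(length(header),
                                           character(0), simplify = FALSE),
                                 header), stringsAsFactors = FALSE)
    return(list(df = df, lineno = integer(0), path = path))
  }
  mat <- vapply(lines[rows], function(x) {
    f <- split_row(x)
    length(f) <- length(header)
    f
  }, character(length(header)))
  df <- as.data.frame(t(matrix(mat, nrow = length(header))),
                      stringsAsFactors = FALSE)
  names(df) <- header
  list(df = df, lineno = rows, path = path)
}

.requireColumns <- function(tsv, cols) {
  miss <- setdiff(cols, names(tsv$df))
  if (length(miss))
    stopf("%s: missing required column '%s'", tsv$path, miss[1])
}

.numericColumn <- function(tsv, col) {
  x <- suppressWarnings(as.numeric(tsv$df[[col]]))
  bad <- which(is.na(x) & !tsv$df[[col]] %in% c("NA", ""))
  if (length(bad))
    stopf("%s: non-numeric value '%s' in column '%s' (line %d)",
          tsv$path, tsv$df[[col]][bad[1]], col, tsv$lineno[bad[1]])
  x
}

.writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a DE summary table
#'
#' Dialect: TSV with header; required columns `gene_id`, `mean_ctrl`,
#' `mean_case`, `log2fc`, `pvalue`; optional `fdr` and `status` (added by
#' [applyDECriteria()]). Comment lines start with `#`.
#'
#' @param path file path.
#' @return data.frame with typed columns.
#' @export
readDETable <- function(path) {
  tsv <- .readTsv(path)
  .requireColumns(tsv, c("gene_id", "mean_ctrl", "mean_case", "log2fc",
                         "pvalue"))
  out <- data.frame(gene_id = tsv$df$gene_id, stringsAsFactors = FALSE)
  for (col in c("mean_ctrl", "mean_case", "log2fc", "pvalue"))
    out[[col]] <- .numericColumn(tsv, col)
  if ("fdr" %in% names(tsv$df)) out$fdr <- .numericColumn(tsv, "fdr")
  if ("status" %in% names(tsv$df)) out$status <- tsv$df$status
  out
}

#' @rdname readDETable
#' @param table data.frame to write.
#' @export
writeDETable <- function(table, path) .writeTsv(table, path)

#' Read / write an ortholog map (two-column TSV: focal_id, other_id)
#' @param path file path.
#' @return data.frame with columns `focal_id`, `other_id`.
#' @export
readOrthologMap <- function(path) {
  tsv <- .readTsv(path)
  .requireColumns(tsv, c("focal_id", "other_id"))
  tsv$df[, c("focal_id", "other_id")]
}

#' @rdname readOrthologMap
#' @param map data.frame to write.
#' @export
writeOrthologMap <- function(map, path) .writeTsv(map, path)

#' Read / write a gene-term annotation table (TSV: gene_id, term_id)
#' @param path file path.
#' @return data.frame with columns `gene_id`, `term_id`.
#' @export
readAnnotationTable <- function(path) {
  tsv <- .readTsv(path)
  .requireColumns(tsv, c("gene_id", "term_id"))
  tsv$df[, c("gene_id", "term_id")]
}

#' @rdname readAnnotationTable
#' @param annotation data.frame to write.
#' @export
writeAnnotationTable <- function(annotation, path) .writeTsv(annotation, path)

#' Read / write a weighted edge list (TSV: node_a, node_b, score)
#' @param path file path.
#' @return a [GeneNetwork-class].
#' @export
readEdgeList <- function(path) {
  tsv <- .readTsv(path)
  .requireColumns(tsv, c("node_a", "node_b", "score"))
  geneNetwork(data.frame(node_a = tsv$df$node_a, node_b = tsv$df$node_b,
                         score = .numericColumn(tsv, "score"),
                         stringsAsFactors = FALSE))
}

#' @rdname readEdgeList
#' @param network a [GeneNetwork-class] to write.
#' @export
writeEdgeList <- function(network, path) .writeTsv(network@edges, path)

#' Read / write interleaved FASTA ortholog pairs
#'
#' Pairs are stored interleaved: records 1,3,5,... are the focal sequences,
#' records 2,4,6,... their orthologs. CRLF files are tolerated.
#'
#' @param path FASTA file.
#' @return list with `seq_a`, `seq_b` ([Biostrings::DNAStringSet]s).
#' @export
readFastaPairs <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) %% 2 != 0)
    stopf("%s: interleaved pair FASTA must contain an even number of records",
          path)
  odd <- seq(1, length(x), by = 2)
  list(seq_a = x[odd], seq_b = x[odd + 1])
}

#' @rdname readFastaPairs
#' @param pairs list with `seq_a` and `seq_b` of equal length.
#' @export
writeFastaPairs <- function(pairs, path) {
  stopifnot(length(pairs$seq_a) == length(pairs$seq_b))
  n <- length(pairs$seq_a)
  all <- c(pairs$seq_a, pairs$seq_b)[rep(seq_len(n), each = 2) +
                                       rep(c(0, n), n)]
  names(all) <- paste0(rep(names(pairs$seq_a), each = 2), c("_a", "_b"))
  Biostrings::writeXStringSet(all, path)
  invisible(path)
}

#' Read / write a presence/identity matrix
#'
#' TSV with genes in rows and species in columns; cells are a percent
#' identity (present), `absent`, or `ambiguous`.
#'
#' @param path file path.
#' @param clades named clade list (required to rebuild the object).
#' @param focal focal species name (default: first column).
#' @return a [PresenceMatrix-class].
#' @export
readPresenceMatrix <- function(path, clades, focal = NULL) {
  tsv <- .readTsv(path)
  .requireColumns(tsv, "gene_id")
  species <- setdiff(names(tsv$df), "gene_id")
  if (is.null(focal)) focal <- species[1]
  cells <- as.matrix(tsv$df[, species, drop = FALSE])
  rownames(cells) <- tsv$df$gene_id
  status <- ifelse(cells == "absent", "absent",
                   ifelse(cells == "ambiguous", "ambiguous", "present"))
  identity <- suppressWarnings(
    matrix(as.numeric(cells), nrow(cells), ncol(cells),
           dimnames = dimnames(cells)))
  bad <- which(status == "present" & is.na(identity), arr.ind = TRUE)
  if (nrow(bad))
    stopf("%s: cell '%s' is neither numeric nor absent/ambiguous (line %d)",
          path, cells[bad[1, 1], bad[1, 2]], tsv$lineno[bad[1, 1]])
  presenceMatrix(status, identity, clades, focal)
}

#' @rdname readPresenceMatrix
#' @param pm a [PresenceMatrix-class] to write.
#' @export
writePresenceMatrix <- function(pm, path) {
  cells <- ifelse(pm@status == "present",
                  formatC(pm@identity, format = "g", digits = 15),
                  pm@status)
  df <- data.frame(gene_id = geneIds(pm), cells, stringsAsFactors = FALSE,
                   check.names = FALSE)
  .writeTsv(df, path)
}
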