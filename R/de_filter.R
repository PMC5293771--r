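## Triple-criterion differential-expression filter: FDR, fold change, read
## floor.

#' Benjamini-Hochberg false-discovery-rate correction
#'
#' Step-up adjustment with monotone enforcement, returned in the input order.
#' Thin validated front-end over [stats::p.adjust()] so every stage corrects
#' p-values the same way.
#'
#' @param pvalues numeric vector of probabilities in `[0, 1]`, length >= 1.
#' @return adjusted probabilities, same length and order.
#' @examples
#' benjaminiHochberg(c(0.01, 0.02, 0.03, 0.04))
#' @export
benjaminiHochberg <- function(pvalues) {
  if (length(pvalues) == 0) stopf("benjaminiHochberg: empty p-value vector")
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stopf("benjaminiHochberg: p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH")
}

# shared vectorized status rule
.deStatus <- function(log2fc, fdr, mean_ctrl, mean_case, criteria) {
  reads <- switch(criteria@read_basis,
                  max = pmax(mean_ctrl, mean_case),
                  sum = mean_ctrl + mean_case)
  lf <- log2(criteria@min_fold)
  ok <- fdr < criteria@fdr_max & reads >= criteria@min_reads
  ifelse(ok & log2fc >= lf, "up",
         ifelse(ok & log2fc <= -lf, "down", "not_de"))
}

#' Call DE status for a single record
#'
#' A gene is `up` iff its FDR is strictly below the threshold, its log2 fold
#' change is at least `log2(min_fold)`, and the read floor is met in at least
#' one condition; `down` symmetrically; `not_de` otherwise.
#'
#' @param record list or one-row data.frame with `log2fc`, `fdr`,
#'   `mean_ctrl`, `mean_case`.
#' @param criteria a [DECriteria-class] object.
#' @return one of `"up"`, `"down"`, `"not_de"`.
#' @examples
#' callDEStatus(list(fdr = 0.05, log2fc = 1.5, mean_ctrl = 10,
#'                   mean_case = 200), deCriteria())
#' @export
callDEStatus <- function(record, criteria = deCriteria()) {
  validObject(criteria)
  record <- as.list(record)
  need <- c("log2fc", "fdr", "mean_ctrl", "mean_case")
  miss <- setdiff(need, names(record))
  if (length(miss)) stopf("callDEStatus: missing field(s) %s",
                          paste(miss, collapse = ", "))
  if (is.na(record$fdr)) stopf("callDEStatus: fdr not populated")
  .deStatus(record$log2fc, record$fdr, record$mean_ctrl, record$mean_case,
            criteria)
}

#' Apply the DE criteria to a whole table
#'
#' Computes BH FDR over exactly the genes present in the table (the supplied
#' table defines the testing universe), then assigns a status per record.
#'
#' @param table data.frame with columns `gene_id`, `mean_ctrl`, `mean_case`,
#'   `log2fc`, `pvalue`.
#' @param criteria a [DECriteria-class] object.
#' @return the table with `fdr` and `status` columns added/overwritten.
#' @examples
#' sim <- genDETables(simConfig(n_genes = 200, seed = 1))
#' called <- applyDECriteria(sim$tables$focal)
#' table(called$status)
#' @export
applyDECriteria <- function(table, criteria = deCriteria()) {
  validObject(criteria)
  need <- c("gene_id", "mean_ctrl", "mean_case", "log2fc", "pvalue")
  miss <- setdiff(need, names(table))
  if (length(miss)) stopf("applyDECriteria: missing column(s) %s",
                          paste(miss, collapse = ", "))
  if (nrow(table) == 0) {
    table$fdr <- numeric(0); table$status <- character(0)
    return(table)
  }
  table$fdr <- benjaminiHochberg(table$pvalue)
  table$status <- .deStatus(table$log2fc, table$fdr, table$mean_ctrl,
                            table$mean_case, criteria)
  table
}

#' Summarize DE calls
#'
#' @param table data.frame with a `status` column.
#' @return data.frame with one row: `n_de`, `n_up`, `n_down`.
#' @examples
#' summarizeDE(data.frame(status = c("up", "up", "down", "not_de")))
#' @export
summarizeDE <- function(table) {
  if (!"status" %in% names(table))
    stopf("summarizeDE: statuses not assigned (no status column)")
  n_up <- sum(table$status == "up")
  n_down <- sum(table$status == "down")
  data.frame(n_de = n_up + n_down, n_up = n_up, n_down = n_down)
}
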