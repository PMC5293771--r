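test_that("timepoint classification follows the band and direction rules", {
  expect_equal(classifyAtTimepoint("up", "not_de", 0.1), "differing")
  expect_equal(classifyAtTimepoint("up", "up", 2.0), "coincident")
  expect_equal(classifyAtTimepoint("up", "down", -1.5), "differing")
  expect_equal(classifyAtTimepoint("up", "not_de", 0.8), "indeterminate")
  expect_error(classifyAtTimepoint("not_de", "up", 1), "up.*down")
})

test_that("classification equals the brute-force oracle over the full grid", {
  fcs <- c(0, 0.2, 0.39, 0.41, 1, 2)
  fcs <- sort(unique(c(fcs, -fcs)))
  for (focal in c("up", "down"))
    for (other in c("up", "down", "not_de"))
      for (fc in fcs) {
        got <- classifyAtTimepoint(focal, other, fc)
        expect_identical(got, tpOracle(focal, other, fc),
                         label = sprintf("%s/%s/%g", focal, other, fc))
        for (other2 in c("up", "down", "not_de"))
          for (fc2 in fcs) {
            g2 <- classifyAtTimepoint(focal, other2, fc2)
            expect_identical(classifyGene(got, g2),
                             consensusOracle(tpOracle(focal, other, fc),
                                             tpOracle(focal, other2, fc2)))
          }
      }
})

test_that("consensus combinations partition into the three classes", {
  expect_equal(classifyGene("differing", "differing"), "departing")
  expect_equal(classifyGene("coincident", "differing"), "ambiguous")
  expect_equal(classifyGene("indeterminate", "indeterminate"), "ambiguous")
  lv <- c("differing", "coincident", "indeterminate")
  combos <- expand.grid(a = lv, b = lv, stringsAsFactors = FALSE)
  cons <- classifyGene(combos$a, combos$b)
  expect_true(all(cons %in% c("departing", "coincident", "ambiguous")))
  expect_equal(sum(cons == "departing"), 1)
  expect_equal(sum(cons == "coincident"), 1)
  expect_equal(sum(cons == "ambiguous"), 7)
})

test_that("band monotonicity: widening never turns differing into coincident", {
  set.seed(31)
  for (i in 1:200) {
    focal <- sample(c("up", "down"), 1)
    other <- sample(c("up", "down", "not_de"), 1)
    fc <- runif(1, -3, 3)
    narrow <- classifyAtTimepoint(focal, other, fc, band_halfwidth = 0.4)
    wide <- classifyAtTimepoint(focal, other, fc, band_halfwidth = 1.2)
    if (narrow == "differing") expect_equal(wide, "differing")
    if (narrow == "indeterminate")
      expect_true(wide %in% c("differing", "indeterminate"))
  }
})

.mkComparison <- function(consensus_by_gene, focal = NULL) {
  # build a comparison fixture realizing the requested consensus per gene
  genes <- names(consensus_by_gene)
  if (is.null(focal)) focal <- setNames(rep("up", length(genes)), genes)
  tp <- function(kind, sgn) switch(kind,
    differing = list(status = "not_de", fc = 0.1),
    coincident = list(status = if (sgn > 0) "up" else "down", fc = sgn * 2),
    indeterminate = list(status = "not_de", fc = 0.9))
  t1 <- t2 <- data.frame(gene_id = paste0("o_", genes), log2fc = 0,
                         status = "not_de", stringsAsFactors = FALSE)
  for (i in seq_along(genes)) {
    kinds <- switch(consensus_by_gene[i],
                    departing = c("differing", "differing"),
                    coincident = c("coincident", "coincident"),
                    ambiguous = c("coincident", "differing"))
    sgn <- if (focal[[genes[i]]] == "up") 1 else -1
    a <- tp(kinds[1], sgn); b <- tp(kinds[2], sgn)
    t1$status[i] <- a$status; t1$log2fc[i] <- a$fc
    t2$status[i] <- b$status; t2$log2fc[i] <- b$fc
  }
  list(tables = list(t1, t2),
       map = data.frame(focal_id = genes, other_id = paste0("o_", genes)))
}

test_that("comparison summaries match hand counts and handle edge cases", {
  genes <- sprintf("g%02d", 1:10)
  plan <- setNames(rep(c("departing", "coincident", "ambiguous"),
                       c(4, 3, 3)), genes)
  fx <- .mkComparison(plan)
  calls <- classifyComparison(setNames(rep("up", 10), genes), fx$tables,
                              fx$map)
  s <- summarizeComparison(calls)
  expect_equal(s$pct_departing_both, 40)
  expect_equal(s$pct_coincident_both, 30)
  expect_equal(s$pct_ambiguous, 30)
  expect_equal(s$pct_departing_both + s$pct_coincident_both +
                 s$pct_ambiguous, 100, tolerance = 1e-9)
  # all double-coincident
  fx2 <- .mkComparison(setNames(rep("coincident", 5), genes[1:5]))
  s2 <- summarizeComparison(classifyComparison(
    setNames(rep("up", 5), genes[1:5]), fx2$tables, fx2$map))
  expect_equal(unlist(s2[c("pct_differing_t1", "pct_differing_t2",
                           "pct_departing_both", "pct_ambiguous")],
                      use.names = FALSE), c(0, 0, 0, 0))
  expect_equal(s2$pct_coincident_both, 100)
  # zero comparable genes: explicit empty summary, not a division error
  s0 <- summarizeComparison(classifyComparison(
    c(gX = "up"), fx$tables, data.frame(focal_id = character(),
                                        other_id = character())))
  expect_equal(s0$n_comparable, 0)
  expect_true(is.na(s0$pct_departing_both))
})

test_that("genes without an ortholog or record are non-comparable", {
  genes <- c("g1", "g2", "g3")
  fx <- .mkComparison(setNames(rep("coincident", 3), genes))
  map <- fx$map[1:2, ]                       # g3 has no ortholog
  tables <- fx$tables
  tables[[2]] <- tables[[2]][-2, ]           # g2 missing at timepoint 2
  calls <- classifyComparison(setNames(rep("up", 3), genes), tables, map)
  expect_equal(calls$comparable, c(TRUE, FALSE, FALSE))
  expect_true(all(is.na(calls$consensus[!calls$comparable])))
})

test_that("double-behavior overlay combines the two comparisons", {
  genes <- sprintf("g%02d", 1:6)
  planA <- setNames(c("departing", "departing", "coincident", "coincident",
                      "ambiguous", "departing"), genes)
  planB <- setNames(c("departing", "coincident", "coincident", "departing",
                      "departing", "ambiguous"), genes)
  focal <- setNames(c("up", "down", "up", "up", "up", "down"), genes)
  fxA <- .mkComparison(planA, focal); fxB <- .mkComparison(planB, focal)
  callsA <- classifyComparison(focal, fxA$tables, fxA$map)
  callsB <- classifyComparison(focal, fxB$tables, fxB$map)
  ov <- doubleBehaviorOverlay(callsA, callsB, focal)
  expect_equal(unname(ov[genes]),
               c("double_departing_up", "excluded", "double_coincident_up",
                 "excluded", "excluded", "excluded"))
  # gene present in only one comparison is excluded (and logged)
  callsA2 <- callsA[callsA$gene_id != "g01", ]
  expect_message(ov2 <- doubleBehaviorOverlay(callsA2, callsB, focal),
                 "excluded")
  expect_equal(unname(ov2["g01"]), "excluded")
})
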