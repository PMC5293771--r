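test_that("global alignment handles identity, gaps and validation", {
  al <- globalAlign("ACGT", "ACGT")
  expect_equal(al$score, 4)
  expect_equal(al$aligned_a, al$aligned_b)
  al2 <- globalAlign("ACGT", "AGT")
  expect_equal(al2$score, 1)  # A C G T / A - G T: 1 - 2 + 1 + 1
  expect_equal(al2$aligned_a, "ACGT")
  expect_equal(al2$aligned_b, "A-GT")
  expect_error(globalAlign("", "ACGT"), "non-empty")
  expect_error(globalAlign("ACGT", "ACXT"), "alphabet")
})

test_that("alignment scores equal exhaustive dynamic-programming oracle", {
  seqs <- allSeqs(1:4)                       # every pair of lengths <= 4
  for (a in seqs)
    for (b in seqs)
      expect_equal(globalAlign(a, b)$score, nwOracleScore(a, b),
                   label = paste(a, b))
  # symmetry, and spot-checks on longer random sequences
  set.seed(5)
  for (i in 1:25) {
    a <- paste(sample(c("A", "C", "G", "T"), sample(3:12, 1), TRUE),
               collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), sample(3:12, 1), TRUE),
               collapse = "")
    expect_equal(globalAlign(a, b)$score, nwOracleScore(a, b))
    expect_equal(globalAlign(a, b)$score, globalAlign(b, a)$score)
  }
})

test_that("alignment score agrees with Biostrings on random pairs", {
  set.seed(8)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  for (i in 1:10) {
    a <- paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), 28, TRUE), collapse = "")
    ref <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                         substitutionMatrix = mat,
                                         gapOpening = 0, gapExtension = 2)
    expect_equal(globalAlign(a, b)$score, Biostrings::score(ref))
  }
})

test_that("percent identity excludes terminal gaps", {
  expect_equal(percentIdentity(globalAlign(strrep("ACGT", 25),
                                           strrep("ACGT", 25))), 100)
  expect_equal(percentIdentity(globalAlign("ACGT", "ACGA")), 75)
  # internal gap counts against identity, terminal overhang does not
  al <- globalAlign("ACGTACGT", "ACGTAC")    # 2-base terminal overhang
  expect_equal(percentIdentity(al), 100)
})

test_that("identity distributions summarize planted pairs", {
  p <- genSequencePairs(500, 1000, identity = 98, seed = 12)
  d <- identityDistribution(p$seq_a, p$seq_b)
  expect_lt(abs(mean(d$identities) - 98), 0.2)
  expect_equal(sum(d$counts), 500)
  # fraction above is monotone non-increasing in the threshold
  th <- seq(0, 100, by = 5)
  fr <- vapply(th, function(t) fractionAbove(d, t), numeric(1))
  expect_true(all(diff(fr) <= 0))
  expect_equal(fractionAbove(d, 0), 1.0)
  # planted construction: 9 pairs >= 99%, one at 90%
  d2 <- identityDistribution(c(rep(99.5, 9), 90))
  expect_equal(fractionAbove(d2, 98), 0.9)
  ident <- identityDistribution(genSequencePairs(5, 200, 100, seed = 1)$seq_a,
                                genSequencePairs(5, 200, 100, seed = 1)$seq_b)
  expect_equal(fractionAbove(ident, 98), 1.0)
})

test_that("presence classification equals the truth-table oracle over 2^9 vectors", {
  species <- paste0("s", 1:9)
  combos <- as.matrix(expand.grid(replicate(9, c(TRUE, FALSE),
                                            simplify = FALSE)))
  colnames(combos) <- species
  rownames(combos) <- sprintf("g%03d", seq_len(nrow(combos)))
  pm <- presenceMatrixFromVectors(combos)
  calls <- classifyPresence(pm)
  expected <- apply(combos, 1, function(r) presenceOracle(setNames(r, species)))
  expect_identical(setNames(calls$category, calls$gene_id), expected)
})

test_that("named fixture cases classify as in the study design", {
  sp <- defaultSpeciesPanel()
  mk <- function(absent) {
    status <- matrix("present", 1, length(sp),
                     dimnames = list("g1", sp))
    status[1, absent] <- "absent"
    identity <- ifelse(status == "present", 95, NA_real_)
    identity[, "T_scripta"] <- 100
    presenceMatrix(status, identity, defaultClades(), "T_scripta")
  }
  expect_equal(classifyPresence(mk(character()))$category, "universal")
  expect_equal(classifyPresence(mk("P_sinensis"))$category,
               "single_species_absence")
  expect_equal(classifyPresence(mk("D_rerio"))$category,
               "tetrapod_innovation_candidate")
  expect_equal(classifyPresence(mk(c("X_tropicalis", "D_rerio")))$category,
               "amniote_specific")
  expect_equal(classifyPresence(mk(c("human", "mouse", "opossum")))$category,
               "clade_absence")
})

test_that("rescue check resolves single-species absences", {
  calls <- data.frame(gene_id = c("gA", "gB", "gC"),
                      category = rep("single_species_absence", 3),
                      resolution = NA_character_, stringsAsFactors = FALSE)
  # present in the confirm species: an annotation gap, not a real loss
  res <- rescueCheck(calls, c(gA = TRUE, gB = FALSE))
  expect_equal(res$resolution, c("annotation_gap", "supported_absence",
                                 "unresolved"))
  # no confirm species configured
  res0 <- rescueCheck(calls, NULL)
  expect_true(all(res0$resolution == "unresolved"))
})

test_that("fish outgroups separate innovations from lineage losses", {
  calls <- data.frame(gene_id = c("gA", "gB", "gC"),
                      category = rep("tetrapod_innovation_candidate", 3),
                      resolution = NA_character_, stringsAsFactors = FALSE)
  outg <- rbind(gA = c(fugu = FALSE, medaka = FALSE),
                gB = c(fugu = TRUE, medaka = FALSE),
                gC = c(fugu = FALSE, medaka = TRUE))
  res <- resolveFishOutgroups(calls, outg)
  expect_equal(res$resolution,
               c("innovation_confirmed", "lineage_loss", "lineage_loss"))
})
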