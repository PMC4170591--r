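test_that("compositional surface forms standardize to the expected triples", {
  cases <- tibble::tribble(
    ~text, ~level, ~wild, ~mutant, ~position, ~locality,
    "the c.758C>T variant", "nucleotide", "C", "T", 758L, "local",
    "the Arg 117 His substitution", "protein", "R", "H", 117L, "local",
    "carriers of R117H", "protein", "R", "H", 117L, "local",
    "the p.G12D allele", "protein", "G", "D", 12L, "local",
    "a T to C at position 59 change", "nucleotide", "T", "C", 59L, "local",
    "the Lys303Arg substitution", "protein", "K", "R", 303L, "local",
    "a 758C>T substitution", "nucleotide", "C", "T", 758L, "local",
    "the c.35G>A change", "nucleotide", "G", "A", 35L, "local"
  )
  for (i in seq_len(nrow(cases))) {
    std <- standardize_matches(match_patterns(cases$text[i]), cases$text[i])
    expect_equal(nrow(std$concepts), 1L, info = cases$text[i])
    expect_equal(
      std$concepts[, c("level", "wild", "mutant", "position", "locality")],
      cases[i, c("level", "wild", "mutant", "position", "locality")],
      info = cases$text[i]
    )
  }
})

test_that("texts without mutation expressions yield nothing", {
  expect_equal(nrow(match_patterns("the cat sat on the mat")), 0L)
  expect_equal(nrow(match_patterns("")), 0L)
})

test_that("independent surface scan agrees on multi-mention text", {
  # hand scan: exactly two compositional expressions, no others
  txt <- "R117H and c.758C>T were both seen"
  m <- match_patterns(txt)
  expect_equal(nrow(m), 2L)
  expect_setequal(m$surface, c("c.758C>T", "R117H"))
})

test_that("wild/mutant pairs without in-pattern position use the window search", {
  txt <- "T to C at position 59 resulting in substitution of Pro for Ser"
  std <- standardize_matches(match_patterns(txt), txt)
  cc <- std$concepts[order(std$concepts$level), ]
  expect_equal(nrow(cc), 2L)
  # the compositional nucleotide triple is local
  expect_equal(cc$level[1], "nucleotide")
  expect_equal(unlist(cc[1, c("wild", "mutant")], use.names = FALSE), c("T", "C"))
  expect_equal(cc$position[1], 59L)
  expect_equal(cc$locality[1], "local")
  # the protein pair takes the nearest integer from the window: wrong level,
  # faithfully reproduced
  expect_equal(cc$level[2], "protein")
  expect_equal(unlist(cc[2, c("wild", "mutant")], use.names = FALSE), c("S", "P"))
  expect_equal(cc$position[2], 59L)
  expect_equal(cc$locality[2], "nonlocal")
})

test_that("pairs with no integer in the window are rejected with a reason", {
  txt <- "this allele causes a substitution of Pro for Ser in the protein"
  std <- standardize_matches(match_patterns(txt), txt)
  expect_equal(nrow(std$concepts), 0L)
  expect_equal(nrow(std$rejected), 1L)
  expect_match(std$rejected$reason, "no position")
})

test_that("rs identifiers become dbSNP mentions, never triples", {
  txt <- "genotyped rs35490896 in all samples"
  std <- standardize_matches(match_patterns(txt), txt)
  expect_equal(std$dbsnp$rs_id, "rs35490896")
  expect_equal(nrow(std$concepts), 0L)
})

test_that("contradictory captures (wild equals mutant) are rejected", {
  txt <- "an unusual T to T at position 5 artifact"
  std <- standardize_matches(match_patterns(txt), txt)
  expect_equal(nrow(std$concepts), 0L)
  expect_match(std$rejected$reason, "wild type equals mutant")
})

test_that("the stop-list vetoes overlapping matches and logs the pattern id", {
  txt <- "experiments in T47D cells showed the R175H effect"
  m <- match_patterns(txt)
  expect_true("T47D" %in% m$surface) # raw pattern fires
  kept <- apply_stoplist(m, txt)
  expect_false("T47D" %in% kept$surface)
  expect_true("R175H" %in% kept$surface)
  expect_equal(attr(kept, "dropped")$stop_id, "cell_line_known")
  # empty stop-list is the identity
  empty <- mutation_stoplist()[0, ]
  expect_equal(nrow(apply_stoplist(m, txt, empty)), nrow(m))
  # a stop hit elsewhere in the text removes nothing
  txt2 <- "the R175H variant; cultures used T47D cells"
  kept2 <- apply_stoplist(match_patterns(txt2), txt2)
  expect_true("R175H" %in% kept2$surface)
})

test_that("the coding filter removes negative positions and noncoding contexts", {
  txt <- "We saw c.-34C>T here. In intron 4 a G to A at position 99 occurred. The R175H change is coding."
  std <- standardize_matches(match_patterns(txt), txt)
  kept <- filter_coding(std$concepts, txt)
  expect_equal(kept$surface, "R175H")
  d <- attr(kept, "dropped")
  expect_setequal(d$reason, c("negative position", "noncoding context"))
})

test_that("mentions of one standardized triple group into one concept", {
  txt <- "The R117H variant, also written Arg117His, was frequent"
  std <- standardize_matches(match_patterns(txt), txt)
  g <- group_mutation_mentions(std$concepts)
  expect_equal(nrow(g), 1L)
  expect_equal(nrow(g$mentions[[1]]), 2L)
  expect_equal(g$mentions[[1]]$surface, c("R117H", "Arg117His"))
  # same letters at a different level never merge
  txt2 <- "both c.12A>C and p.A12C were reported"
  g2 <- group_mutation_mentions(standardize_matches(match_patterns(txt2), txt2)$concepts)
  expect_equal(nrow(g2), 2L)
  expect_setequal(g2$level, c("nucleotide", "protein"))
})

test_that("extraction is idempotent and mentions satisfy the slice invariant", {
  corpus <- synth_mutation_corpus(n = 40, seed = 3)
  r1 <- extract_mutations(corpus)
  r2 <- extract_mutations(corpus)
  expect_equal(r1, r2)
  so <- mutations_to_standoff(r1$concepts)
  expect_silent(validate_standoff(so, corpus))
})

test_that("locality is sound: local positions inside the span, nonlocal outside", {
  corpus <- synth_mutation_corpus(n = 60, seed = 9)
  res <- extract_mutations(corpus)
  for (i in seq_len(nrow(res$concepts))) {
    cc <- res$concepts[i, ]
    m <- cc$mentions[[1]][1, ]
    inside <- grepl(as.character(cc$position), m$surface, fixed = TRUE)
    if (cc$locality == "local") {
      expect_true(inside, info = m$surface)
    } else {
      expect_false(inside, info = m$surface)
    }
  }
})

test_that("disabling the stop-list and coding filter never loses concepts", {
  ab <- demo_abstracts()
  full <- extract_mutations(ab)
  no_filter <- extract_mutations(ab, stoplist = mutation_stoplist()[0, ],
                                 coding_filter = FALSE)
  expect_gte(nrow(no_filter$concepts), nrow(full$concepts))
  # every filtered concept is present in the unfiltered set
  expect_equal(
    nrow(dplyr::semi_join(full$concepts, no_filter$concepts,
                          by = c("pmid", "concept_key"))),
    nrow(full$concepts)
  )
})

test_that("template sentences with planted triples are recovered exactly", {
  corpus <- synth_mutation_corpus(n = 60, seed = 21)
  res <- extract_mutations(corpus)
  got <- res$concepts[, c("pmid", "level", "wild", "mutant", "position")]
  planted <- corpus[, c("pmid", "level", "wild", "mutant", "position")]
  hit <- dplyr::semi_join(planted, got,
                          by = c("pmid", "level", "wild", "mutant", "position"))
  expect_gte(nrow(hit) / nrow(planted), 0.95)
  # nothing extracted beyond the planted triples
  stray <- dplyr::anti_join(got, planted,
                            by = c("pmid", "level", "wild", "mutant", "position"))
  expect_equal(nrow(stray), 0L)
})

test_that("stop-codon substitutions are recognized only with the opt-in registry", {
  txt <- "the nonsense change R117X truncates the protein"
  expect_equal(nrow(match_patterns(txt)), 0L)
  reg <- mutation_patterns(include_stop = TRUE)
  m <- match_patterns(txt, reg)
  expect_equal(m$surface, "R117X")
  std <- standardize_matches(m, txt)
  expect_equal(std$concepts$mutant, "*")
})
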