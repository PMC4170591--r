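test_that("entity scores follow the count definitions, including degenerate cases", {
  e <- entity_score("genes", n_gold = 10, n_candidates = 25, n_correct = 9)
  expect_equal(e$precision, 9 / 25)
  expect_equal(e$recall, 0.9)
  empty <- entity_score("mutations", n_gold = 10, n_candidates = 0, n_correct = 0)
  expect_true(is.na(empty$precision))
  expect_equal(empty$recall, 0)
  expect_error(entity_score("x", 5, 5, 6))
})

test_that("entity scoring of the demo corpus matches hand-enumerated counts", {
  ab <- demo_abstracts()
  gold <- demo_gold()
  mut <- extract_mutations(ab)
  genes <- extract_genes(ab, demo_lexicon())
  cand <- build_candidates(genes, mut$concepts)
  sc <- score_entities(genes, mut$concepts, gold, candidates = cand)
  # hand enumeration over the fixture: 6 gold gene concepts, 6 tagged
  # (catalase is a true tag but not in gold), the nonhuman gene is missed
  g <- sc[sc$entity_class == "genes", ]
  expect_equal(unlist(g[, c("n_gold", "n_candidates", "n_correct")],
                      use.names = FALSE), c(6L, 6L, 5L))
  # 9 gold mutations; the noncoding and nonhuman ones are not extracted
  m <- sc[sc$entity_class == "mutations", ]
  expect_equal(unlist(m[, c("n_gold", "n_candidates", "n_correct")],
                      use.names = FALSE), c(9L, 7L, 7L))
  p <- sc[sc$entity_class == "gene-mutation pairs", ]
  expect_equal(unlist(p[, c("n_gold", "n_candidates", "n_correct")],
                      use.names = FALSE), c(9L, 9L, 7L))
})

test_that("relation scorecards reconcile their margins and ratio definitions", {
  sc <- relation_scorecard(tp = 30, fp = 10, fn_judged = 5, tn = 55,
                           n_gold_total = 50)
  expect_equal(sc$n_judged, 100)
  expect_equal(sc$precision, 0.75)
  expect_equal(sc$accuracy, 0.85)
  expect_equal(sc$hit_recall, 30 / 35)
  expect_equal(sc$e2e_recall, 0.6)
  expect_lte(sc$e2e_recall, sc$hit_recall)
  expect_error(relation_scorecard(30, 10, 25, 55, n_gold_total = 50))
})

test_that("relation scoring classifies decisions by gold membership", {
  fx <- random_relation_fixture(1)
  sc <- score_relations(fx$decisions, fx$candidates, fx$gold)
  # brute-force reclassification
  key <- c("pmid", "entrez_id", "level", "wild", "mutant", "position")
  in_gold <- vapply(seq_len(nrow(fx$candidates)), function(i) {
    nrow(dplyr::semi_join(fx$candidates[i, key], fx$gold[, key], by = key)) > 0
  }, TRUE)
  lab <- fx$decisions$label[match(fx$candidates$item_id, fx$decisions$item_id)]
  expect_equal(sc$tp, sum(lab == "YES" & in_gold))
  expect_equal(sc$fp, sum(lab == "YES" & !in_gold))
  expect_equal(sc$fn_judged, sum(lab == "NO" & in_gold))
  expect_equal(sc$tn, sum(lab == "NO" & !in_gold))
  expect_equal(sc$tp + sc$fp + sc$fn_judged + sc$tn, nrow(fx$candidates))
  expect_error(
    score_relations(tibble::tibble(item_id = "missing", label = "YES"),
                    fx$candidates, fx$gold),
    "without matching candidate"
  )
})

test_that("dropping nonlocal items never increases end-to-end recall", {
  for (s in 1:25) {
    fx <- random_relation_fixture(s)
    all_sc <- score_relations(fx$decisions, fx$candidates, fx$gold)
    loc_sc <- score_relations(fx$decisions, fx$candidates, fx$gold,
                              drop_nonlocal = TRUE)
    expect_lte(loc_sc$tp, all_sc$tp)
    expect_lte(loc_sc$e2e_recall, all_sc$e2e_recall)
    expect_equal(loc_sc$n_gold_total, all_sc$n_gold_total)
  }
})

test_that("pairwise agreement and kappa behave at the reference points", {
  # perfect agreement with varied labels
  j <- dplyr::bind_rows(
    judgments_of("a", sprintf("i%d", 1:10), rep(c("YES", "NO"), 5)),
    judgments_of("b", sprintf("i%d", 1:10), rep(c("YES", "NO"), 5))
  )
  r <- pairwise_agreement(j)
  expect_equal(r$raw_agreement, 1)
  expect_equal(r$kappa, 1)
  # independent random responses: kappa near zero
  withr::with_seed(12, {
    jr <- dplyr::bind_rows(
      judgments_of("a", sprintf("i%d", 1:2000),
                   sample(c("YES", "NO"), 2000, TRUE)),
      judgments_of("b", sprintf("i%d", 1:2000),
                   sample(c("YES", "NO"), 2000, TRUE))
    )
  })
  expect_lt(abs(pairwise_agreement(jr)$kappa), 0.06)
  # both raters constant and identical: undefined
  jc <- dplyr::bind_rows(
    judgments_of("a", sprintf("i%d", 1:5), rep("YES", 5)),
    judgments_of("b", sprintf("i%d", 1:5), rep("YES", 5))
  )
  rc <- pairwise_agreement(jc)
  expect_true(is.na(rc$kappa))
  expect_match(rc$note, "undefined")
  # min_items excludes thin pairs
  expect_equal(nrow(pairwise_agreement(jc, min_items = 6)), 0L)
})

test_that("kappa on a printed toy table matches the hand computation", {
  # shared responses: a/b agree on 6 YES and 2 NO, disagree on 2
  resp_a <- c(rep("YES", 7), rep("NO", 3))
  resp_b <- c(rep("YES", 6), "NO", "YES", rep("NO", 2))
  j <- dplyr::bind_rows(
    judgments_of("a", sprintf("i%d", 1:10), resp_a),
    judgments_of("b", sprintf("i%d", 1:10), resp_b)
  )
  po <- 8 / 10
  pe <- (0.7 * 0.7) + (0.3 * 0.3)
  expect_equal(pairwise_agreement(j)$kappa, (po - pe) / (1 - pe))
})

test_that("kappa agrees with brute force on random contingency tables", {
  withr::with_seed(77, {
    for (case in 1:100) {
      tab <- matrix(sample(0:8, 9, replace = TRUE), 3)
      if (sum(tab) < 2) next
      cats <- c("YES", "NO", "INCONSISTENT")
      ra <- rep(rep(cats, 3), as.vector(t(tab)))
      rb <- rep(rep(cats, each = 3), as.vector(t(tab)))
      ids <- sprintf("i%03d", seq_along(ra))
      j <- dplyr::bind_rows(judgments_of("a", ids, ra), judgments_of("b", ids, rb))
      got <- pairwise_agreement(j)$kappa
      want <- kappa_brute(t(tab))
      if (is.na(want) || !is.finite(want)) {
        expect_true(is.na(got))
      } else {
        expect_equal(got, want, tolerance = 1e-12)
      }
    }
  })
})

test_that("kappa agrees with an established implementation", {
  skip_if_not_installed("e1071")
  withr::with_seed(31, {
    for (case in 1:25) {
      tab <- matrix(sample(1:9, 4, replace = TRUE), 2)
      ra <- rep(rep(c("YES", "NO"), 2), as.vector(t(tab)))
      rb <- rep(rep(c("YES", "NO"), each = 2), as.vector(t(tab)))
      ids <- sprintf("i%03d", seq_along(ra))
      j <- dplyr::bind_rows(judgments_of("a", ids, ra), judgments_of("b", ids, rb))
      expect_equal(pairwise_agreement(j)$kappa,
                   e1071::classAgreement(t(tab))$kappa, tolerance = 1e-12)
    }
  })
})

test_that("unanimous expert surface labels override gold; split panels do not", {
  fx <- random_relation_fixture(3)
  base <- surface_rescore(fx$decisions, fx$candidates, fx$gold,
                          expert_labels = NULL)
  base2 <- score_relations(fx$decisions, fx$candidates, fx$gold)
  expect_equal(scorecard_to_tibble(base), scorecard_to_tibble(base2))
  # pick a false positive and flip it with a unanimous YES panel
  key <- c("pmid", "entrez_id", "level", "wild", "mutant", "position")
  in_gold <- vapply(seq_len(nrow(fx$candidates)), function(i) {
    nrow(dplyr::semi_join(fx$candidates[i, key], fx$gold[, key], by = key)) > 0
  }, TRUE)
  lab <- fx$decisions$label[match(fx$candidates$item_id, fx$decisions$item_id)]
  fp_item <- fx$candidates$item_id[lab == "YES" & !in_gold][1]
  panel <- tibble::tibble(item_id = fp_item, annotator = c("A", "B", "C"),
                          label = "YES")
  up <- surface_rescore(fx$decisions, fx$candidates, fx$gold, panel)
  expect_equal(up$tp, base$tp + 1)
  expect_equal(up$fp, base$fp - 1)
  expect_gt(up$precision, base$precision)
  # 2-of-3 agreement: no override
  split <- tibble::tibble(item_id = fp_item, annotator = c("A", "B", "C"),
                          label = c("YES", "YES", "NO"))
  same <- surface_rescore(fx$decisions, fx$candidates, fx$gold, split)
  expect_equal(scorecard_to_tibble(same), scorecard_to_tibble(base))
})

test_that("the cost-accuracy table covers every scenario and prices the dynamic row lower", {
  crowd <- test_crowd(seed = 44, n_items = 120, n_workers = 10,
                      sens = c(runif(8, 0.7, 0.95), 0.3, 0.35),
                      spec = c(runif(8, 0.7, 0.95), 0.35, 0.3))
  # score against a gold table derived from the ledger so relation scoring runs
  cand <- tibble::tibble(
    item_id = crowd$items$item_id,
    pmid = "p1", entrez_id = "672", level = "protein", wild = "R", mutant = "H",
    position = seq_len(nrow(crowd$items)), locality = "local",
    is_control = FALSE, control_truth = NA_character_
  )
  gold <- cand[crowd$items$truth == "YES",
               c("pmid", "entrez_id", "level", "wild", "mutant", "position")]
  gold$flags <- list(character(0))
  scen <- tibble::tibble(
    name = c("n5", "n4", "n3", "n2", "n1", "dynamic"),
    n_turkers = c(5L, 4L, 3L, 2L, 1L, NA),
    fire_below = c(NA, NA, NA, NA, NA, 0.5)
  )
  curve <- cost_accuracy_curve(crowd$judgments, cand, gold, scen,
                               n_abstracts = 30)
  expect_equal(nrow(curve), 6L)
  expect_true(all(is.finite(curve$accuracy)))
  dyn <- curve[curve$name == "dynamic", ]
  n5 <- curve[curve$name == "n5", ]
  expect_gt(dyn$n_fired, 0)
  expect_lt(dyn$total_cost, n5$total_cost)
  expect_lt(curve$total_cost[curve$name == "n1"], n5$total_cost)
})
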