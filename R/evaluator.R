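# Evaluation against the gold standard.
#
# Two views are scored. Entity concepts: was each gold gene (EntrezGene id)
# or mutation (triple) proposed as a candidate in its abstract at all?
# Relation concepts: did the aggregated judgment of each candidate
# <gene id, mutation triple> agree with gold membership? Relation scoring
# reports precision, accuracy, HIT recall (over judged candidates) and
# end-to-end recall (over the entire gold standard, including relations
# the extractors never surfaced).

#' Entity-level score from counts
#'
#' Ratios are computed from the three counts: precision =
#' correct/candidates (NA when no candidates), recall = correct/gold.
#' Precision at this level is approximate by construction: the gold
#' standard lists only entities involved in a curated relation.
#'
#' @param entity_class label for the row (e.g. `"genes"`)
#' @param n_gold,n_candidates,n_correct integer counts
#' @return a one-row tibble with the counts and both ratios
#' @export
entity_score <- function(entity_class, n_gold, n_candidates, n_correct) {
  stopifnot(n_correct <= n_candidates, n_correct <= n_gold)
  tibble::tibble(
    entity_class = entity_class,
    n_gold = n_gold, n_candidates = n_candidates, n_correct = n_correct,
    precision = if (n_candidates > 0) n_correct / n_candidates else NA_real_,
    recall = if (n_gold > 0) n_correct / n_gold else NA_real_
  )
}

#' Score extracted entity concepts against gold
#'
#' Genes match on `(pmid, entrez_id)`; mutations on
#' `(pmid, level, wild, mutant, position)`; when a candidate table is
#' supplied, pairs match on the full relation key. Duplicates collapse to
#' concepts before counting.
#'
#' @param gene_concepts tibble with `pmid`, `entrez_id`
#' @param mutation_concepts tibble with `pmid`, `level`, `wild`, `mutant`,
#'   `position`
#' @param gold a gold tibble from [read_gold()]
#' @param candidates optional candidate tibble from [build_candidates()];
#'   adds the gene-mutation pair row
#' @return a tibble with one row per entity class (see [entity_score()])
#' @export
score_entities <- function(gene_concepts, mutation_concepts, gold,
                           candidates = NULL) {
  gold_genes <- dplyr::distinct(gold, .data$pmid, .data$entrez_id)
  gold_muts <- dplyr::distinct(gold, .data$pmid, .data$level, .data$wild,
                               .data$mutant, .data$position)
  gold_pairs <- dplyr::distinct(gold, .data$pmid, .data$entrez_id, .data$level,
                                .data$wild, .data$mutant, .data$position)
  cand_genes <- dplyr::distinct(gene_concepts, .data$pmid, .data$entrez_id)
  cand_muts <- dplyr::distinct(mutation_concepts, .data$pmid, .data$level,
                               .data$wild, .data$mutant, .data$position)
  out <- dplyr::bind_rows(
    entity_score("genes", nrow(gold_genes), nrow(cand_genes),
                 nrow(dplyr::semi_join(cand_genes, gold_genes,
                                       by = c("pmid", "entrez_id")))),
    entity_score("mutations", nrow(gold_muts), nrow(cand_muts),
                 nrow(dplyr::semi_join(cand_muts, gold_muts,
                                       by = c("pmid", "level", "wild", "mutant",
                                              "position"))))
  )
  if (!is.null(candidates)) {
    cand_pairs <- dplyr::distinct(candidates, .data$pmid, .data$entrez_id,
                                  .data$level, .data$wild, .data$mutant,
                                  .data$position)
    out <- dplyr::bind_rows(out, entity_score(
      "gene-mutation pairs", nrow(gold_pairs), nrow(cand_pairs),
      nrow(dplyr::semi_join(cand_pairs, gold_pairs,
                            by = c("pmid", "entrez_id", "level", "wild",
                                   "mutant", "position")))
    ))
  }
  out
}

#' Relation-level scorecard from confusion counts
#'
#' `tp`/`fp` split the YES decisions by gold membership; `fn_judged`/`tn`
#' split the NO decisions. `n_gold_total` is the size of the whole gold
#' standard, which may exceed `tp + fn_judged` when the extractors missed
#' relations entirely; hence end-to-end recall <= HIT recall.
#'
#' @param tp,fp,fn_judged,tn confusion counts over judged items
#' @param n_gold_total total gold relations (judged or not)
#' @return an object of class `relation_scorecard`
#' @examples
#' relation_scorecard(350, 137, 21, 570, n_gold_total = 444)
#' @export
relation_scorecard <- function(tp, fp, fn_judged, tn, n_gold_total) {
  stopifnot(tp >= 0, fp >= 0, fn_judged >= 0, tn >= 0,
            tp + fn_judged <= n_gold_total)
  n_judged <- tp + fp + fn_judged + tn
  structure(list(
    tp = tp, fp = fp, fn_judged = fn_judged, tn = tn,
    n_judged = n_judged, n_gold_total = n_gold_total,
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    accuracy = if (n_judged > 0) (tp + tn) / n_judged else NA_real_,
    hit_recall = if (tp + fn_judged > 0) tp / (tp + fn_judged) else NA_real_,
    e2e_recall = if (n_gold_total > 0) tp / n_gold_total else NA_real_
  ), class = "relation_scorecard")
}

#' @export
print.relation_scorecard <- function(x, ...) {
  cat("Relation scorecard (concept level)\n")
  cat(sprintf("               gold YES  gold NO   total\n"))
  cat(sprintf("  judged YES  %8d %8d %7d   precision %5.1f%%\n",
              x$tp, x$fp, x$tp + x$fp, pct1(x$precision)))
  cat(sprintf("  judged NO   %8d %8d %7d   HIT recall %4.1f%%\n",
              x$fn_judged, x$tn, x$fn_judged + x$tn, pct1(x$hit_recall)))
  cat(sprintf("  total       %8d %8d %7d   accuracy  %5.1f%%\n",
              x$tp + x$fn_judged, x$fp + x$tn, x$n_judged, pct1(x$accuracy)))
  cat(sprintf("  total gold  %8d                     E2E recall %4.1f%%\n",
              x$n_gold_total, pct1(x$e2e_recall)))
  invisible(x)
}

#' @rdname relation_scorecard
#' @param x a `relation_scorecard`
#' @export
scorecard_to_tibble <- function(x) {
  tibble::tibble(
    tp = x$tp, fp = x$fp, fn_judged = x$fn_judged, tn = x$tn,
    n_judged = x$n_judged, n_gold_total = x$n_gold_total,
    precision = x$precision, accuracy = x$accuracy,
    hit_recall = x$hit_recall, e2e_recall = x$e2e_recall
  )
}

# Gold relation keys as a deduplicated tibble.
gold_keys <- function(gold) {
  dplyr::distinct(gold, .data$pmid, .data$entrez_id, .data$level, .data$wild,
                  .data$mutant, .data$position)
}

# Per-item gold-derived truth for a candidate table.
candidate_truth <- function(candidates, gold) {
  gk <- dplyr::mutate(gold_keys(gold), in_gold = TRUE)
  out <- dplyr::left_join(
    candidates, gk,
    by = c("pmid", "entrez_id", "level", "wild", "mutant", "position")
  )
  ifelse(!is.na(out$in_gold), "YES", "NO")
}

#' Score aggregated relation decisions against gold
#'
#' A YES decision is a true positive iff its `(pmid, entrez_id, triple)` is
#' in the gold standard; NO decisions split into judged false negatives and
#' true negatives likewise. `drop_nonlocal` removes items whose mutation
#' position was window-searched before scoring (the post-hoc rescoring
#' configuration); `n_gold_total` stays the full gold count regardless.
#'
#' @param decisions a decisions tibble (`item_id`, `label`)
#' @param candidates the candidate tibble the decisions refer to
#' @param gold a gold tibble
#' @param drop_nonlocal remove nonlocal-position items before scoring?
#' @return a `relation_scorecard`
#' @export
score_relations <- function(decisions, candidates, gold, drop_nonlocal = FALSE) {
  cand <- candidates[!candidates$is_control, , drop = FALSE]
  missing <- setdiff(decisions$item_id, cand$item_id)
  if (length(missing)) {
    stop(sprintf("decision(s) without matching candidate: %s",
                 paste(head(missing, 5L), collapse = ", ")), call. = FALSE)
  }
  d <- dplyr::inner_join(decisions, cand, by = "item_id")
  if (drop_nonlocal) d <- d[d$locality != "nonlocal", , drop = FALSE]
  truth <- candidate_truth(d, gold)
  relation_scorecard(
    tp = sum(d$label == "YES" & truth == "YES"),
    fp = sum(d$label == "YES" & truth == "NO"),
    fn_judged = sum(d$label == "NO" & truth == "YES"),
    tn = sum(d$label == "NO" & truth == "NO"),
    n_gold_total = nrow(gold_keys(gold))
  )
}

#' Pairwise agreement and Cohen's kappa between workers
#'
#' For every worker pair sharing at least `min_items` judged items: raw
#' agreement is the share of identical responses; kappa corrects it by the
#' chance agreement expected from each worker's marginal response
#' distribution over the shared items, with three response categories.
#' When both workers are constant and identical, kappa is undefined
#' (reported NA with a note).
#'
#' @param judgments a judgments tibble
#' @param min_items minimum shared items for a pair to be reported
#' @return a tibble: `worker_a`, `worker_b`, `n_common`, `raw_agreement`,
#'   `kappa`, `note`
#' @export
pairwise_agreement <- function(judgments, min_items = 1L) {
  stopifnot(min_items >= 1L)
  key <- if ("slot_id" %in% names(judgments)) "slot_id" else "item_id"
  j <- judgments |>
    dplyr::distinct(dplyr::across(dplyr::all_of(c("worker_id", key, "response"))))
  workers <- sort(unique(j$worker_id))
  if (length(workers) < 2L) {
    return(tibble::tibble(worker_a = character(), worker_b = character(),
                          n_common = integer(), raw_agreement = double(),
                          kappa = double(), note = character()))
  }
  pairs <- combn(workers, 2L)
  rows <- purrr::map(seq_len(ncol(pairs)), function(p) {
    a <- pairs[1L, p]
    b <- pairs[2L, p]
    ja <- j[j$worker_id == a, c(key, "response")]
    jb <- j[j$worker_id == b, c(key, "response")]
    shared <- dplyr::inner_join(ja, jb, by = key, suffix = c("_a", "_b"))
    if (nrow(shared) < min_items) return(NULL)
    po <- mean(shared$response_a == shared$response_b)
    cats <- c("YES", "NO", "INCONSISTENT")
    ma <- table(factor(shared$response_a, levels = cats)) / nrow(shared)
    mb <- table(factor(shared$response_b, levels = cats)) / nrow(shared)
    pe <- sum(as.numeric(ma) * as.numeric(mb))
    if (pe >= 1 - 1e-12) {
      kappa <- NA_real_
      note <- "both raters constant and identical: kappa undefined"
    } else {
      kappa <- (po - pe) / (1 - pe)
      note <- NA_character_
    }
    tibble::tibble(worker_a = a, worker_b = b, n_common = nrow(shared),
                   raw_agreement = po, kappa = kappa, note = note)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(worker_a = character(), worker_b = character(),
                          n_common = integer(), raw_agreement = double(),
                          kappa = double(), note = character())
  }
  out
}

#' Rescore relations with unanimous expert surface labels
#'
#' Surface-level rescoring: for items covered by expert labels where all
#' three annotators agree, the gold-derived truth is overridden by the
#' unanimous expert label before the confusion is recomputed; items with
#' partial coverage or disagreement are left as scored. `n_gold_total` is
#' unchanged.
#'
#' @param decisions,candidates,gold as in [score_relations()]
#' @param expert_labels long tibble: `item_id`, `annotator`, `label`
#'   (YES/NO); three labels per covered item
#' @param drop_nonlocal as in [score_relations()]
#' @return a `relation_scorecard`
#' @export
surface_rescore <- function(decisions, candidates, gold, expert_labels,
                            drop_nonlocal = FALSE) {
  cand <- candidates[!candidates$is_control, , drop = FALSE]
  d <- dplyr::inner_join(decisions, cand, by = "item_id")
  if (drop_nonlocal) d <- d[d$locality != "nonlocal", , drop = FALSE]
  truth <- candidate_truth(d, gold)
  if (!is.null(expert_labels) && nrow(expert_labels)) {
    unanimous <- expert_labels |>
      dplyr::group_by(.data$item_id) |>
      dplyr::summarise(n = dplyr::n(),
                       agreed = dplyr::n_distinct(.data$label) == 1L,
                       label = .data$label[1L], .groups = "drop") |>
      dplyr::filter(.data$n >= 3L, .data$agreed)
    ix <- match(d$item_id, unanimous$item_id)
    truth <- ifelse(!is.na(ix), unanimous$label[ix], truth)
  }
  relation_scorecard(
    tp = sum(d$label == "YES" & truth == "YES"),
    fp = sum(d$label == "YES" & truth == "NO"),
    fn_judged = sum(d$label == "NO" & truth == "YES"),
    tn = sum(d$label == "NO" & truth == "NO"),
    n_gold_total = nrow(gold_keys(gold))
  )
}

#' Cost-accuracy tradeoff table over aggregation scenarios
#'
#' One row per scenario: truncate to `n_turkers` judgments per item (NA =
#' all), optionally fire below-chance workers, re-profile, aggregate with
#' Naive Bayes, score, and cost the judgments actually used (test and
#' control alike, at the configured fee and overhead).
#'
#' @param judgments full-depth judgments (controls included)
#' @param candidates,gold scoring inputs (see [score_relations()])
#' @param scenarios tibble: `name`, `n_turkers` (integer or NA),
#'   `fire_below` (threshold or NA)
#' @param fee_per_judgment,overhead_rate,n_abstracts cost model
#' @param prior_yes,smoothing_alpha aggregation parameters
#' @param drop_nonlocal score on local-position items only?
#' @return a tibble: `name`, `n_turkers`, `fire_below`, `n_judgments`,
#'   `accuracy`, `total_cost`, `cost_per_abstract`
#' @export
cost_accuracy_curve <- function(judgments, candidates, gold, scenarios,
                                fee_per_judgment = 0.07, overhead_rate = 0.10,
                                n_abstracts = NULL, prior_yes = 0.5,
                                smoothing_alpha = 1, drop_nonlocal = FALSE) {
  rows <- purrr::pmap(scenarios, function(name, n_turkers, fire_below, ...) {
    j <- judgments
    fired <- character(0)
    if (!is.na(fire_below)) {
      f <- dynamic_fire(j, accuracy_threshold = fire_below)
      j <- f$judgments
      fired <- f$fired
    }
    if (!is.na(n_turkers)) j <- truncate_to_n(j, n_turkers)
    profiles <- profile_workers(j, smoothing_alpha)
    decisions <- nb_aggregate(j[!j$is_control, , drop = FALSE], profiles,
                              prior_yes = prior_yes)
    sc <- score_relations(decisions, candidates, gold,
                          drop_nonlocal = drop_nonlocal)
    cost <- cost_of_judgments(nrow(j), fee_per_judgment, overhead_rate,
                              n_abstracts)
    tibble::tibble(
      name = name, n_turkers = n_turkers, fire_below = fire_below,
      n_fired = length(fired), n_judgments = nrow(j),
      accuracy = sc$accuracy, total_cost = cost$total,
      cost_per_abstract = cost$cost_per_abstract
    )
  })
  dplyr::bind_rows(rows)
}

#' Accuracy of decisions against a latent-truth ledger
#'
#' For simulation studies: the share of decided items whose label matches
#' the generator's latent truth.
#'
#' @param decisions a decisions tibble
#' @param items a ledger with `item_id`, `truth`
#' @return a single number in `[0, 1]`
#' @export
decision_accuracy <- function(decisions, items) {
  d <- dplyr::inner_join(decisions, items, by = "item_id")
  mean(d$label == d$truth)
}
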