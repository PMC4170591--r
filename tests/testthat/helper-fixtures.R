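# Shared fixture builders and independent oracles.

demo_path <- function(f) system.file("extdata", f, package = "hybridcurate")

demo_abstracts <- function() read_medline(demo_path("demo.medline"))
demo_lexicon <- function() read_lexicon(demo_path("demo_lexicon.tsv"))
demo_gold <- function() read_gold(demo_path("demo_gold.tsv"))

# A one-abstract tibble from raw text.
abstract_of <- function(body, pmid = "1", title = "T") {
  tibble::tibble(pmid = pmid, title = title, body = body,
                 display_text = paste0(title, "\n", body))
}

# Judgment rows from vectors (control rows carry their truth).
judgments_of <- function(worker_id, item_id, response,
                         timestamp = seq_along(response),
                         is_control = FALSE, control_truth = NA_character_) {
  tibble::tibble(worker_id = worker_id, item_id = item_id, response = response,
                 timestamp = timestamp, is_control = is_control,
                 control_truth = control_truth)
}

# Control-judgment block for one worker: n_pos/n_neg controls with the given
# numbers answered correctly.
control_block <- function(worker, ok_pos, n_pos, ok_neg, n_neg, t0 = 0) {
  resp_pos <- c(rep("YES", ok_pos), rep("NO", n_pos - ok_pos))
  resp_neg <- c(rep("NO", ok_neg), rep("YES", n_neg - ok_neg))
  judgments_of(
    worker_id = worker,
    item_id = paste0("c", seq_len(n_pos + n_neg), "_", worker),
    response = c(resp_pos, resp_neg),
    timestamp = t0 + seq_len(n_pos + n_neg),
    is_control = TRUE,
    control_truth = c(rep("YES", n_pos), rep("NO", n_neg))
  )
}

# Independent oracle: two-class posterior enumeration for one item.
# profiles: tibble rows aligned with responses (p_yes_pos, p_yes_neg, ...).
nb_brute <- function(responses, profiles, prior_yes = 0.5) {
  lik_pos <- 1
  lik_neg <- 1
  for (i in seq_along(responses)) {
    r <- responses[i]
    if (r == "YES") {
      lik_pos <- lik_pos * profiles$p_yes_pos[i]
      lik_neg <- lik_neg * profiles$p_yes_neg[i]
    } else if (r == "NO") {
      lik_pos <- lik_pos * profiles$p_no_pos[i]
      lik_neg <- lik_neg * profiles$p_no_neg[i]
    } # INCONSISTENT: likelihood 1 under both classes
  }
  post_yes <- prior_yes * lik_pos
  post_no <- (1 - prior_yes) * lik_neg
  log(post_yes / post_no)
}

# Independent oracle: Cohen's kappa from a square contingency table.
kappa_brute <- function(tab) {
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  (po - pe) / (1 - pe)
}

# Small simulated crowd for aggregation studies: workers are built directly
# (volumes cover the stream) so tests control ability exactly.
test_crowd <- function(seed, n_items = 150, n_workers = 10, k = 5,
                       sens = NULL, spec = NULL, control_fraction = 0.3,
                       pool_size = 40, truth_rate = 0.35,
                       inconsistent_rate = 0.014) {
  withr::with_seed(seed, {
    if (is.null(sens)) sens <- runif(n_workers, 0.55, 0.95)
    if (is.null(spec)) spec <- runif(n_workers, 0.55, 0.95)
    items <- tibble::tibble(
      item_id = sprintf("i%04d", seq_len(n_items)),
      truth = ifelse(runif(n_items) < truth_rate, "YES", "NO")
    )
    pool <- tibble::tibble(
      item_id = sprintf("c%03d", seq_len(pool_size)),
      control_truth = rep(c("YES", "NO"), length.out = pool_size)
    )
    pool$truth <- pool$control_truth
  })
  stream <- inject_controls(items, pool, control_fraction, rng_seed = seed + 7L)
  workers <- tibble::tibble(
    worker_id = sprintf("w%02d", seq_len(n_workers)),
    sensitivity = sens, specificity = spec,
    inconsistent_rate = inconsistent_rate,
    volume = nrow(stream)
  )
  judgments <- simulate_judgments(stream, workers, k, seed = seed + 13L)
  list(judgments = judgments, items = items, workers = workers, stream = stream)
}

# NB accuracy of a judgment set against the ledger, re-profiling first.
nb_accuracy <- function(judgments, items, prior_yes = 0.5) {
  profiles <- profile_workers(judgments)
  decisions <- nb_aggregate(judgments[!judgments$is_control, , drop = FALSE],
                            profiles, prior_yes = prior_yes)
  decision_accuracy(decisions, items)
}

# Random relation-scoring fixture: candidates with random locality, random
# gold membership, random decisions.
random_relation_fixture <- function(seed, n = 60) {
  withr::with_seed(seed, {
    cand <- tibble::tibble(
      item_id = sprintf("x%03d", seq_len(n)),
      pmid = sample(sprintf("p%02d", 1:8), n, replace = TRUE),
      entrez_id = as.character(sample(100:120, n, replace = TRUE)),
      level = sample(c("nucleotide", "protein"), n, replace = TRUE),
      wild = sample(c("A", "C", "G", "T"), n, replace = TRUE),
      mutant = sample(c("R", "H", "S", "P"), n, replace = TRUE),
      position = sample(1:500, n, replace = TRUE),
      locality = sample(c("local", "nonlocal"), n, replace = TRUE, prob = c(0.7, 0.3)),
      is_control = FALSE, control_truth = NA_character_
    )
    cand <- dplyr::distinct(cand, pmid, entrez_id, level, wild, mutant, position,
                            .keep_all = TRUE)
    in_gold <- runif(nrow(cand)) < 0.4
    gold <- cand[in_gold, c("pmid", "entrez_id", "level", "wild", "mutant", "position")]
    extra <- tibble::tibble(pmid = "p99", entrez_id = "999", level = "protein",
                            wild = "A", mutant = "V",
                            position = sample(1:100, 3), flags = list(character(0)))
    gold$flags <- list(character(0))
    gold <- dplyr::bind_rows(gold, extra)
    decisions <- tibble::tibble(
      item_id = cand$item_id,
      label = sample(c("YES", "NO"), nrow(cand), replace = TRUE)
    )
  })
  list(candidates = cand, gold = gold, decisions = decisions)
}
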