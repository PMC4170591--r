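test_that("worker profiles tally control counts with add-alpha smoothing", {
  j <- control_block("w1", ok_pos = 5, n_pos = 5, ok_neg = 5, n_neg = 5)
  p <- profile_workers(j, smoothing_alpha = 1)
  expect_equal(p$p_yes_pos, 6 / 7)
  expect_equal(p$p_no_neg, 6 / 7)
  expect_equal(p$p_no_pos, 1 / 7)
  expect_equal(p$control_accuracy, 1.0)
  expect_false(p$no_controls)
})

test_that("a 50% worker on balanced controls has unit Bayes factors at alpha 0", {
  j <- control_block("w1", ok_pos = 4, n_pos = 5, ok_neg = 1, n_neg = 5)
  p <- profile_workers(j, smoothing_alpha = 0)
  expect_equal(p$control_accuracy, 0.5)
  expect_equal(p$p_yes_pos, p$p_yes_neg)
  expect_equal(p$p_no_pos, p$p_no_neg)
})

test_that("workers without countable controls get a flagged uniform profile", {
  j <- judgments_of("w1", c("a", "b"), c("INCONSISTENT", "INCONSISTENT"),
                    is_control = TRUE, control_truth = c("YES", "NO"))
  p <- profile_workers(j)
  expect_true(p$no_controls)
  expect_equal(p$p_yes_pos, 0.5)
  expect_equal(p$p_yes_neg, 0.5)
  expect_true(is.na(p$control_accuracy))
})

test_that("single chance-level judgment yields log-odds zero and the NO tie rule", {
  prof <- profile_workers(control_block("w1", 4, 5, 1, 5), smoothing_alpha = 0)
  j <- judgments_of("w1", "item1", "YES")
  d <- nb_aggregate(j, prof, prior_yes = 0.5)
  expect_equal(d$log_odds, 0)
  expect_equal(d$label, "NO")
})

test_that("identical high-accuracy workers make 3-2 splits go with the majority", {
  profs <- dplyr::bind_rows(lapply(sprintf("w%d", 1:5), function(w) {
    profile_workers(control_block(w, 9, 10, 9, 10))
  }))
  j <- judgments_of(sprintf("w%d", 1:5), "item1",
                    c("YES", "YES", "YES", "NO", "NO"))
  d <- nb_aggregate(j, profs, prior_yes = 0.5)
  expect_equal(d$label, "YES")
  expect_gt(d$log_odds, 0)
})

test_that("Inconsistent responses abstain by default, count as NO on request", {
  prof <- profile_workers(control_block("w1", 9, 10, 9, 10))
  j <- judgments_of("w1", "item1", "INCONSISTENT")
  d <- nb_aggregate(j, prof)
  expect_equal(d$log_odds, 0)
  expect_equal(d$n_used, 0L)
  d2 <- nb_aggregate(j, prof, inconsistent = "as_no")
  expect_lt(d2$log_odds, 0)
})

test_that("aggregation refuses judgments from unprofiled workers", {
  prof <- profile_workers(control_block("w1", 9, 10, 9, 10))
  j <- judgments_of(c("w1", "ghost"), c("i", "i"), c("YES", "YES"))
  expect_error(nb_aggregate(j, prof), "no profile for worker")
})

test_that("NB log-odds equals exhaustive posterior enumeration on random cases", {
  withr::with_seed(99, {
    for (case in 1:300) {
      n <- sample(1:3, 1)
      profs <- tibble::tibble(
        worker_id = sprintf("w%d", seq_len(n)),
        p_yes_pos = runif(n, 0.05, 0.95)
      )
      profs$p_no_pos <- 1 - profs$p_yes_pos
      profs$p_yes_neg <- runif(n, 0.05, 0.95)
      profs$p_no_neg <- 1 - profs$p_yes_neg
      prior <- runif(1, 0.1, 0.9)
      resp <- sample(c("YES", "NO", "INCONSISTENT"), n, replace = TRUE)
      j <- judgments_of(profs$worker_id, "item", resp)
      d <- nb_aggregate(j, profs, prior_yes = prior)
      expect_equal(d$log_odds, nb_brute(resp, profs, prior), tolerance = 1e-12)
    }
  })
})

test_that("majority vote follows the strict-majority and tie rules", {
  mk <- function(resp) majority_aggregate(
    judgments_of(sprintf("w%d", seq_along(resp)), "i", resp))$label
  expect_equal(mk(c("YES", "YES", "NO", "NO", "NO")), "NO")
  expect_equal(mk(c("YES", "YES", "YES", "NO", "NO")), "YES")
  expect_equal(mk(c("YES", "NO")), "NO")
  expect_equal(mk(c("INCONSISTENT", "INCONSISTENT")), "NO")
})

test_that("NB with one shared profile and flat prior reduces to majority vote", {
  prof_one <- profile_workers(control_block("w1", 8, 10, 8, 10))
  workers <- sprintf("w%d", 1:5)
  profs <- dplyr::bind_rows(lapply(workers, function(w) {
    p <- prof_one
    p$worker_id <- w
    p
  }))
  withr::with_seed(41, {
    for (case in 1:50) {
      resp <- sample(c("YES", "NO"), 5, replace = TRUE)
      j <- judgments_of(workers, "i", resp)
      expect_equal(nb_aggregate(j, profs)$label, majority_aggregate(j)$label)
    }
  })
})

test_that("truncation keeps the n earliest judgments per item", {
  j <- judgments_of(c("b", "a", "c", "a", "b"), c("i1", "i1", "i1", "i2", "i2"),
                    c("YES", "NO", "YES", "YES", "NO"),
                    timestamp = c(3, 1, 2, 5, 4))
  t1 <- truncate_to_n(j, 1)
  expect_equal(nrow(t1), 2L)
  expect_equal(t1$worker_id[t1$item_id == "i1"], "a") # earliest
  expect_equal(truncate_to_n(j, 5), dplyr::arrange(j, item_id, timestamp),
               ignore_attr = TRUE)
  # timestamp ties break by worker id
  jt <- judgments_of(c("z", "a"), c("i", "i"), c("YES", "NO"), timestamp = c(1, 1))
  expect_equal(truncate_to_n(jt, 1)$worker_id, "a")
})

test_that("firing removes all judgments of below-chance workers", {
  good <- control_block("good", 9, 10, 9, 10)
  bad <- control_block("bad", 2, 10, 1, 10, t0 = 100)
  test_j <- judgments_of(c("good", "bad"), c("t1", "t1"), c("YES", "NO"),
                         timestamp = c(200, 201))
  j <- dplyr::bind_rows(good, bad, test_j)
  f <- dynamic_fire(j, accuracy_threshold = 0.5)
  expect_equal(f$fired, "bad")
  expect_false("bad" %in% f$judgments$worker_id)
  # everyone above threshold: identity
  f2 <- dynamic_fire(dplyr::bind_rows(good, test_j[1, ]), 0.5)
  expect_equal(f2$fired, character(0))
  expect_equal(nrow(f2$judgments), nrow(good) + 1L)
})

test_that("online firing cuts a worker from the failing control onward", {
  # worker answers controls wrong from the start: fired at the min_controls-th
  bad <- control_block("bad", 0, 6, 6, 6) # all pos controls wrong, negs right
  f <- dynamic_fire(bad, accuracy_threshold = 0.5, min_controls = 3, online = TRUE)
  expect_equal(f$fired, "bad")
  expect_lt(nrow(f$judgments), nrow(bad))
  expect_true(all(f$judgments$timestamp < min(bad$timestamp[3])))
})

test_that("the cost model is exact and linear; display truncates to the cent", {
  c0 <- compute_cost(1354, 5, 0.07, 0.10, n_abstracts = 275)
  expect_equal(c0$total, 521.29, tolerance = 1e-9)
  expect_equal(compute_cost(0, 5, 0.07)$total, 0)
  expect_equal(compute_cost(100, 5, 0)$total, 0)
  # linearity in each argument
  expect_equal(compute_cost(200, 5, 0.07, 0.1)$total,
               2 * compute_cost(100, 5, 0.07, 0.1)$total)
  expect_equal(compute_cost(100, 10, 0.07, 0.1)$total,
               2 * compute_cost(100, 5, 0.07, 0.1)$total)
  expect_equal(compute_cost(100, 5, 0.14, 0.1)$total,
               2 * compute_cost(100, 5, 0.07, 0.1)$total)
  expect_match(format_cost(c0), "\\$521.29")
  expect_match(format_cost(c0), "\\$1.89") # 1.8956 truncated, not rounded
})

test_that("aggregate accuracy beats the mean individual when all are above chance", {
  wins <- vapply(1:20, function(s) {
    crowd <- test_crowd(seed = 500 + s, n_items = 120, n_workers = 8)
    acc <- nb_accuracy(crowd$judgments, crowd$items)
    wa <- worker_test_accuracy(crowd$judgments, crowd$items)
    acc > stats::weighted.mean(wa$accuracy, wa$n_items)
  }, TRUE)
  expect_gte(mean(wins), 0.95)
})
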