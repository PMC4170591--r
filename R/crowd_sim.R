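# Simulated crowd of redundant judges.
#
# The simulator emulates the human stage of the pipeline: a small worker
# population of heterogeneous ability (a competent majority plus a
# below-chance minority), heavy-tailed work volumes (the most prolific
# worker may take every item, the least only one), a five-item qualifier
# gate, ~20% control items injected into the stream, and k-fold redundant
# assignment. It makes aggregation and evaluation testable without a crowd
# platform; latent truths come from the scenario generator's ledger.

#' Simulation configuration
#'
#' Defaults are the study conditions of the experiment the package models:
#' 1078 test items at a ~34% positive rate, a 99-item near-balanced control
#' pool at a 20% control fraction, 24 workers, 5-fold redundancy, a 5-item
#' qualifier passed at 4 correct, 7 cents per judgment with a 10% platform
#' overhead, and a 1.4% rate of the third ("Inconsistent") response.
#'
#' @param n_items number of test items
#' @param truth_rate probability a test item's latent truth is YES
#' @param n_workers workers sampled initially (topped up if capacity or the
#'   qualifier leaves too few)
#' @param redundancy judgments requested per item (k)
#' @param qualifier_size,qualifier_pass qualifier length and pass threshold
#' @param control_fraction target control share of each stream
#' @param control_pool_size size of the known-truth control pool
#' @param fee_per_judgment,overhead_rate cost model parameters (currency and
#'   fraction)
#' @param inconsistent_rate truth-independent probability of the third
#'   response
#' @param p_competent mixture weight of the competent worker component
#' @param competent_shape,poor_shape Beta shape pairs for sensitivity and
#'   specificity in the two components (competent mean 0.85; below-chance
#'   mean 0.35)
#' @param seed integer RNG seed
#' @return a list of class `sim_config`
#' @export
sim_config <- function(n_items = 1078L,
                       truth_rate = 371 / 1078,
                       n_workers = 24L,
                       redundancy = 5L,
                       qualifier_size = 5L,
                       qualifier_pass = 4L,
                       control_fraction = 0.2,
                       control_pool_size = 99L,
                       fee_per_judgment = 0.07,
                       overhead_rate = 0.10,
                       inconsistent_rate = 0.014,
                       p_competent = 0.8,
                       competent_shape = c(8.5, 1.5),
                       poor_shape = c(3.5, 6.5),
                       seed = 1L) {
  stopifnot(qualifier_pass <= qualifier_size, redundancy >= 1L,
            control_fraction >= 0, control_fraction < 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Sample a simulated worker population
#'
#' Sensitivity (P(YES | true YES)) and specificity (P(NO | true NO)) are
#' drawn per worker from a two-component Beta mixture; volumes (maximum
#' items a worker will do) are log-uniform on `1..max_volume`, giving the
#' heavy tail observed on crowd platforms.
#'
#' @param config a [sim_config()]
#' @param max_volume upper bound for volumes (typically the stream length)
#' @param n number of workers (defaults to `config$n_workers`)
#' @param id_offset offset for worker ids (used when topping up)
#' @return a tibble: `worker_id`, `sensitivity`, `specificity`,
#'   `inconsistent_rate`, `volume`, `competent`
#' @export
sample_workers <- function(config, max_volume, n = config$n_workers, id_offset = 0L) {
  competent <- runif(n) < config$p_competent
  draw <- function(is_comp) {
    sh <- if (is_comp) config$competent_shape else config$poor_shape
    rbeta(1L, sh[1L], sh[2L])
  }
  tibble::tibble(
    worker_id = sprintf("w%03d", id_offset + seq_len(n)),
    sensitivity = vapply(competent, draw, 1.0),
    specificity = vapply(competent, draw, 1.0),
    inconsistent_rate = config$inconsistent_rate,
    volume = pmax(1L, as.integer(ceiling(exp(runif(n, 0, log(max_volume)))))),
    competent = competent
  )
}

# One response from one worker given a latent truth.
worker_response <- function(truth, sensitivity, specificity, inconsistent_rate) {
  u <- runif(length(truth))
  inc <- u < inconsistent_rate
  correct <- runif(length(truth)) < ifelse(truth == "YES", sensitivity, specificity)
  resp <- ifelse(truth == "YES",
                 ifelse(correct, "YES", "NO"),
                 ifelse(correct, "NO", "YES"))
  ifelse(inc, "INCONSISTENT", resp)
}

#' Run the qualifier gate over a worker population
#'
#' Each worker answers `qualifier_size` known-truth items according to its
#' response probabilities; it passes when at least `qualifier_pass` are
#' correct. An always-Inconsistent worker can never pass.
#'
#' @param workers a worker tibble from [sample_workers()]
#' @param qualifier_truths character vector of YES/NO truths (one per
#'   qualifier item)
#' @param pass_threshold minimum correct responses to pass
#' @return `workers` with added columns `qualifier_correct`, `passed`
#' @export
run_qualifier <- function(workers, qualifier_truths, pass_threshold) {
  stopifnot(pass_threshold <= length(qualifier_truths))
  n_correct <- vapply(seq_len(nrow(workers)), function(i) {
    resp <- worker_response(qualifier_truths,
                            workers$sensitivity[i], workers$specificity[i],
                            workers$inconsistent_rate[i])
    sum(resp == qualifier_truths)
  }, 1L)
  workers$qualifier_correct <- n_correct
  workers$passed <- n_correct >= pass_threshold
  workers
}

#' Simulate redundant judgments over an item stream
#'
#' Each stream slot is judged by `k` distinct workers drawn uniformly among
#' those with remaining volume; responses follow each worker's confusion
#' probabilities against the slot's latent truth; timestamps record the
#' simulated completion order (within a slot, responder order is random).
#'
#' @param stream an item stream with `slot_id`, `item_id`, `truth`,
#'   `is_control`, `control_truth`
#' @param workers a worker tibble (only rows with `passed`, if present, are
#'   used)
#' @param k judgments per item
#' @param seed integer RNG seed
#' @return a judgments tibble: `worker_id`, `item_id`, `response`,
#'   `timestamp`, `is_control`, `control_truth`, `slot_id`
#' @export
simulate_judgments <- function(stream, workers, k, seed = 1L) {
  if ("passed" %in% names(workers)) workers <- workers[workers$passed, , drop = FALSE]
  if (nrow(workers) < k) {
    stop(sprintf("insufficient worker capacity: %d workers available for %d-fold redundancy",
                 nrow(workers), k), call. = FALSE)
  }
  n <- nrow(stream)
  out_worker <- character(n * k)
  out_resp <- character(n * k)
  out_slot <- integer(n * k)
  withr::with_seed(seed, {
    remaining <- workers$volume
    order_items <- sample.int(n) # fill in random order to avoid stranding
    for (row in order_items) {
      eligible <- which(remaining > 0L)
      if (length(eligible) < k) {
        stop(sprintf(
          "insufficient worker capacity: only %d workers with remaining volume for slot %s (need %d)",
          length(eligible), stream$slot_id[row], k), call. = FALSE)
      }
      chosen <- eligible[sample.int(length(eligible), k)]
      remaining[chosen] <- remaining[chosen] - 1L
      resp <- worker_response(rep(stream$truth[row], k),
                              workers$sensitivity[chosen],
                              workers$specificity[chosen],
                              workers$inconsistent_rate[chosen])
      idx <- (which(order_items == row) - 1L) * k + seq_len(k)
      ord <- sample.int(k) # responder order within the slot
      out_worker[idx] <- workers$worker_id[chosen][ord]
      out_resp[idx] <- resp[ord]
      out_slot[idx] <- stream$slot_id[row]
    }
  })
  slot_ix <- match(out_slot, stream$slot_id)
  tibble::tibble(
    worker_id = out_worker,
    item_id = stream$item_id[slot_ix],
    response = out_resp,
    timestamp = seq_len(n * k),
    is_control = stream$is_control[slot_ix],
    control_truth = stream$control_truth[slot_ix],
    slot_id = out_slot
  )
}

#' Run a complete simulated crowd scenario
#'
#' Generates test items with latent truths, builds a near-balanced control
#' pool, injects controls, samples and qualifies workers (topping up the
#' population until qualified capacity covers the requested redundancy),
#' and simulates all judgments.
#'
#' @param config a [sim_config()]
#' @return a list: `judgments`, `stream` (with truths: the generator's
#'   ledger), `items` (test items + truths), `control_pool`, `workers`
#'   (with qualifier outcome)
#' @examples
#' sim <- simulate_crowd(sim_config(n_items = 50, n_workers = 10, seed = 7))
#' head(sim$judgments)
#' @export
simulate_crowd <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(child_seed(config$seed, 1L), {
    items <- tibble::tibble(
      item_id = sprintf("item%05d", seq_len(config$n_items)),
      truth = ifelse(runif(config$n_items) < config$truth_rate, "YES", "NO")
    )
    n_pos <- ceiling(config$control_pool_size / 2)
    pool <- tibble::tibble(
      item_id = sprintf("ctrl%03d", seq_len(config$control_pool_size)),
      control_truth = sample(c(rep("YES", n_pos),
                               rep("NO", config$control_pool_size - n_pos)))
    )
    pool$truth <- pool$control_truth
  })
  stream <- inject_controls(items, pool, config$control_fraction,
                            rng_seed = child_seed(config$seed, 2L))
  n_stream <- nrow(stream)
  needed <- config$redundancy * n_stream
  withr::with_seed(child_seed(config$seed, 3L), {
    workers <- sample_workers(config, max_volume = n_stream)
    qualifier_truths <- sample(c("YES", "NO"), config$qualifier_size,
                               replace = TRUE)
    workers <- run_qualifier(workers, qualifier_truths, config$qualifier_pass)
    # a crowd platform has an open worker supply: top up until the qualified
    # pool can cover the stream with some slack
    tries <- 0L
    while ((sum(workers$volume[workers$passed]) < 1.3 * needed ||
            sum(workers$passed) < config$redundancy + 2L) && tries < 50L) {
      extra <- sample_workers(config, max_volume = n_stream,
                              n = max(4L, config$n_workers %/% 4L),
                              id_offset = nrow(workers))
      extra <- run_qualifier(extra, qualifier_truths, config$qualifier_pass)
      workers <- dplyr::bind_rows(workers, extra)
      tries <- tries + 1L
    }
  })
  judgments <- simulate_judgments(stream, workers, config$redundancy,
                                  seed = child_seed(config$seed, 4L))
  list(judgments = judgments, stream = stream, items = items,
       control_pool = pool, workers = workers)
}

#' Per-worker accuracy against the latent truth ledger
#'
#' Convenience for simulation studies: the share of each worker's YES/NO
#' responses on test items that match the generator's latent truths.
#'
#' @param judgments a judgments tibble from [simulate_judgments()]
#' @param items the test-item ledger (`item_id`, `truth`)
#' @return a tibble: `worker_id`, `n_items`, `accuracy`
#' @export
worker_test_accuracy <- function(judgments, items) {
  judgments |>
    dplyr::filter(!.data$is_control, .data$response != "INCONSISTENT") |>
    dplyr::inner_join(items, by = "item_id") |>
    dplyr::group_by(.data$worker_id) |>
    dplyr::summarise(n_items = dplyr::n(),
                     accuracy = mean(.data$response == .data$truth),
                     .groups = "drop")
}
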