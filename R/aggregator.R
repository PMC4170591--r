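# Aggregation of redundant judgments.
#
# Each worker is one Naive Bayes feature: from its control-item record we
# estimate per-response likelihoods P(response | relation true) and
# P(response | relation false), and an item's label is the sign of the
# posterior log-odds summed over its judgments. A worker whose balanced
# control accuracy is exactly 50% has unit Bayes factors and contributes
# nothing; below-chance workers get their responses weighted *against*
# them, which is why the aggregate can beat every voting scheme that counts
# heads.

#' Estimate worker response likelihoods from control items
#'
#' Counts are tallied from control judgments only; Inconsistent responses
#' are excluded. Likelihoods use add-alpha smoothing (default alpha = 1,
#' Laplace). `control_accuracy` is the unsmoothed share of counted control
#' responses that are correct. Workers with no countable control judgments
#' get a uniform profile and a flag.
#'
#' @param judgments a judgments tibble (control rows must carry
#'   `control_truth`)
#' @param smoothing_alpha add-alpha pseudo-count
#' @return a tibble: `worker_id`, raw counts `n_yes_pos`, `n_no_pos`,
#'   `n_yes_neg`, `n_no_neg`, likelihoods `p_yes_pos`, `p_no_pos`,
#'   `p_yes_neg`, `p_no_neg`, `control_accuracy`, `n_controls`,
#'   `no_controls` flag
#' @export
profile_workers <- function(judgments, smoothing_alpha = 1) {
  workers <- unique(judgments$worker_id)
  ctrl <- judgments |>
    dplyr::filter(.data$is_control, .data$response %in% c("YES", "NO"),
                  !is.na(.data$control_truth))
  counts <- ctrl |>
    dplyr::count(.data$worker_id, .data$response, .data$control_truth) |>
    tidyr::pivot_wider(
      names_from = c("response", "control_truth"),
      values_from = "n", values_fill = 0L
    )
  for (col in c("YES_YES", "NO_YES", "YES_NO", "NO_NO")) {
    if (!col %in% names(counts)) counts[[col]] <- 0L
  }
  out <- tibble::tibble(worker_id = workers) |>
    dplyr::left_join(counts, by = "worker_id") |>
    dplyr::mutate(dplyr::across(dplyr::all_of(c("YES_YES", "NO_YES", "YES_NO", "NO_NO")),
                                ~ tidyr::replace_na(.x, 0L))) |>
    dplyr::rename(n_yes_pos = "YES_YES", n_no_pos = "NO_YES",
                  n_yes_neg = "YES_NO", n_no_neg = "NO_NO")
  a <- smoothing_alpha
  out |>
    dplyr::mutate(
      n_controls = .data$n_yes_pos + .data$n_no_pos + .data$n_yes_neg + .data$n_no_neg,
      no_controls = .data$n_controls == 0L,
      p_yes_pos = (.data$n_yes_pos + a) / (.data$n_yes_pos + .data$n_no_pos + 2 * a),
      p_no_pos = (.data$n_no_pos + a) / (.data$n_yes_pos + .data$n_no_pos + 2 * a),
      p_yes_neg = (.data$n_yes_neg + a) / (.data$n_yes_neg + .data$n_no_neg + 2 * a),
      p_no_neg = (.data$n_no_neg + a) / (.data$n_yes_neg + .data$n_no_neg + 2 * a),
      control_accuracy = ifelse(.data$n_controls > 0L,
                                (.data$n_yes_pos + .data$n_no_neg) / .data$n_controls,
                                NA_real_)
    ) |>
    dplyr::mutate(
      # degenerate smoothing (alpha = 0) with one-sided counts can yield 0/0
      p_yes_pos = ifelse(is.nan(.data$p_yes_pos), 0.5, .data$p_yes_pos),
      p_no_pos = ifelse(is.nan(.data$p_no_pos), 0.5, .data$p_no_pos),
      p_yes_neg = ifelse(is.nan(.data$p_yes_neg), 0.5, .data$p_yes_neg),
      p_no_neg = ifelse(is.nan(.data$p_no_neg), 0.5, .data$p_no_neg)
    )
}

#' Naive Bayes aggregation of judgments per item
#'
#' `log_odds = log(prior/(1 - prior)) + sum over judgments of
#' log(P(r | true) / P(r | false))`. Inconsistent responses contribute
#' nothing by default (`inconsistent = "ignore"`); with
#' `inconsistent = "as_no"` they are counted as NO. The label is YES iff
#' the log-odds is strictly positive; ties go to NO, the conservative
#' choice for database deposit.
#'
#' @param judgments a judgments tibble (typically test items only)
#' @param profiles worker profiles from [profile_workers()]
#' @param prior_yes prior probability that a candidate relation is true
#' @param inconsistent `"ignore"` or `"as_no"`
#' @return a decisions tibble: `item_id`, `log_odds`, `label`, `n_used`
#' @export
nb_aggregate <- function(judgments, profiles, prior_yes = 0.5,
                         inconsistent = c("ignore", "as_no")) {
  inconsistent <- match.arg(inconsistent)
  missing <- setdiff(unique(judgments$worker_id), profiles$worker_id)
  if (length(missing)) {
    stop(sprintf("no profile for worker(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  j <- dplyr::left_join(judgments, profiles, by = "worker_id")
  resp <- j$response
  if (inconsistent == "as_no") resp[resp == "INCONSISTENT"] <- "NO"
  lf <- rep(0, nrow(j))
  lf[resp == "YES"] <- log(j$p_yes_pos / j$p_yes_neg)[resp == "YES"]
  lf[resp == "NO"] <- log(j$p_no_pos / j$p_no_neg)[resp == "NO"]
  j$lf <- lf
  j$counted <- resp %in% c("YES", "NO")
  prior_term <- log(prior_yes / (1 - prior_yes))
  j |>
    dplyr::group_by(.data$item_id) |>
    dplyr::summarise(
      log_odds = prior_term + sum(.data$lf),
      n_used = sum(.data$counted),
      .groups = "drop"
    ) |>
    dplyr::mutate(label = ifelse(.data$log_odds > 0, "YES", "NO"))
}

#' Majority-vote aggregation per item
#'
#' Strict majority of the YES/NO judgments; ties and items with no
#' countable judgment go to NO.
#'
#' @param judgments a judgments tibble
#' @return a decisions tibble: `item_id`, `label`, `n_used`
#' @export
majority_aggregate <- function(judgments) {
  judgments |>
    dplyr::group_by(.data$item_id) |>
    dplyr::summarise(
      n_yes = sum(.data$response == "YES"),
      n_no = sum(.data$response == "NO"),
      .groups = "drop"
    ) |>
    dplyr::mutate(label = ifelse(.data$n_yes > .data$n_no, "YES", "NO"),
                  n_used = .data$n_yes + .data$n_no) |>
    dplyr::select("item_id", "label", "n_used")
}

#' Keep only the first n judgments per item
#'
#' Simulates having requested lower redundancy, by keeping the `n` earliest
#' judgments per stream slot (ties broken by worker id). When the judgments
#' carry a `slot_id` (simulator output), truncation is per slot; otherwise
#' per item id.
#'
#' @param judgments a judgments tibble with `timestamp`
#' @param n judgments to keep per item
#' @return the truncated judgments tibble
#' @export
truncate_to_n <- function(judgments, n) {
  stopifnot(n >= 1L)
  key <- if ("slot_id" %in% names(judgments)) "slot_id" else "item_id"
  judgments |>
    dplyr::group_by(dplyr::across(dplyr::all_of(key))) |>
    dplyr::arrange(.data$timestamp, .data$worker_id, .by_group = TRUE) |>
    dplyr::slice_head(n = n) |>
    dplyr::ungroup()
}

#' Fire workers performing below chance on control items
#'
#' Workers whose control accuracy (given at least `min_controls` countable
#' control judgments) falls below `accuracy_threshold` are dismissed and
#' all their judgments removed, so remaining items may carry fewer than k
#' judgments. The default mirrors the post-hoc simulation the package
#' models: final control accuracy decides. `online = TRUE` instead fires at
#' the first control judgment where the running accuracy drops below the
#' threshold (after `min_controls` controls), and removes only judgments
#' from that point on.
#'
#' @param judgments a judgments tibble
#' @param accuracy_threshold fire below this control accuracy (default 0.5,
#'   chance)
#' @param min_controls minimum countable control judgments before firing
#' @param online fire on the running accuracy instead of the final one?
#' @return a list: `judgments` (surviving), `fired` (worker ids)
#' @export
dynamic_fire <- function(judgments, accuracy_threshold = 0.5, min_controls = 1L,
                         online = FALSE) {
  stopifnot(accuracy_threshold >= 0, accuracy_threshold <= 1)
  if (!online) {
    prof <- profile_workers(judgments)
    fired <- prof$worker_id[!prof$no_controls &
                              prof$n_controls >= min_controls &
                              prof$control_accuracy < accuracy_threshold]
    return(list(
      judgments = judgments[!judgments$worker_id %in% fired, , drop = FALSE],
      fired = fired
    ))
  }
  cut_at <- judgments |>
    dplyr::filter(.data$is_control, .data$response %in% c("YES", "NO")) |>
    dplyr::group_by(.data$worker_id) |>
    dplyr::arrange(.data$timestamp, .by_group = TRUE) |>
    dplyr::mutate(
      correct = .data$response == .data$control_truth,
      running = cumsum(.data$correct) / dplyr::row_number(),
      n_seen = dplyr::row_number()
    ) |>
    dplyr::filter(.data$n_seen >= min_controls, .data$running < accuracy_threshold) |>
    dplyr::summarise(cut_time = min(.data$timestamp), .groups = "drop")
  fired <- cut_at$worker_id
  j <- dplyr::left_join(judgments, cut_at, by = "worker_id")
  keep <- is.na(j$cut_time) | j$timestamp < j$cut_time
  list(judgments = judgments[keep, , drop = FALSE], fired = fired)
}

#' Crowd-labor cost model
#'
#' `total = n_items * judgments_per_item * fee * (1 + overhead_rate)`;
#' per-abstract cost divides by the number of abstracts. Values are exact;
#' rounding (truncation to the cent) happens only at presentation via
#' [format_cost()].
#'
#' @param n_items number of items posted (controls included)
#' @param judgments_per_item redundancy actually paid for
#' @param fee_per_judgment fee per judgment, currency units
#' @param overhead_rate platform commission as a fraction of fees
#' @param n_abstracts abstracts covered (optional; enables per-abstract cost)
#' @return a list of class `curation_cost`: `total`, `cost_per_abstract`
#'   (NA without `n_abstracts`), plus the inputs
#' @examples
#' compute_cost(1354, 5, 0.07, 0.10, n_abstracts = 275)
#' @export
compute_cost <- function(n_items, judgments_per_item, fee_per_judgment,
                         overhead_rate = 0.10, n_abstracts = NULL) {
  stopifnot(n_items >= 0, judgments_per_item >= 0, fee_per_judgment >= 0,
            overhead_rate >= 0)
  total <- n_items * judgments_per_item * fee_per_judgment * (1 + overhead_rate)
  structure(list(
    total = total,
    cost_per_abstract = if (is.null(n_abstracts)) NA_real_ else total / n_abstracts,
    n_items = n_items, judgments_per_item = judgments_per_item,
    fee_per_judgment = fee_per_judgment, overhead_rate = overhead_rate,
    n_abstracts = n_abstracts %||% NA_real_
  ), class = "curation_cost")
}

#' @rdname compute_cost
#' @param x a `curation_cost`
#' @export
format_cost <- function(x) {
  sprintf("$%.2f total, $%s per abstract",
          floor_cents(x$total),
          ifelse(is.na(x$cost_per_abstract), "NA",
                 sprintf("%.2f", floor_cents(x$cost_per_abstract))))
}

#' @export
print.curation_cost <- function(x, ...) {
  cat(format_cost(x), "\n")
  invisible(x)
}

# Cost of a set of judgments actually paid for (dynamic scenarios).
cost_of_judgments <- function(n_judgments, fee_per_judgment, overhead_rate = 0.10,
                              n_abstracts = NULL) {
  compute_cost(n_judgments, 1L, fee_per_judgment, overhead_rate, n_abstracts)
}
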