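# End-to-end orchestration: extract -> tag -> build -> simulate/ingest ->
# aggregate -> evaluate, from one config, seeded and reproducible.

#' Read and validate a run configuration
#'
#' JSON with fields: `medline`, `lexicon`, `gold` (paths; `lexicon` may be
#' omitted when `external_genes` is given), optional `external_genes`
#' (stand-off TSV), `crowd` (`"simulate"` or `"ingest"`; ingest requires
#' `judgments` and `items` paths), `out_dir`, `seed`, and optional flag and
#' parameter overrides (`coding_filter`, `drop_nonlocal`, `include_dbsnp`,
#' `control_fraction`, `redundancy`, `fee_per_judgment`, `overhead_rate`,
#' `prior_yes`, `smoothing_alpha`, `fire_below`, simulator worker
#' parameters).
#'
#' @param path path to a JSON config, or a named list
#' @return the validated config list, with a `config_hash` attribute
#' @export
read_run_config <- function(path) {
  config <- if (is.character(path)) jsonlite::read_json(path, simplifyVector = TRUE) else path
  defaults <- list(
    crowd = "simulate", coding_filter = TRUE, drop_nonlocal = FALSE,
    include_dbsnp = FALSE, control_fraction = 0.2, redundancy = 5L,
    fee_per_judgment = 0.07, overhead_rate = 0.10, prior_yes = 0.5,
    smoothing_alpha = 1, fire_below = NA_real_, seed = 1L,
    qualifier_size = 5L, qualifier_pass = 4L, n_workers = 24L,
    inconsistent_rate = 0.014, p_competent = 0.8, control_pool_size = 30L
  )
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  for (f in c("medline", "gold")) {
    if (is.null(config[[f]])) stop(sprintf("config field '%s' is required", f), call. = FALSE)
    if (!file.exists(config[[f]])) {
      stop(sprintf("config field '%s': file not found: %s", f, config[[f]]), call. = FALSE)
    }
  }
  if (is.null(config$external_genes) && is.null(config$lexicon)) {
    stop("config needs either 'lexicon' or 'external_genes'", call. = FALSE)
  }
  if (!config$crowd %in% c("simulate", "ingest")) {
    stop("config field 'crowd' must be \"simulate\" or \"ingest\"", call. = FALSE)
  }
  if (config$crowd == "ingest" && is.null(config$judgments)) {
    stop("crowd mode \"ingest\" requires a 'judgments' path", call. = FALSE)
  }
  if (is.null(config$out_dir)) stop("config field 'out_dir' is required", call. = FALSE)
  attr(config, "config_hash") <-
    fnv1a_hex(jsonlite::toJSON(config[order(names(config))], auto_unbox = TRUE))
  config
}

#' Run the full hybrid-curation pipeline
#'
#' Executes every stage and writes a run directory of artifacts: a manifest
#' (config, hash, seed), stand-off entity files, the items manifest, the
#' judgments CSV (simulated or ingested), the decisions CSV, relation and
#' entity scorecards, the cost report and a plain-text log. Deterministic
#' given identical inputs and seed.
#'
#' @param config a config list or JSON path (see [read_run_config()])
#' @return (invisibly) a list of the in-memory artifacts
#' @export
run_pipeline <- function(config) {
  config <- read_run_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    invisible(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  hash <- attr(config, "config_hash")
  say("run config hash %s seed %d", hash, as.integer(config$seed))

  abstracts <- stage("read_medline", read_medline(config$medline))
  gold <- stage("read_gold", read_gold(config$gold))
  say("read %d abstracts, %d gold relations", nrow(abstracts), nrow(gold))

  mut <- stage("extract_mutations", extract_mutations(
    abstracts,
    coding_filter = isTRUE(config$coding_filter),
    drop_nonlocal = isTRUE(config$drop_nonlocal)
  ))
  say("extracted %d mutation concepts (%d dbSNP mentions, %d dropped)",
      nrow(mut$concepts), nrow(mut$dbsnp), nrow(mut$dropped))

  genes <- if (!is.null(config$external_genes)) {
    stage("ingest_external_genes",
          ingest_external_genes(read_standoff(config$external_genes), abstracts))
  } else {
    lexicon <- stage("read_lexicon", read_lexicon(config$lexicon))
    stage("extract_genes", extract_genes(abstracts, lexicon))
  }
  say("tagged %d gene concepts", nrow(genes))

  candidates <- stage("build_candidates", build_candidates(
    genes, mut$concepts, dbsnp = mut$dbsnp,
    include_dbsnp = isTRUE(config$include_dbsnp)
  ))
  say("built %d candidate relations", nrow(candidates))

  if (config$crowd == "simulate") {
    truth <- candidate_truth(candidates, gold)
    items <- tibble::tibble(item_id = candidates$item_id, truth = truth)
    n_pool <- min(config$control_pool_size, nrow(items))
    withr::with_seed(child_seed(config$seed, 11L), {
      pool_ix <- sample.int(nrow(items), n_pool)
    })
    pool <- tibble::tibble(item_id = paste0("ctrl|", items$item_id[pool_ix]),
                           control_truth = items$truth[pool_ix],
                           truth = items$truth[pool_ix])
    stream <- inject_controls(items, pool, config$control_fraction,
                              rng_seed = child_seed(config$seed, 12L))
    scfg <- sim_config(
      n_items = nrow(items), n_workers = config$n_workers,
      redundancy = config$redundancy, control_fraction = config$control_fraction,
      qualifier_size = config$qualifier_size, qualifier_pass = config$qualifier_pass,
      fee_per_judgment = config$fee_per_judgment, overhead_rate = config$overhead_rate,
      inconsistent_rate = config$inconsistent_rate, p_competent = config$p_competent,
      seed = config$seed
    )
    withr::with_seed(child_seed(config$seed, 13L), {
      workers <- sample_workers(scfg, max_volume = nrow(stream))
      qt <- sample(c("YES", "NO"), scfg$qualifier_size, replace = TRUE)
      workers <- run_qualifier(workers, qt, scfg$qualifier_pass)
      while (sum(workers$volume[workers$passed]) < 1.3 * scfg$redundancy * nrow(stream) ||
             sum(workers$passed) < scfg$redundancy + 2L) {
        extra <- sample_workers(scfg, max_volume = nrow(stream), n = 6L,
                                id_offset = nrow(workers))
        extra <- run_qualifier(extra, qt, scfg$qualifier_pass)
        workers <- dplyr::bind_rows(workers, extra)
      }
    })
    judgments <- stage("simulate_judgments", simulate_judgments(
      stream, workers, scfg$redundancy, seed = child_seed(config$seed, 14L)
    ))
    say("simulated %d judgments from %d qualified workers",
        nrow(judgments), sum(workers$passed))
  } else {
    judgments <- stage("read_judgments", read_judgments(config$judgments))
    say("ingested %d judgments", nrow(judgments))
  }

  if (!is.na(config$fire_below)) {
    f <- stage("dynamic_fire", dynamic_fire(judgments, config$fire_below))
    judgments <- f$judgments
    say("fired %d worker(s) below control accuracy %.2f",
        length(f$fired), config$fire_below)
  }
  profiles <- stage("profile_workers",
                    profile_workers(judgments, config$smoothing_alpha))
  decisions <- stage("nb_aggregate", nb_aggregate(
    judgments[!judgments$is_control, , drop = FALSE], profiles,
    prior_yes = config$prior_yes
  ))
  scorecard <- stage("score_relations", score_relations(
    decisions, candidates, gold, drop_nonlocal = isTRUE(config$drop_nonlocal)
  ))
  entity_scores <- stage("score_entities",
                         score_entities(genes, mut$concepts, gold, candidates))
  cost <- compute_cost(
    dplyr::n_distinct(judgments$item_id), config$redundancy,
    config$fee_per_judgment, config$overhead_rate, n_abstracts = nrow(abstracts)
  )
  say("relation accuracy %.1f%%, precision %.1f%%, E2E recall %.1f%%",
      pct1(scorecard$accuracy), pct1(scorecard$precision), pct1(scorecard$e2e_recall))

  provenance <- list(config_hash = hash, seed = config$seed)
  write_standoff(mutations_to_standoff(mut$concepts),
                 file.path(out_dir, "mutations.tsv"))
  write_standoff(genes_to_standoff(genes), file.path(out_dir, "genes.tsv"))
  write_items_manifest(candidates, file.path(out_dir, "items.csv"))
  write_judgments(judgments, file.path(out_dir, "judgments.csv"))
  readr::write_csv(decisions, file.path(out_dir, "decisions.csv"), progress = FALSE)
  jsonlite::write_json(
    c(provenance, list(relation_scorecard = scorecard_to_tibble(scorecard),
                       entity_scores = entity_scores)),
    file.path(out_dir, "scorecard.json"), auto_unbox = TRUE, digits = NA, na = "null"
  )
  jsonlite::write_json(
    c(provenance, unclass(cost)),
    file.path(out_dir, "cost.json"), auto_unbox = TRUE, digits = NA, na = "null"
  )
  jsonlite::write_json(
    c(provenance, list(config = config[order(names(config))])),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA, na = "null"
  )
  readr::write_lines(c(sprintf("# config %s seed %d", hash, as.integer(config$seed)),
                       log_lines),
                     file.path(out_dir, "run.log"))

  invisible(list(
    abstracts = abstracts, gold = gold, mutations = mut, genes = genes,
    candidates = candidates, judgments = judgments, profiles = profiles,
    decisions = decisions, scorecard = scorecard, entity_scores = entity_scores,
    cost = cost, config = config
  ))
}
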