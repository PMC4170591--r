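# Candidate gene-mutation relation items (HITs).
#
# Within each abstract, the cross product of distinct gene concepts and
# distinct mutation concepts forms the candidate relations shown to judges.
# dbSNP rs-identifier mentions are excluded by default: an rs id already
# names its gene in dbSNP, so there is nothing to judge.

#' Build candidate gene-mutation relations
#'
#' Forms the per-abstract cross product of gene concepts and mutation
#' concepts. The item id is the deterministic composite key
#' `pmid|entrez_id|level|wild|position|mutant`.
#'
#' @param gene_concepts tibble with `pmid`, `entrez_id`, `mentions`
#' @param mutation_concepts tibble with `pmid`, triple fields, `locality`,
#'   `concept_key`, `mentions`
#' @param dbsnp optional dbSNP mention tibble from [extract_mutations()]
#' @param include_dbsnp keep candidates for rs-identifier mentions? Default
#'   `FALSE`; when `TRUE`, dbSNP rows are crossed with genes too, keyed by
#'   rs id, with NA triple fields.
#' @return a candidate tibble: `item_id`, `pmid`, `entrez_id`, `level`,
#'   `wild`, `mutant`, `position`, `locality`, `is_control`, `control_truth`,
#'   plus `gene_mentions` and `mutation_mentions` list-columns
#' @export
build_candidates <- function(gene_concepts, mutation_concepts, dbsnp = NULL,
                             include_dbsnp = FALSE) {
  empty <- tibble::tibble(
    item_id = character(), pmid = character(), entrez_id = character(),
    level = character(), wild = character(), mutant = character(),
    position = integer(), locality = character(),
    is_control = logical(), control_truth = character(),
    gene_mentions = list(), mutation_mentions = list()
  )
  muts <- mutation_concepts
  if (include_dbsnp && !is.null(dbsnp) && nrow(dbsnp)) {
    rs <- dbsnp |>
      dplyr::group_by(.data$pmid, .data$rs_id) |>
      dplyr::summarise(
        mentions = list(mention_tibble(.data$start, .data$end, .data$surface)),
        .groups = "drop"
      ) |>
      dplyr::mutate(level = NA_character_, wild = NA_character_,
                    mutant = NA_character_, position = NA_integer_,
                    locality = "local", concept_key = .data$rs_id) |>
      dplyr::select(-"rs_id")
    muts <- dplyr::bind_rows(muts, rs)
  }
  if (nrow(gene_concepts) == 0L || nrow(muts) == 0L) return(empty)
  g <- gene_concepts |>
    dplyr::select("pmid", "entrez_id", gene_mentions = "mentions")
  m <- muts |>
    dplyr::select("pmid", "level", "wild", "mutant", "position", "locality",
                  "concept_key", mutation_mentions = "mentions")
  out <- dplyr::inner_join(g, m, by = "pmid", relationship = "many-to-many")
  if (nrow(out) == 0L) return(empty)
  out |>
    dplyr::mutate(
      item_id = paste(.data$pmid, .data$entrez_id, .data$concept_key, sep = "|"),
      is_control = FALSE,
      control_truth = NA_character_
    ) |>
    dplyr::select("item_id", "pmid", "entrez_id", "level", "wild", "mutant",
                  "position", "locality", "is_control", "control_truth",
                  "gene_mentions", "mutation_mentions")
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Render one candidate relation as a self-contained judgment page
#'
#' All gene mentions are wrapped in one highlight class and all mutation
#' mentions in another (inline styles; no external assets), followed by the
#' three-way question: Yes / No / Inconsistent annotation. Control truths
#' are never rendered. Stripping tags and unescaping entities recovers the
#' abstract's display text exactly.
#'
#' @param candidate one row of a candidate tibble
#' @param abstract the matching row of the abstracts tibble
#' @return a length-1 character string of HTML
#' @export
render_item <- function(candidate, abstract) {
  stopifnot(nrow(candidate) == 1L, nrow(abstract) == 1L,
            candidate$pmid == abstract$pmid)
  gm <- candidate$gene_mentions[[1L]]
  mm <- candidate$mutation_mentions[[1L]]
  overlap <- any(outer(gm$start, mm$end, `<`) & outer(gm$end, mm$start, `>`))
  if (overlap) {
    stop(sprintf("item %s: gene and mutation mention spans overlap",
                 candidate$item_id), call. = FALSE)
  }
  spans <- dplyr::bind_rows(
    tibble::tibble(start = gm$start, end = gm$end, class = "gene"),
    tibble::tibble(start = mm$start, end = mm$end, class = "mutation")
  )
  spans <- spans[order(spans$start), , drop = FALSE]
  text <- abstract$display_text
  style <- c(gene = "background-color:#aee1ae", mutation = "background-color:#f6c7f6")
  pieces <- character(0)
  cursor <- 0L
  for (i in seq_len(nrow(spans))) {
    pieces <- c(pieces,
                html_escape(slice_text(text, cursor, spans$start[i])),
                sprintf('<span class="%s" style="%s">%s</span>',
                        spans$class[i], style[[spans$class[i]]],
                        html_escape(slice_text(text, spans$start[i], spans$end[i]))))
    cursor <- spans$end[i]
  }
  pieces <- c(pieces, html_escape(slice_text(text, cursor, nchar(text))))
  body <- paste(pieces, collapse = "")
  paste0(
    "<html><body>\n<div class=\"abstract\">", body, "</div>\n",
    "<p>Is the highlighted gene described as related to the highlighted mutation?</p>\n",
    "<label><input type=\"radio\" name=\"judgment\" value=\"YES\">Yes</label>\n",
    "<label><input type=\"radio\" name=\"judgment\" value=\"NO\">No</label>\n",
    "<label><input type=\"radio\" name=\"judgment\" value=\"INCONSISTENT\">",
    "Inconsistent annotation</label>\n</body></html>\n"
  )
}

#' Interleave control items into a test-item stream
#'
#' Controls are drawn with replacement from the control pool so that the
#' expected control share of the final stream equals `fraction`, and are
#' interleaved uniformly at random. The result is reproducible from
#' `rng_seed`. Each stream row gets a unique `slot_id`; a control item may
#' recur under different slots.
#'
#' @param items a tibble of test items (must have `item_id`; any other
#'   columns are carried through)
#' @param control_pool a tibble of control items with `item_id` and
#'   `control_truth` in `c("YES", "NO")`
#' @param fraction target control share of the stream, in `[0, 1)`
#' @param rng_seed integer seed
#' @return the ordered stream: input columns plus `slot_id`, `is_control`,
#'   `control_truth`
#' @export
inject_controls <- function(items, control_pool, fraction = 0.2, rng_seed = 1L) {
  stopifnot(fraction >= 0, fraction < 1)
  items$is_control <- FALSE
  if (!"control_truth" %in% names(items)) items$control_truth <- NA_character_
  if (fraction == 0) {
    items$slot_id <- seq_len(nrow(items))
    return(items)
  }
  if (is.null(control_pool) || nrow(control_pool) == 0L) {
    stop("control fraction > 0 requires a non-empty control pool", call. = FALSE)
  }
  stopifnot(all(control_pool$control_truth %in% c("YES", "NO")))
  withr::with_seed(rng_seed, {
    n_test <- nrow(items)
    n_ctrl <- rbinom(1L, size = round(n_test / (1 - fraction)), prob = fraction)
    picked <- control_pool[sample.int(nrow(control_pool), n_ctrl, replace = TRUE), ,
                           drop = FALSE]
    picked$is_control <- TRUE
    stream <- dplyr::bind_rows(items, picked)
    stream <- stream[sample.int(nrow(stream)), , drop = FALSE]
  })
  stream$slot_id <- seq_len(nrow(stream))
  stream
}

#' Write the items manifest
#'
#' Flat CSV view of a candidate/stream tibble (mention list-columns are
#' omitted; stand-off files carry the spans).
#'
#' @param items a candidate or stream tibble
#' @param path output path
#' @export
write_items_manifest <- function(items, path) {
  keep <- intersect(c("slot_id", "item_id", "pmid", "entrez_id", "level", "wild",
                      "mutant", "position", "locality", "is_control", "control_truth"),
                    names(items))
  readr::write_csv(items[, keep], path, na = "", progress = FALSE)
  invisible(path)
}
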