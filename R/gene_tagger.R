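# Gene mention tagging normalized to EntrezGene identifiers.
#
# Two paths produce the same gene-concept table: (i) the native path —
# longest-match gazetteer tagging against a human gene lexicon, followed by
# an abbreviation-resolution filter that drops short-form hits whose spelled-
# out long form is not a human gene name (the classic "CAT" trap: the text
# says chloramphenicol acetyltransferase, not catalase); (ii) the fidelity
# path — ingesting stand-off annotations produced by an external tagger.

#' Read a gene lexicon
#'
#' TSV with header columns `name`, `entrez_id`, `name_type` (e.g. `symbol`,
#' `synonym`, `full_name`). Restricted by construction to human genes: the
#' lexicon is the species filter.
#'
#' @param path path to the lexicon TSV (plain or gzip)
#' @return a tibble with the three columns, deduplicated on `name`
#' @export
read_lexicon <- function(path) {
  lx <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  required <- c("name", "entrez_id", "name_type")
  missing <- setdiff(required, names(lx))
  if (length(missing)) {
    stop(sprintf("lexicon is missing required column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (any(is.na(suppressWarnings(as.integer(lx$entrez_id))))) {
    stop("lexicon entrez_id values must be positive integers rendered as text",
         call. = FALSE)
  }
  dplyr::distinct(tibble::as_tibble(lx), .data$name, .keep_all = TRUE)
}

# Case rule shared by tagging and lexicon lookup: short symbols (<= 5
# characters) match exactly; longer names match case-insensitively.
lexicon_lookup <- function(lexicon, name) {
  hit <- lexicon$entrez_id[lexicon$name == name & nchar(lexicon$name) <= 5L]
  if (length(hit)) return(hit[1L])
  low <- tolower(name)
  long <- nchar(lexicon$name) >= 6L
  hit <- lexicon$entrez_id[long & tolower(lexicon$name) == low]
  if (length(hit)) hit[1L] else NA_character_
}

#' Tag gene mentions with a gazetteer
#'
#' Longest-match, token-boundary matching of every lexicon name against the
#' text. Symbols of five or fewer characters match case-sensitively; longer
#' names match case-insensitively. Hits are grouped per EntrezGene id.
#'
#' @param display_text a length-1 string
#' @param lexicon a lexicon tibble from [read_lexicon()]
#' @return a tibble with `entrez_id` and a `mentions` list-column of spans,
#'   ordered by first mention
#' @examples
#' lx <- tibble::tibble(name = c("BRCA1", "ESR1"), entrez_id = c("672", "2099"),
#'                      name_type = "symbol")
#' tag_genes("BRCA1 and ESR1 variants", lx)
#' @export
tag_genes <- function(display_text, lexicon) {
  if (nrow(lexicon) == 0L) stop("empty gene lexicon", call. = FALSE)
  hits <- purrr::pmap(lexicon, function(name, entrez_id, name_type, ...) {
    rx <- paste0("(?<![A-Za-z0-9])", rx_escape(name), "(?![A-Za-z0-9])")
    h <- regex_find(display_text, rx, ignore_case = nchar(name) >= 6L)
    if (nrow(h) == 0L) return(NULL)
    h$entrez_id <- entrez_id
    h
  })
  hits <- dplyr::bind_rows(hits)
  if (nrow(hits) == 0L) {
    return(tibble::tibble(entrez_id = character(), mentions = list()))
  }
  hits$priority <- seq_len(nrow(hits))
  hits <- resolve_overlaps(hits)
  group_gene_mentions(hits)
}

rx_escape <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

# Group per-mention gene hits (columns start, end, surface, entrez_id) into
# concepts with a mentions list-column.
group_gene_mentions <- function(hits) {
  if (nrow(hits) == 0L) {
    return(tibble::tibble(entrez_id = character(), mentions = list()))
  }
  hits |>
    dplyr::group_by(.data$entrez_id) |>
    dplyr::summarise(
      mentions = list(mention_tibble(.data$start, .data$end, .data$surface)),
      .groups = "drop"
    ) |>
    dplyr::arrange(purrr::map_int(.data$mentions, ~ .x$start[1L]))
}

#' Detect abbreviation definitions in a text
#'
#' Finds parenthesized short forms immediately following their spelled-out
#' long forms, using the Schwartz-Hearst character-alignment rule set: the
#' candidate long form is the up-to `min(|short| + 5, 2|short|)` words before
#' the parenthesis; short-form characters are matched right-to-left against
#' the long form, and the short form's first character must align with the
#' start of a long-form word. Trailing digits in the short form that cannot
#' be aligned are dropped before retrying (so `ESR1` pairs with "estrogen
#' receptor alpha").
#'
#' @param display_text a length-1 string
#' @return a tibble of pairs: `long_form`, `short_form`, with spans of both
#' @examples
#' detect_abbreviations("Antagonists selective for estrogen receptor alpha (ESR1)")
#' @export
detect_abbreviations <- function(display_text) {
  empty <- tibble::tibble(long_form = character(), short_form = character(),
                          long_start = integer(), long_end = integer(),
                          short_start = integer(), short_end = integer())
  parens <- regex_find(display_text, "\\(([^()]{1,30})\\)")
  if (nrow(parens) == 0L) return(empty)
  out <- list()
  for (i in seq_len(nrow(parens))) {
    short <- substring(parens$surface[i], 2L, nchar(parens$surface[i]) - 1L)
    short <- trimws(short)
    if (!valid_short_form(short)) next
    short_start <- parens$start[i] + 1L
    # candidate long form: words before "(" in the same sentence
    prefix <- substring(display_text, 1L, parens$start[i])
    prefix <- sub(".*[.;\n]", "", prefix)
    words <- regex_find(prefix, "\\S+")
    if (nrow(words) == 0L) next
    max_words <- min(nchar(short) + 5L, 2L * nchar(short))
    take <- utils::tail(seq_len(nrow(words)), max_words)
    words <- words[take, , drop = FALSE]
    cand <- paste(words$surface, collapse = " ")
    lf <- find_best_long_form(short, cand)
    if (is.na(lf)) next
    # map the long form back to display_text offsets: it ends just before
    # " (", so scan leftward for the matching slice
    long_start <- parens$start[i] - nchar(lf) - 1L
    while (long_start >= 0L &&
           slice_text(display_text, long_start, long_start + nchar(lf)) != lf) {
      long_start <- long_start - 1L
    }
    if (long_start < 0L) next
    out[[length(out) + 1L]] <- tibble::tibble(
      long_form = lf, short_form = short,
      long_start = long_start, long_end = long_start + nchar(lf),
      short_start = short_start, short_end = short_start + nchar(short)
    )
  }
  if (!length(out)) return(empty)
  dplyr::bind_rows(out)
}

# Schwartz-Hearst short-form sanity conditions.
valid_short_form <- function(s) {
  nchar(s) >= 2L && nchar(s) <= 10L &&
    length(strsplit(s, "\\s+")[[1L]]) <= 2L &&
    grepl("[A-Za-z]", s) &&
    grepl("^[A-Za-z0-9]", s)
}

# Right-to-left character alignment of short form against candidate long
# form; returns the matched long-form suffix or NA. Falls back to the short
# form with digits stripped when the full form cannot be aligned.
find_best_long_form <- function(short, cand) {
  align <- function(s) {
    schars <- strsplit(tolower(s), "")[[1L]]
    lchars <- strsplit(tolower(cand), "")[[1L]]
    li <- length(lchars)
    for (si in rev(seq_along(schars))) {
      ch <- schars[si]
      if (!grepl("[a-z0-9]", ch)) next
      repeat {
        if (li < 1L) return(NA_character_)
        at_word_start <- li == 1L || !grepl("[a-z0-9]", lchars[li - 1L])
        if (lchars[li] == ch && (si > 1L || at_word_start)) break
        li <- li - 1L
      }
      li <- li - 1L
    }
    # trim to the start of the word containing the first matched character
    first <- li + 1L
    while (first > 1L && grepl("[A-Za-z0-9]", substring(cand, first - 1L, first - 1L))) {
      first <- first - 1L
    }
    lf <- substring(cand, first)
    if (nchar(lf) <= nchar(s)) return(NA_character_) # long form must be longer
    lf
  }
  lf <- align(short)
  if (is.na(lf) && grepl("[0-9]", short)) {
    stripped <- gsub("[0-9]", "", short)
    if (nchar(stripped) >= 1L) lf <- align(stripped)
  }
  lf
}

#' Filter gene concepts by abbreviation resolution
#'
#' For each gene mention whose surface equals a detected short form, the
#' mention is kept only if the paired long form — whole, or (by default) any
#' contiguous word subsequence of it — is a lexicon name for the same
#' EntrezGene id. Concepts left with no mentions are removed. Concepts with
#' at least one non-short-form mention are never removed.
#'
#' @param concepts a gene-concept tibble from [tag_genes()]
#' @param pairs abbreviation pairs from [detect_abbreviations()]
#' @param lexicon the lexicon used for tagging
#' @param partial allow a contiguous word subsequence of the long form to
#'   validate (default), or require the whole long form to match?
#' @return the filtered concept tibble
#' @export
filter_by_abbreviation <- function(concepts, pairs, lexicon, partial = TRUE) {
  if (nrow(concepts) == 0L || nrow(pairs) == 0L) return(concepts)
  long_validates <- function(long_form, entrez_id) {
    if (identical(lexicon_lookup(lexicon, long_form), entrez_id)) return(TRUE)
    if (!partial) return(FALSE)
    words <- strsplit(long_form, "\\s+")[[1L]]
    n <- length(words)
    for (i in seq_len(n)) {
      for (j in i:n) {
        sub <- paste(words[i:j], collapse = " ")
        if (sub == long_form) next
        if (identical(lexicon_lookup(lexicon, sub), entrez_id)) return(TRUE)
      }
    }
    FALSE
  }
  filtered <- purrr::pmap(concepts, function(entrez_id, mentions, ...) {
    keep <- vapply(seq_len(nrow(mentions)), function(k) {
      surf <- mentions$surface[k]
      hit <- pairs[pairs$short_form == surf, , drop = FALSE]
      if (nrow(hit) == 0L) return(TRUE) # not a defined short form: untouched
      any(vapply(hit$long_form, long_validates, TRUE, entrez_id = entrez_id))
    }, TRUE)
    if (!any(keep)) return(NULL)
    tibble::tibble(entrez_id = entrez_id, mentions = list(mentions[keep, , drop = FALSE]))
  })
  out <- dplyr::bind_rows(filtered)
  if (nrow(out) == 0L) {
    return(tibble::tibble(entrez_id = character(), mentions = list()))
  }
  out
}

#' Ingest externally produced gene annotations
#'
#' The fidelity path: stand-off rows with `entity_class == "gene"` and an
#' EntrezGene id in `concept_key` (for instance the output of a full gene
#' normalization system) are slice-validated and grouped per id per
#' abstract.
#'
#' @param annotations a stand-off tibble from [read_standoff()]
#' @param abstracts the abstracts the annotations index
#' @return a tibble with `pmid`, `entrez_id`, `mentions`
#' @export
ingest_external_genes <- function(annotations, abstracts) {
  genes <- annotations[annotations$entity_class == "gene", , drop = FALSE]
  validate_standoff(genes, abstracts)
  genes |>
    dplyr::rename(entrez_id = "concept_key") |>
    dplyr::group_by(.data$pmid) |>
    dplyr::group_modify(~ group_gene_mentions(.x)) |>
    dplyr::ungroup()
}

#' Extract gene concepts from abstracts (native path)
#'
#' Gazetteer tagging plus the abbreviation-resolution filter, per abstract.
#'
#' @param abstracts an abstracts tibble from [read_medline()]
#' @param lexicon a lexicon tibble from [read_lexicon()]
#' @param abbrev_filter apply the abbreviation filter?
#' @param partial see [filter_by_abbreviation()]
#' @return a tibble with `pmid`, `entrez_id`, `mentions`
#' @export
extract_genes <- function(abstracts, lexicon, abbrev_filter = TRUE, partial = TRUE) {
  rows <- purrr::map2(abstracts$pmid, abstracts$display_text, function(pmid, text) {
    concepts <- tag_genes(text, lexicon)
    if (abbrev_filter && nrow(concepts)) {
      pairs <- detect_abbreviations(text)
      concepts <- filter_by_abbreviation(concepts, pairs, lexicon, partial)
    }
    if (nrow(concepts)) concepts <- dplyr::mutate(concepts, pmid = pmid, .before = 1L)
    concepts
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    return(tibble::tibble(pmid = character(), entrez_id = character(), mentions = list()))
  }
  out
}

#' Export gene concepts as stand-off annotations
#'
#' @param concepts a gene-concept tibble with `pmid`, `entrez_id`, `mentions`
#' @return a stand-off tibble (entity_class `"gene"`)
#' @export
genes_to_standoff <- function(concepts) {
  if (nrow(concepts) == 0L) {
    return(tibble::tibble(pmid = character(), start = integer(), end = integer(),
                          surface = character(), entity_class = character(),
                          concept_key = character()))
  }
  concepts_to_standoff(concepts$pmid, concepts$entrez_id, concepts$mentions, "gene")
}
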