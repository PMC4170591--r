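# Mutation mention recognition and standardization.
#
# A point mutation is standardized to a triple <wild, mutant, position> at
# either the nucleotide or the protein level. Compositional surface forms
# ("c.758C>T", "Arg 117 His", "R117H", "T to C at position 59") are parsed
# directly; bare wild/mutant pairs ("substitution of Pro for Ser") trigger a
# window search of the surrounding text for the nearest integer, and such
# positions are flagged "nonlocal" — they are the dominant source of
# concept-level error, so downstream stages can drop them.

AA3_TO_1 <- c(
  Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C", Gln = "Q",
  Glu = "E", Gly = "G", His = "H", Ile = "I", Leu = "L", Lys = "K",
  Met = "M", Phe = "F", Pro = "P", Ser = "S", Thr = "T", Trp = "W",
  Tyr = "Y", Val = "V"
)
AA3_STOP <- c(Ter = "*")
AA1 <- unname(AA3_TO_1)
NT <- c("A", "C", "G", "T")

#' The mutation pattern registry
#'
#' Loads the versioned table of named surface-form patterns shipped with the
#' package (or a user-supplied table in the same two-plus-column TSV layout:
#' `pattern_id`, `level`, `regex`). Regexes may use the macro alphabets
#' `%NT%` (nucleotides, with `U` accepted and later mapped to `T`), `%AA1%`
#' (one-letter amino acids) and `%AA3%` (three-letter amino acids), which
#' are expanded at load time. Registry order is the tie-break priority when
#' overlapping matches have equal span.
#'
#' @param path path to a registry TSV; default is the shipped registry
#' @param include_stop also recognize stop-codon substitutions (`Ter`, `X`,
#'   `*` as mutant residues)? Off by default: the extractor emulated here
#'   does not recognize them, a documented recall loss.
#' @return a tibble with columns `pattern_id`, `level`, `regex`, `priority`
#' @export
mutation_patterns <- function(path = NULL, include_stop = FALSE) {
  path <- path %||% system.file("extdata", "mutation_patterns.tsv",
                                package = "hybridcurate")
  reg <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  stopifnot(all(c("pattern_id", "level", "regex") %in% names(reg)))
  aa1 <- AA1
  aa3 <- names(AA3_TO_1)
  nt <- c(NT, "U")
  if (include_stop) {
    aa1 <- c(aa1, "X", "\\*")
    aa3 <- c(aa3, names(AA3_STOP))
  }
  expand <- function(rx) {
    rx <- gsub("%NT%", paste0("[", paste(nt, collapse = ""), "]"), rx, fixed = TRUE)
    rx <- gsub("%AA1%", paste0("[", paste(setdiff(aa1, "\\*"), collapse = ""),
                               if ("\\*" %in% aa1) "*" else "", "]"), rx, fixed = TRUE)
    gsub("%AA3%", paste0("(?:", paste(aa3, collapse = "|"), ")"), rx, fixed = TRUE)
  }
  reg$regex <- vapply(reg$regex, expand, "")
  reg$priority <- seq_len(nrow(reg))
  tibble::as_tibble(reg)
}

#' The mutation stop-list
#'
#' Patterns that veto spurious mutation matches: cell-line names that look
#' like substitution codes (T47D), chromosome bands, and measurements with
#' units. A candidate match is removed when its span overlaps a stop-pattern
#' match in the same text.
#'
#' @param path path to a stop-list TSV (`stop_id`, `regex`); default is the
#'   shipped list
#' @return a tibble with columns `stop_id`, `regex`
#' @export
mutation_stoplist <- function(path = NULL) {
  path <- path %||% system.file("extdata", "mutation_stoplist.tsv",
                                package = "hybridcurate")
  sl <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  stopifnot(all(c("stop_id", "regex") %in% names(sl)))
  tibble::as_tibble(sl)
}

#' Match mutation surface-form patterns in a text
#'
#' Runs every registry pattern over `display_text` and resolves overlaps
#' longest-first, leftmost-first (registry order breaks remaining ties).
#' Captured components are returned raw; [standardize_matches()] normalizes
#' them.
#'
#' @param display_text a length-1 string (title + newline + body)
#' @param patterns a pattern registry from [mutation_patterns()]
#' @return a tibble of raw matches: `start`, `end`, `surface`, `pattern_id`,
#'   `level`, `wild`, `mut`, `pos` (components NA when not captured)
#' @examples
#' match_patterns("the c.758C>T change and the Arg 117 His substitution")
#' @export
match_patterns <- function(display_text, patterns = mutation_patterns()) {
  hits <- purrr::pmap(patterns, function(pattern_id, level, regex, priority) {
    h <- regex_find(display_text, regex)
    if (nrow(h) == 0L) return(NULL)
    for (col in c("wild", "mut", "pos")) {
      if (!col %in% names(h)) h[[col]] <- NA_character_
    }
    h$pattern_id <- pattern_id
    h$level <- level
    h$priority <- priority
    h[, c("start", "end", "surface", "pattern_id", "level", "wild", "mut", "pos", "priority")]
  })
  hits <- dplyr::bind_rows(hits)
  if (nrow(hits) == 0L) {
    return(tibble::tibble(
      start = integer(), end = integer(), surface = character(),
      pattern_id = character(), level = character(), wild = character(),
      mut = character(), pos = character()
    ))
  }
  out <- resolve_overlaps(hits)
  out$priority <- NULL
  out
}

#' Remove matches vetoed by the stop-list
#'
#' A match is removed when its span overlaps any stop-pattern match in the
#' text. Removals are recorded (with the stop pattern id) in the `"dropped"`
#' attribute of the result.
#'
#' @param matches a raw-match tibble from [match_patterns()]
#' @param display_text the text the matches index
#' @param stoplist a stop-list tibble from [mutation_stoplist()]
#' @return the surviving matches, with attribute `dropped`
#' @export
apply_stoplist <- function(matches, display_text, stoplist = mutation_stoplist()) {
  if (nrow(matches) == 0L || nrow(stoplist) == 0L) {
    attr(matches, "dropped") <- matches[0, ]
    return(matches)
  }
  stops <- purrr::pmap(stoplist, function(stop_id, regex) {
    h <- regex_find(display_text, regex)
    if (nrow(h)) h$stop_id <- stop_id
    h
  })
  stops <- dplyr::bind_rows(stops)
  if (nrow(stops) == 0L) {
    attr(matches, "dropped") <- matches[0, ]
    return(matches)
  }
  hit_stop <- vapply(seq_len(nrow(matches)), function(i) {
    ov <- matches$start[i] < stops$end & matches$end[i] > stops$start
    if (any(ov)) stops$stop_id[which(ov)[1L]] else NA_character_
  }, "")
  dropped <- matches[!is.na(hit_stop), , drop = FALSE]
  if (nrow(dropped)) dropped$stop_id <- hit_stop[!is.na(hit_stop)]
  out <- matches[is.na(hit_stop), , drop = FALSE]
  attr(out, "dropped") <- dropped
  out
}

# Normalize a captured residue symbol to one uppercase letter.
normalize_residue <- function(x, level) {
  x <- trimws(x)
  if (level == "nucleotide") {
    x <- toupper(x)
    if (x == "U") x <- "T"
    return(x)
  }
  if (nchar(x) == 1L) {
    x <- toupper(x)
    if (x == "X") x <- "*" # one-letter stop codon notation
    return(x)
  }
  key <- paste0(toupper(substring(x, 1, 1)), tolower(substring(x, 2)))
  out <- c(AA3_TO_1, AA3_STOP)[key]
  if (is.na(out)) NA_character_ else unname(out)
}

# Nearest integer in text within window_w characters of span [s, e);
# ties broken leftward. Returns NA_integer_ if none.
window_position <- function(display_text, s, e, window_w) {
  ints <- regex_find(display_text, "\\d+")
  if (nrow(ints) == 0L) return(NA_integer_)
  inside <- ints$start >= s & ints$end <= e
  ints <- ints[!inside, , drop = FALSE]
  if (nrow(ints) == 0L) return(NA_integer_)
  dist <- ifelse(ints$end <= s, s - ints$end, ints$start - e)
  dist[ints$start < e & ints$end > s] <- 0L # partial overlap: treat as adjacent
  ok <- dist <= window_w
  if (!any(ok)) return(NA_integer_)
  ints <- ints[ok, , drop = FALSE]
  dist <- dist[ok]
  pick <- order(dist, ints$start)[1L]
  as.integer(ints$surface[pick])
}

#' Standardize raw matches into mutation concepts
#'
#' Each raw match becomes one of: a mutation concept (complete compositional
#' form, locality `"local"`); a mutation concept whose position was found by
#' searching the surrounding `window_w` characters for the nearest integer
#' (locality `"nonlocal"`, ties broken leftward); a dbSNP rs-identifier
#' mention (kept separate, never decomposed into a triple); or a rejection
#' (wild equals mutant after normalization, or no position found in the
#' window).
#'
#' @param matches a raw-match tibble (after the stop-list)
#' @param display_text the text the matches index
#' @param window_w window half-width in characters for nonlocal position
#'   search (default 200)
#' @return a list with tibbles `concepts` (level, wild, mutant, position,
#'   locality + mention span), `dbsnp` (rs_id + span), `rejected`
#'   (span + reason)
#' @export
standardize_matches <- function(matches, display_text, window_w = 200L) {
  concepts <- list()
  dbsnp <- list()
  rejected <- list()
  for (i in seq_len(nrow(matches))) {
    m <- matches[i, ]
    if (m$level == "dbsnp") {
      dbsnp[[length(dbsnp) + 1L]] <- tibble::tibble(
        rs_id = m$surface, start = m$start, end = m$end, surface = m$surface
      )
      next
    }
    wild <- normalize_residue(m$wild, m$level)
    mutant <- normalize_residue(m$mut, m$level)
    if (is.na(wild) || is.na(mutant)) {
      rejected[[length(rejected) + 1L]] <- tibble::tibble(
        start = m$start, end = m$end, surface = m$surface,
        reason = "unrecognized residue symbol"
      )
      next
    }
    if (wild == mutant) {
      rejected[[length(rejected) + 1L]] <- tibble::tibble(
        start = m$start, end = m$end, surface = m$surface,
        reason = "wild type equals mutant type"
      )
      next
    }
    if (!is.na(m$pos)) {
      position <- as.integer(m$pos)
      locality <- "local"
    } else {
      position <- window_position(display_text, m$start, m$end, window_w)
      locality <- "nonlocal"
      if (is.na(position)) {
        rejected[[length(rejected) + 1L]] <- tibble::tibble(
          start = m$start, end = m$end, surface = m$surface,
          reason = sprintf("no position within %d characters", window_w)
        )
        next
      }
    }
    concepts[[length(concepts) + 1L]] <- tibble::tibble(
      level = m$level, wild = wild, mutant = mutant, position = position,
      locality = locality, start = m$start, end = m$end, surface = m$surface
    )
  }
  empty_concepts <- tibble::tibble(
    level = character(), wild = character(), mutant = character(),
    position = integer(), locality = character(), start = integer(),
    end = integer(), surface = character()
  )
  empty_dbsnp <- tibble::tibble(rs_id = character(), start = integer(),
                                end = integer(), surface = character())
  empty_rej <- tibble::tibble(start = integer(), end = integer(),
                              surface = character(), reason = character())
  list(
    concepts = if (length(concepts)) dplyr::bind_rows(concepts) else empty_concepts,
    dbsnp = if (length(dbsnp)) dplyr::bind_rows(dbsnp) else empty_dbsnp,
    rejected = if (length(rejected)) dplyr::bind_rows(rejected) else empty_rej
  )
}

#' Filter noncoding mutation concepts
#'
#' Drops concepts with negative positions and concepts whose mention
#' sentence explicitly places them in introns or untranslated regions. The
#' keyword set is configurable; sentence boundaries are a simple period /
#' semicolon split.
#'
#' @param concepts a per-mention concept tibble from [standardize_matches()]
#' @param display_text the text the concepts index
#' @param keywords noncoding-context keywords (matched case-insensitively at
#'   a word boundary within the mention sentence)
#' @return the surviving concepts, with attribute `dropped`
#' @export
filter_coding <- function(concepts, display_text,
                          keywords = c("intron", "IVS", "UTR", "untranslated", "promoter")) {
  if (nrow(concepts) == 0L) {
    attr(concepts, "dropped") <- concepts[0, ]
    return(concepts)
  }
  sentences <- regex_find(display_text, "[^.;]+")
  kw_rx <- paste0("(?i)\\b(?:", paste(keywords, collapse = "|"), ")")
  noncoding_sentence <- vapply(seq_len(nrow(sentences)), function(j) {
    grepl(kw_rx, sentences$surface[j], perl = TRUE)
  }, TRUE)
  in_noncoding <- vapply(concepts$start, function(s) {
    j <- which(sentences$start <= s & sentences$end > s)
    length(j) > 0L && any(noncoding_sentence[j])
  }, TRUE)
  negative <- concepts$position < 0L
  drop <- negative | in_noncoding
  dropped <- concepts[drop, , drop = FALSE]
  if (nrow(dropped)) {
    dropped$reason <- ifelse(negative[drop], "negative position", "noncoding context")
  }
  out <- concepts[!drop, , drop = FALSE]
  attr(out, "dropped") <- dropped
  out
}

# Serialized concept key for a mutation triple.
mutation_key <- function(level, wild, position, mutant) {
  paste(level, wild, position, mutant, sep = "|")
}

#' Group mutation mentions by standardized triple
#'
#' Mentions whose standardized `(level, wild, mutant, position)` coincide
#' are merged into one concept: mention spans are concatenated and sorted by
#' start offset, and the merged locality is `"local"` if any contributing
#' mention parsed its position inside the match.
#'
#' @param concepts a per-mention concept tibble (one abstract)
#' @return a deduplicated concept tibble with a `mentions` list-column and a
#'   `concept_key` column
#' @export
group_mutation_mentions <- function(concepts) {
  if (nrow(concepts) == 0L) {
    return(tibble::tibble(
      level = character(), wild = character(), mutant = character(),
      position = integer(), locality = character(), concept_key = character(),
      mentions = list()
    ))
  }
  concepts |>
    dplyr::group_by(.data$level, .data$wild, .data$mutant, .data$position) |>
    dplyr::summarise(
      locality = if (any(.data$locality == "local")) "local" else "nonlocal",
      mentions = list(mention_tibble(.data$start, .data$end, .data$surface)),
      .groups = "drop"
    ) |>
    dplyr::mutate(concept_key = mutation_key(.data$level, .data$wild,
                                             .data$position, .data$mutant)) |>
    dplyr::arrange(purrr::map_int(.data$mentions, ~ .x$start[1L]))
}

#' Extract standardized mutation concepts from abstracts
#'
#' The full mutation pipeline per abstract: pattern matching, stop-list
#' filtering, standardization with nonlocal window search, the coding-region
#' filter, and grouping of repeated mentions of one triple.
#'
#' @param abstracts an abstracts tibble from [read_medline()]
#' @param patterns,stoplist registries (see [mutation_patterns()],
#'   [mutation_stoplist()])
#' @param window_w nonlocal position search half-width, characters
#' @param coding_filter apply the noncoding filter?
#' @param drop_nonlocal drop concepts whose position came from the window
#'   search?
#' @return a list: `concepts` (tibble with `pmid`, triple fields, `locality`,
#'   `concept_key`, `mentions` list-column), `dbsnp` (rs-identifier mentions),
#'   `dropped` (per-stage removals with reasons)
#' @examples
#' ab <- tibble::tibble(pmid = "1", title = "BRCA1", body = "We found c.758C>T.",
#'                      display_text = "BRCA1\nWe found c.758C>T.")
#' extract_mutations(ab)$concepts
#' @export
extract_mutations <- function(abstracts,
                              patterns = mutation_patterns(),
                              stoplist = mutation_stoplist(),
                              window_w = 200L,
                              coding_filter = TRUE,
                              drop_nonlocal = FALSE) {
  per_abstract <- purrr::map2(abstracts$pmid, abstracts$display_text, function(pmid, text) {
    raw <- match_patterns(text, patterns)
    kept <- apply_stoplist(raw, text, stoplist)
    stop_dropped <- attr(kept, "dropped")
    std <- standardize_matches(kept, text, window_w)
    concepts <- std$concepts
    if (is.null(concepts) || nrow(concepts) == 0L) {
      concepts <- tibble::tibble(level = character(), wild = character(),
                                 mutant = character(), position = integer(),
                                 locality = character(), start = integer(),
                                 end = integer(), surface = character())
    }
    coding_dropped <- concepts[0, ]
    if (coding_filter) {
      concepts <- filter_coding(concepts, text)
      coding_dropped <- attr(concepts, "dropped")
    }
    nonlocal_dropped <- concepts[0, ]
    if (drop_nonlocal) {
      nonlocal_dropped <- concepts[concepts$locality == "nonlocal", , drop = FALSE]
      concepts <- concepts[concepts$locality == "local", , drop = FALSE]
    }
    grouped <- group_mutation_mentions(concepts)
    if (nrow(grouped)) grouped <- dplyr::mutate(grouped, pmid = pmid, .before = 1L)
    dropped <- dplyr::bind_rows(
      if (nrow(stop_dropped)) dplyr::mutate(
        tibble::tibble(start = stop_dropped$start, end = stop_dropped$end,
                       surface = stop_dropped$surface,
                       reason = paste0("stop-list: ", stop_dropped$stop_id)),
        stage = "stoplist"),
      if (nrow(std$rejected)) dplyr::mutate(std$rejected, stage = "standardize"),
      if (nrow(coding_dropped)) dplyr::mutate(
        coding_dropped[, c("start", "end", "surface", "reason")], stage = "coding_filter"),
      if (nrow(nonlocal_dropped)) dplyr::mutate(
        tibble::tibble(start = nonlocal_dropped$start, end = nonlocal_dropped$end,
                       surface = nonlocal_dropped$surface,
                       reason = "nonlocal position"),
        stage = "drop_nonlocal")
    )
    if (!is.null(dropped) && nrow(dropped)) dropped$pmid <- pmid
    dbsnp <- std$dbsnp
    if (nrow(dbsnp)) dbsnp$pmid <- pmid
    list(concepts = grouped, dbsnp = dbsnp, dropped = dropped)
  })
  list(
    concepts = dplyr::bind_rows(purrr::map(per_abstract, "concepts")),
    dbsnp = dplyr::bind_rows(purrr::map(per_abstract, "dbsnp")),
    dropped = dplyr::bind_rows(purrr::map(per_abstract, "dropped"))
  )
}

#' Export mutation concepts as stand-off annotations
#'
#' @param concepts grouped concepts from [extract_mutations()]
#' @return a stand-off tibble (entity_class `"mutation"`)
#' @export
mutations_to_standoff <- function(concepts) {
  if (nrow(concepts) == 0L) {
    return(tibble::tibble(pmid = character(), start = integer(), end = integer(),
                          surface = character(), entity_class = character(),
                          concept_key = character()))
  }
  concepts_to_standoff(concepts$pmid, concepts$concept_key, concepts$mentions, "mutation")
}
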