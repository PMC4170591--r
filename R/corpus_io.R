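#' Read a MEDLINE flat file of titles and abstracts
#'
#' Parses the tagged MEDLINE record format (`PMID- `, `TI  - `, `AB  - `,
#' continuation lines indented with spaces; records separated by blank
#' lines) into one row per record. Only the PMID, TI and AB fields are
#' retained: the pipeline operates on titles and abstracts.
#'
#' The canonical text of an abstract is `display_text = title \n body`; every
#' stand-off annotation in the package indexes this string with 0-based
#' half-open code-point offsets.
#'
#' @param path path to a MEDLINE flat file (plain or gzip)
#' @return a tibble with columns `pmid`, `title`, `body`, `display_text`
#' @examples
#' f <- system.file("extdata", "demo.medline", package = "hybridcurate")
#' read_medline(f)
#' @export
read_medline <- function(path) {
  lines <- readr::read_lines(path)
  # split into records on blank lines
  blank <- !nzchar(trimws(lines))
  rec_id <- cumsum(c(TRUE, blank[-length(blank)])) # record index per line
  keep <- !blank
  recs <- split(lines[keep], rec_id[keep])
  recs <- recs[vapply(recs, length, 1L) > 0L]

  parse_record <- function(rec_lines, idx) {
    tag_at <- grepl("^[A-Z][A-Z0-9]{0,3}\\s{0,3}- ", rec_lines)
    if (!any(tag_at)) {
      stop(sprintf("malformed MEDLINE record %d: no tagged fields", idx), call. = FALSE)
    }
    field_id <- cumsum(tag_at)
    fields <- split(rec_lines, field_id)
    tags <- vapply(fields, function(fl) sub("^([A-Z][A-Z0-9]{0,3})\\s{0,3}- .*$", "\\1", fl[1L]), "")
    values <- vapply(fields, function(fl) {
      first <- sub("^[A-Z][A-Z0-9]{0,3}\\s{0,3}- ", "", fl[1L])
      paste(c(first, trimws(fl[-1L])), collapse = " ")
    }, "")
    vals <- setNames(values, tags)
    if (!"PMID" %in% tags || !nzchar(trimws(vals[["PMID"]]))) {
      stop(sprintf("malformed MEDLINE record %d: no PMID field", idx), call. = FALSE)
    }
    pmid <- trimws(vals[["PMID"]])
    title <- if ("TI" %in% tags) vals[["TI"]] else ""
    if (!"AB" %in% tags) {
      warning(sprintf("MEDLINE record %d (PMID %s) has no AB field; empty body used",
                      idx, pmid), call. = FALSE)
      body <- ""
    } else {
      body <- vals[["AB"]]
    }
    tibble::tibble(pmid = pmid, title = title, body = body)
  }

  out <- purrr::imap(unname(recs), function(r, i) parse_record(r, i))
  out <- dplyr::bind_rows(out)
  if (anyDuplicated(out$pmid)) {
    stop(sprintf("duplicate PMID(s) in corpus: %s",
                 paste(unique(out$pmid[duplicated(out$pmid)]), collapse = ", ")),
         call. = FALSE)
  }
  dplyr::mutate(out, display_text = paste0(.data$title, "\n", .data$body))
}

#' Write abstracts back to MEDLINE flat-file form
#'
#' Emits single-line PMID/TI/AB fields (no re-wrapping), so that
#' `read_medline(write_medline(x))` round-trips losslessly.
#'
#' @param abstracts a tibble as returned by [read_medline()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_medline <- function(abstracts, path) {
  recs <- purrr::pmap_chr(
    abstracts[, c("pmid", "title", "body")],
    function(pmid, title, body) {
      paste(c(paste0("PMID- ", pmid),
              paste0("TI  - ", title),
              if (nzchar(body)) paste0("AB  - ", body)),
            collapse = "\n")
    }
  )
  readr::write_lines(paste(recs, collapse = "\n\n"), path)
  invisible(path)
}

#' Read the gold-standard relation table
#'
#' Tab-separated with header columns `pmid`, `entrez_id`, `level`, `wild`,
#' `mutant`, `position`, `flags`. `flags` is a comma-joined subset of
#' `noncoding,nonhuman` (empty for ordinary coding human relations). Rows
#' whose position does not parse as an integer are rejected with a warning
#' naming the row.
#'
#' @param path path to the gold TSV (plain or gzip)
#' @return a tibble with one row per gold relation; `flags` is a list-column
#'   of character vectors
#' @export
read_gold <- function(path) {
  g <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                       progress = FALSE)
  required <- c("pmid", "entrez_id", "level", "wild", "mutant", "position", "flags")
  missing <- setdiff(required, names(g))
  if (length(missing)) {
    stop(sprintf("gold table is missing required column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  pos <- suppressWarnings(as.integer(g$position))
  bad <- which(is.na(pos) & !is.na(g$position))
  if (length(bad)) {
    warning(sprintf("gold rows with unparseable position rejected: %s",
                    paste(bad, collapse = ", ")), call. = FALSE)
    g <- g[-bad, , drop = FALSE]
    pos <- pos[-bad]
  }
  g$position <- pos
  g$flags <- lapply(ifelse(is.na(g$flags), "", g$flags), function(f) {
    f <- trimws(strsplit(f, ",", fixed = TRUE)[[1L]])
    f[nzchar(f)]
  })
  bad_level <- !g$level %in% c("nucleotide", "protein")
  if (any(bad_level)) {
    stop(sprintf("gold rows with unknown level: %s",
                 paste(which(bad_level), collapse = ", ")), call. = FALSE)
  }
  noncoding <- vapply(g$flags, function(f) "noncoding" %in% f, TRUE)
  if (any(g$wild == g$mutant)) {
    warning("gold rows where wild == mutant retained but suspect: ",
            paste(which(g$wild == g$mutant), collapse = ", "), call. = FALSE)
  }
  if (any(g$position < 1L & !noncoding, na.rm = TRUE)) {
    warning("gold rows with position < 1 not flagged noncoding: ",
            paste(which(g$position < 1L & !noncoding), collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(g)
}

#' @rdname read_gold
#' @param gold a gold tibble as returned by [read_gold()]
#' @export
write_gold <- function(gold, path) {
  out <- gold
  out$flags <- vapply(gold$flags, paste, "", collapse = ",")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read and write crowd judgment records
#'
#' CSV with columns `worker_id`, `item_id`, `response` (one of `YES`, `NO`,
#' `INCONSISTENT`), `timestamp`, `is_control`, and optional `control_truth`
#' (`YES`/`NO`, empty on non-control rows). A write followed by a read
#' returns an identical tibble.
#'
#' @param path path to a judgments CSV (plain or gzip)
#' @return a tibble of judgments
#' @export
read_judgments <- function(path) {
  j <- readr::read_csv(path, col_types = readr::cols(
    worker_id = readr::col_character(),
    item_id = readr::col_character(),
    response = readr::col_character(),
    timestamp = readr::col_double(),
    is_control = readr::col_logical(),
    .default = readr::col_character()
  ), progress = FALSE)
  required <- c("worker_id", "item_id", "response", "timestamp", "is_control")
  missing <- setdiff(required, names(j))
  if (length(missing)) {
    stop(sprintf("judgments file is missing required column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  check_responses(j$response)
  if (!"control_truth" %in% names(j)) {
    j$control_truth <- NA_character_
  } else {
    j$control_truth[!is.na(j$control_truth) & !nzchar(j$control_truth)] <- NA_character_
    bad <- !is.na(j$control_truth) & !j$control_truth %in% c("YES", "NO")
    if (any(bad)) {
      stop(sprintf("unknown control_truth token at row(s) %s",
                   paste(which(bad), collapse = ", ")), call. = FALSE)
    }
  }
  tibble::as_tibble(j)
}

#' @rdname read_judgments
#' @param judgments a judgments tibble
#' @export
write_judgments <- function(judgments, path) {
  readr::write_csv(judgments, path, na = "", progress = FALSE)
  invisible(path)
}

#' Read and write stand-off entity annotations
#'
#' PubTator-style tab-separated interchange with header columns `pmid`,
#' `start`, `end`, `surface`, `entity_class` (`gene` or `mutation`) and
#' `concept_key` (an EntrezGene id, or a serialized mutation triple such as
#' `protein|R|117|H`). Offsets are 0-based half-open over `display_text`.
#'
#' @param path path to a stand-off TSV (plain or gzip)
#' @return a tibble of annotations
#' @export
read_standoff <- function(path) {
  a <- readr::read_tsv(path, col_types = readr::cols(
    pmid = readr::col_character(),
    start = readr::col_integer(),
    end = readr::col_integer(),
    surface = readr::col_character(),
    entity_class = readr::col_character(),
    concept_key = readr::col_character()
  ), progress = FALSE)
  required <- c("pmid", "start", "end", "surface", "entity_class", "concept_key")
  missing <- setdiff(required, names(a))
  if (length(missing)) {
    stop(sprintf("stand-off file is missing required column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  bad <- !a$entity_class %in% c("gene", "mutation")
  if (any(bad)) {
    stop(sprintf("unknown entity_class at row(s) %s",
                 paste(which(bad), collapse = ", ")), call. = FALSE)
  }
  tibble::as_tibble(a)
}

#' @rdname read_standoff
#' @param annotations a stand-off tibble
#' @export
write_standoff <- function(annotations, path) {
  readr::write_tsv(annotations, path, progress = FALSE)
  invisible(path)
}

#' Check stand-off annotations against their abstracts
#'
#' Enforces the slice invariant: `0 <= start < end <= nchar(display_text)`
#' and `surface` equals the display-text slice at `[start, end)`.
#'
#' @param annotations a stand-off tibble
#' @param abstracts an abstracts tibble from [read_medline()]
#' @return `annotations` invisibly; errors name the offending rows
#' @export
validate_standoff <- function(annotations, abstracts) {
  idx <- match(annotations$pmid, abstracts$pmid)
  if (anyNA(idx)) {
    stop(sprintf("stand-off rows for unknown pmid(s): %s",
                 paste(which(is.na(idx)), collapse = ", ")), call. = FALSE)
  }
  text <- abstracts$display_text[idx]
  n <- nchar(text)
  bad_span <- annotations$start < 0L | annotations$start >= annotations$end |
    annotations$end > n
  got <- slice_text(text, annotations$start, annotations$end)
  bad_slice <- !bad_span & got != annotations$surface
  bad <- which(bad_span | bad_slice)
  if (length(bad)) {
    stop(sprintf("stand-off slice mismatch at row(s) %s",
                 paste(head(bad, 10L), collapse = ", ")), call. = FALSE)
  }
  invisible(annotations)
}

# Turn a mentions list-column (tibbles with start/end/surface) plus concept
# keys into a flat stand-off tibble.
concepts_to_standoff <- function(pmid, concept_key, mentions, entity_class) {
  rows <- purrr::pmap(list(pmid, concept_key, mentions), function(p, k, m) {
    tibble::tibble(pmid = p, start = m$start, end = m$end, surface = m$surface,
                   entity_class = entity_class, concept_key = k)
  })
  dplyr::bind_rows(rows)
}
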