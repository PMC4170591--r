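#' @importFrom rlang .data %||%
#' @importFrom stats rbeta rbinom runif setNames
#' @importFrom utils head combn
NULL

# All stand-off offsets are 0-based half-open over display_text, counted in
# Unicode code points (R character semantics, not bytes).

#' Find all matches of a Perl regex in one string
#'
#' Low-level matcher used by the mutation and gene taggers. Returns one row
#' per match with 0-based half-open offsets plus a column per named capture
#' group (NA where the group did not participate).
#'
#' @param text a length-1 character string
#' @param pattern a PCRE pattern, possibly with named groups
#' @param ignore_case match case-insensitively?
#' @return a tibble with columns `start`, `end`, `surface` and one column per
#'   named capture group
#' @keywords internal
regex_find <- function(text, pattern, ignore_case = FALSE) {
  stopifnot(is.character(text), length(text) == 1L)
  empty <- tibble::tibble(start = integer(), end = integer(), surface = character())
  if (is.na(text) || !nzchar(text)) return(empty)
  m <- gregexpr(pattern, text, perl = TRUE, ignore.case = ignore_case)[[1L]]
  if (m[1L] == -1L) return(empty)
  start1 <- as.integer(m)
  len <- attr(m, "match.length")
  out <- tibble::tibble(
    start = start1 - 1L,
    end = start1 - 1L + len,
    surface = substring(text, start1, start1 + len - 1L)
  )
  cs <- attr(m, "capture.start")
  if (!is.null(cs) && length(cs)) {
    cl <- attr(m, "capture.length")
    cn <- attr(m, "capture.names")
    for (j in seq_along(cn)) {
      if (!nzchar(cn[j])) next
      val <- ifelse(
        cs[, j] > 0L,
        substring(text, cs[, j], cs[, j] + cl[, j] - 1L),
        NA_character_
      )
      out[[cn[j]]] <- unname(val)
    }
  }
  out
}

#' Resolve overlapping matches longest-first, leftmost-first
#'
#' Greedy selection: longer spans beat shorter, earlier starts beat later,
#' and `priority` (lower wins) breaks remaining ties.
#'
#' @param df a tibble with integer columns `start`, `end` and `priority`
#' @return the non-overlapping subset, ordered by `start`
#' @keywords internal
resolve_overlaps <- function(df) {
  if (nrow(df) == 0L) return(df)
  ord <- order(-(df$end - df$start), df$start, df$priority)
  df <- df[ord, , drop = FALSE]
  keep <- logical(nrow(df))
  taken_s <- integer(0)
  taken_e <- integer(0)
  for (i in seq_len(nrow(df))) {
    s <- df$start[i]
    e <- df$end[i]
    if (!any(s < taken_e & e > taken_s)) {
      keep[i] <- TRUE
      taken_s <- c(taken_s, s)
      taken_e <- c(taken_e, e)
    }
  }
  df <- df[keep, , drop = FALSE]
  df[order(df$start), , drop = FALSE]
}

# Deduplicated mention spans sorted by start offset.
mention_tibble <- function(start, end, surface) {
  m <- dplyr::distinct(tibble::tibble(start = start, end = end, surface = surface))
  m[order(m$start), , drop = FALSE]
}

# Slice display_text with 0-based half-open offsets.
slice_text <- function(text, start, end) {
  substring(text, start + 1L, end)
}

# Ratio rounding used in reports: ratios to 3 decimals, percents to 1 decimal.
round3 <- function(x) round(x, 3)
pct1 <- function(x) round(100 * x, 1)

# Money is displayed truncated to the cent (the convention of the cost
# tables this package reports in).
floor_cents <- function(x) floor(x * 100 + 1e-9) / 100

# 32-bit FNV-1a over a string, returned as 8 hex digits. Used for provenance
# hashes of run configs. h is held in a double < 2^32; xor only ever touches
# the low byte (b < 256), so it is computed exactly on the low byte alone.
fnv1a_hex <- function(s) {
  bytes <- as.integer(charToRaw(enc2utf8(paste(s, collapse = "\n"))))
  h <- 2166136261
  prime <- 16777619
  two32 <- 4294967296
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * prime + ((hi * prime) %% 65536) * 65536) %% two32
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# Validate a response vector against the three allowed tokens.
check_responses <- function(response, context = "response") {
  ok <- response %in% c("YES", "NO", "INCONSISTENT")
  if (!all(ok)) {
    bad <- which(!ok)
    stop(sprintf(
      "unknown %s token(s) %s at row(s) %s",
      context,
      paste(unique(response[bad]), collapse = ", "),
      paste(head(bad, 5L), collapse = ", ")
    ), call. = FALSE)
  }
  invisible(response)
}

# Derive a child seed from a base seed; kept below 2^31.
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483587)
}
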