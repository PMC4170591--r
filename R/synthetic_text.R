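# Synthetic text generators.
#
# These build tiny corpora with a known ledger of planted entities, so the
# extractors can be scored against an exact oracle. The sentences use the
# surface-form templates the mutation patterns are designed for; they do
# not emulate the full messiness of real abstracts (hedging, coordination,
# tables flattened into prose), so extractor recall measured here is an
# upper bound on real-text recall.

#' Generate mutation sentences with a known triple ledger
#'
#' Each sentence plants exactly one point mutation drawn from one of the
#' package's surface-form templates (HGVS-like nucleotide substitutions,
#' one- and three-letter protein substitutions, "X to Y at position N"
#' phrasings, and a nonlocal "substitution of X for Y ... codon N" form).
#' The return value carries the planted triple per sentence, the oracle for
#' extractor recall tests.
#'
#' @param n number of sentences
#' @param seed integer RNG seed
#' @return a tibble: `pmid`, `title`, `body`, `display_text`, `level`,
#'   `wild`, `mutant`, `position`, `template`
#' @export
synth_mutation_corpus <- function(n = 200L, seed = 1L) {
  aa3 <- names(AA3_TO_1)
  withr::with_seed(seed, {
    rows <- purrr::map(seq_len(n), function(i) {
      template <- sample(c("hgvs_c", "aa3_spaced", "aa1_compact", "nt_to_at",
                           "p_dot", "subst_for"), 1L)
      pos <- sample(1:2000, 1L)
      if (template %in% c("hgvs_c", "nt_to_at")) {
        level <- "nucleotide"
        pair <- sample(NT, 2L)
      } else {
        level <- "protein"
        pair <- sample(AA1, 2L)
      }
      wild <- pair[1L]
      mutant <- pair[2L]
      w3 <- aa3[match(wild, AA1)]
      m3 <- aa3[match(mutant, AA1)]
      body <- switch(
        template,
        hgvs_c = sprintf("Sequencing revealed the c.%d%s>%s variant in the index family.",
                         pos, wild, mutant),
        aa3_spaced = sprintf("The %s %d %s substitution segregated with disease.",
                             w3, pos, m3),
        aa1_compact = sprintf("Carriers of %s%d%s showed reduced enzyme activity.",
                              wild, pos, mutant),
        nt_to_at = sprintf("We observed a change of %s to %s at position %d in affected individuals.",
                           wild, mutant, pos),
        p_dot = sprintf("The pathogenic allele p.%s%d%s was absent from controls.",
                        wild, pos, mutant),
        subst_for = sprintf("This allele leads to the substitution of %s for %s at codon %d.",
                            m3, w3, pos)
      )
      tibble::tibble(
        pmid = sprintf("S%04d", i),
        title = sprintf("Synthetic mutation report %d", i),
        body = body,
        level = level, wild = wild, mutant = mutant, position = pos,
        template = template
      )
    })
  })
  out <- dplyr::bind_rows(rows)
  dplyr::mutate(out, display_text = paste0(.data$title, "\n", .data$body),
                .after = "body")
}

#' Generate a gene-tagging abstract with planted names and decoy abbreviations
#'
#' Builds one synthetic abstract containing `k` planted lexicon gene names
#' (each also introduced via a long-form/short-form definition) and `j`
#' decoy abbreviations whose short form is a lexicon symbol but whose long
#' form is not a human gene name. A correct tagger plus abbreviation filter
#' recovers exactly the planted ids.
#'
#' @param planted tibble with `name`, `long_form`, `entrez_id` of genes to
#'   plant (short symbol plus its legitimate long form)
#' @param decoys tibble with `name`, `long_form` of decoy abbreviations
#'   (symbols that collide with lexicon entries)
#' @return a one-row abstracts tibble
#' @export
synth_gene_abstract <- function(planted, decoys) {
  sentences <- c(
    purrr::pmap_chr(planted, function(name, long_form, entrez_id, ...) {
      sprintf("Variants affecting %s (%s) were genotyped.", long_form, name)
    }),
    purrr::pmap_chr(decoys, function(name, long_form, ...) {
      sprintf("Reporter assays used %s (%s) constructs.", long_form, name)
    })
  )
  body <- paste(sentences, collapse = " ")
  tibble::tibble(
    pmid = "G0001",
    title = "Synthetic gene tagging fixture",
    body = body,
    display_text = paste0("Synthetic gene tagging fixture", "\n", body)
  )
}
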