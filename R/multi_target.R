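#' Count occurrences of a guide site in a genome
#'
#' A site occurs wherever the protospacer matches (exactly, or within
#' `max_mismatches`) immediately followed 3' by a PAM-matching trimer, on
#' either strand.  `N` in the genome never satisfies a protospacer base or a
#' PAM position.
#'
#' @param protospacer guide protospacer (concrete A/C/G/T).
#' @param pam guide PAM as observed (used only for its length; matching is
#'   against `pam_pattern`).
#' @param genome genome residues (single string) or a one-row tibble with a
#'   `residues` column.
#' @param region optional `c(start, end)` 1-based inclusive forward-strand
#'   coordinates restricting the search (e.g. a gene's CDS).
#' @param pam_pattern IUPAC PAM pattern, default `"NGG"`.
#' @param max_mismatches protospacer mismatches tolerated, default 0
#'   (the strictest reading of "targets the same region").
#' @return integer occurrence count (both strands).
#' @export
guide_occurrences <- function(protospacer, pam, genome, region = NULL,
                              pam_pattern = "NGG", max_mismatches = 0) {
  if (is.data.frame(genome)) genome <- genome$residues[1]
  subject <- if (is.null(region)) genome else str_sub(genome, region[1], region[2])
  plen <- nchar(pam)
  count_strand <- function(s) {
    hits <- Biostrings::matchPattern(
      Biostrings::DNAString(protospacer), Biostrings::DNAString(s),
      max.mismatch = max_mismatches, with.indels = FALSE, fixed = TRUE
    )
    ends <- BiocGenerics::end(hits)
    ends <- ends[ends + plen <= nchar(s)]
    sum(vapply(ends, function(e) {
      tri <- str_sub(s, e + 1L, e + plen)
      !grepl("N", tri, fixed = TRUE) && iupac_match(tri, pam_pattern)
    }, logical(1)))
  }
  count_strand(subject) + count_strand(reverse_complement(subject))
}

#' Is a guide site present in a genome?
#'
#' Boolean wrapper around [guide_occurrences()] (at least one occurrence);
#' proviral targets are typically multi-copy, so counts are reported
#' separately by [presence_matrix()].
#'
#' @inheritParams guide_occurrences
#' @return `TRUE` iff the site occurs at least once.
#' @export
guide_present <- function(protospacer, pam, genome, region = NULL,
                          pam_pattern = "NGG", max_mismatches = 0) {
  guide_occurrences(protospacer, pam, genome, region, pam_pattern, max_mismatches) > 0
}

#' Guide-by-genome presence matrix
#'
#' For every distinct guide in a design table, decides presence/absence in
#' every panel genome under one uniform matching rule ([guide_present()]),
#' and adds occurrence counts and an `all_present` summary.  When the
#' guide's gene is annotated in a panel entry the search is restricted to
#' that CDS (the design tables are organised per gene); otherwise the whole
#' genome is searched.
#'
#' @param design a design table from [design_stop_guides()] (or any tibble
#'   with `gene`, `protospacer`, `pam` columns; extra columns are carried).
#' @param panel a [genome_panel()].
#' @param pam_pattern IUPAC PAM pattern, default `"NGG"`.
#' @param max_mismatches protospacer mismatches tolerated, default 0.
#' @param search `"gene"` (default) restricts to the annotated CDS,
#'   `"genome"` searches the full sequence.
#' @return a `presence_matrix` tibble: the deduplicated design rows (minus
#'   the per-genome `label` column), one `o`/`x` column per genome label,
#'   one `<label>_n` occurrence-count column, and `all_present`.
#' @export
presence_matrix <- function(design, panel, pam_pattern = "NGG",
                            max_mismatches = 0, search = c("gene", "genome")) {
  search <- match.arg(search)
  labels <- panel$genomes$label
  guides <- design |>
    distinct(.data$gene, .data$protospacer, .data$pam, .keep_all = TRUE) |>
    select(-dplyr::any_of("label"))
  if (nrow(guides) == 0) {
    res <- guides
    for (lab in labels) { res[[lab]] <- character(); res[[paste0(lab, "_n")]] <- integer() }
    res$all_present <- logical()
    return(structure(res, class = c("presence_matrix", class(res)), labels = labels))
  }
  for (lab in labels) {
    g <- panel$genomes$residues[panel$genomes$label == lab]
    counts <- vapply(seq_len(nrow(guides)), function(i) {
      region <- NULL
      if (search == "gene") {
        r <- panel$regions[panel$regions$label == lab &
                           panel$regions$gene == guides$gene[i], ]
        if (nrow(r) > 0) region <- c(r$start[1], r$end[1])
      }
      guide_occurrences(guides$protospacer[i], guides$pam[i], g, region,
                        pam_pattern, max_mismatches)
    }, integer(1))
    guides[[lab]] <- if_else(counts > 0, "o", "x")
    guides[[paste0(lab, "_n")]] <- counts
  }
  guides$all_present <- rowSums(as.matrix(guides[, labels, drop = FALSE]) == "o") == length(labels)
  structure(guides, class = c("presence_matrix", class(guides)), labels = labels)
}

#' @method tidy presence_matrix
#' @export
tidy.presence_matrix <- function(x, ...) {
  labels <- attr(x, "labels")
  as_tibble(x) |>
    select("gene", "protospacer", "pam", all_of(labels)) |>
    tidyr::pivot_longer(all_of(labels), names_to = "genome", values_to = "call") |>
    mutate(present = .data$call == "o")
}
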