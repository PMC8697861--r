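#' Normalise nucleotide residues
#'
#' Uppercases, maps RNA `U` to `T`, and replaces any symbol outside
#' `{A,C,G,T}` by `N` (with a warning naming the offending symbols).
#'
#' @param residues character vector of nucleotide strings.
#' @return character vector over the alphabet `{A,C,G,T,N}`.
#' @export
normalize_residues <- function(residues) {
  x <- chartr("u", "t", str_to_upper(residues))
  x <- chartr("U", "T", x)
  bad <- unique(unlist(stringr::str_extract_all(x, "[^ACGTN]")))
  if (length(bad) > 0) {
    warn(paste0(
      "replacing non-ACGT symbol(s) ", paste(bad, collapse = ", "), " with N"
    ))
    x <- stringr::str_replace_all(x, "[^ACGTN]", "N")
  }
  x
}

#' Read a FASTA file into a tibble
#'
#' Records are normalised on read: residues are uppercased, `U` becomes `T`,
#' and anything outside `{A,C,G,T}` becomes `N` (warned).
#'
#' @param path path to a (optionally gzipped) FASTA file.
#' @return a tibble with columns `id` (full header line, `>` stripped) and
#'   `residues`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path), class = "crisprstop_format_error")
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = "fasta"),
    error = function(e) abort(paste0("not readable as FASTA: ", path, " (", conditionMessage(e), ")"),
                              class = "crisprstop_format_error")
  )
  if (length(set) == 0) abort(paste0("empty FASTA file: ", path), class = "crisprstop_format_error")
  res <- as.character(set)
  if (any(nchar(res) == 0)) {
    abort(paste0("FASTA record with empty sequence in ", path), class = "crisprstop_format_error")
  }
  tibble(id = names(set), residues = normalize_residues(unname(res)))
}

#' Write sequences to FASTA
#'
#' @param sequences a tibble with columns `id` and `residues` (as returned by
#'   [read_fasta()]).
#' @param path output path.
#' @param width line-wrap width, default 60 columns.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path, width = 60) {
  stopifnot(all(c("id", "residues") %in% names(sequences)))
  set <- Biostrings::DNAStringSet(sequences$residues)
  names(set) <- sequences$id
  Biostrings::writeXStringSet(set, path, format = "fasta", width = width)
  invisible(path)
}

#' Reverse complement
#'
#' Watson-Crick complement with `N` mapped to `N`, order reversed.
#'
#' @param residues character vector over `{A,C,G,T,N}` (IUPAC ambiguity codes
#'   are also complemented correctly).
#' @return character vector of the same lengths.
#' @export
reverse_complement <- function(residues) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(residues)))
}

#' Translate a coding sequence
#'
#' Standard genetic code; the three stop codons emit `*` and translation
#' continues to the end of the sequence (premature-stop detection is the
#' caller's concern). Codons containing `N` translate to `X`.
#'
#' @param residues character vector of in-frame coding sequences; each length
#'   must be a multiple of 3.
#' @return character vector of amino-acid strings (`*` = stop, `X` = unknown).
#' @export
translate_cds <- function(residues) {
  if (any(nchar(residues) %% 3 != 0)) {
    abort("coding sequence length must be a multiple of 3", class = "crisprstop_contract_error")
  }
  as.character(Biostrings::translate(
    Biostrings::DNAStringSet(residues),
    if.fuzzy.codon = "X", no.init.codon = TRUE
  ))
}

#' Assemble a genome panel
#'
#' A panel bundles homologous genomes (e.g. proviral subtypes) with their
#' annotated coding regions, the unit that guide design and presence calls
#' operate on.
#'
#' @param genomes tibble with columns `label` and `residues`; labels unique.
#' @param regions tibble with columns `label`, `gene`, `start`, `end`,
#'   `strand` (1-based inclusive forward-strand coordinates; CDS length must
#'   be a multiple of 3).
#' @return an object of class `genome_panel`.
#' @export
genome_panel <- function(genomes, regions) {
  stopifnot(all(c("label", "residues") %in% names(genomes)),
            all(c("label", "gene", "start", "end", "strand") %in% names(regions)))
  if (anyDuplicated(genomes$label)) abort("panel labels must be unique")
  genomes <- as_tibble(genomes)
  regions <- as_tibble(regions)
  lens <- stats::setNames(nchar(genomes$residues), genomes$label)
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    if (!r$label %in% genomes$label) abort(paste0("region label not in panel: ", r$label))
    if (!(r$start >= 1 && r$start <= r$end && r$end <= lens[[r$label]])) {
      abort(paste0("coding region out of range: ", r$label, "/", r$gene))
    }
    if ((r$end - r$start + 1) %% 3 != 0) {
      abort(paste0("coding region length not a multiple of 3: ", r$label, "/", r$gene))
    }
    if (!r$strand %in% c("+", "-")) abort("strand must be '+' or '-'")
  }
  structure(list(genomes = genomes, regions = regions), class = "genome_panel")
}

#' @export
print.genome_panel <- function(x, ...) {
  cat("<genome_panel> ", nrow(x$genomes), " genome(s), ",
      nrow(x$regions), " coding region(s)\n", sep = "")
  info <- x$regions |>
    group_by(.data$label) |>
    summarise(genes = paste(.data$gene, collapse = ","), .groups = "drop")
  info$length <- nchar(x$genomes$residues)[match(info$label, x$genomes$label)]
  print(as.data.frame(info), row.names = FALSE)
  invisible(x)
}

#' Extract a coding sequence from a panel
#'
#' Returns the spliced-forward (coding-orientation) CDS for one gene of one
#' genome; minus-strand regions are reverse-complemented.
#'
#' @param panel a [genome_panel()].
#' @param label genome label.
#' @param gene gene name.
#' @return the coding sequence as a single string.
#' @export
cds_sequence <- function(panel, label, gene) {
  r <- panel$regions[panel$regions$label == label & panel$regions$gene == gene, ]
  if (nrow(r) == 0) {
    abort(paste0("gene not annotated in panel entry ", label, ": ", gene),
          class = "crisprstop_lookup_error")
  }
  g <- panel$genomes$residues[panel$genomes$label == label]
  s <- str_sub(g, r$start[1], r$end[1])
  if (r$strand[1] == "-") s <- reverse_complement(s)
  s
}
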