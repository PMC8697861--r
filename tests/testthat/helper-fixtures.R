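# In-code fixtures shared across test files.

# A CDS of inert ATT filler with one editable codon planted so that its C
# sits in the default editing window of an NGG guide:
#   sense codon (CAA/CAG/CGA) at codon k, AGG PAM at codon k+6;
#   antisense TGG at codon k with CCA (minus-strand AGG) at codon k-6.
# ATT filler contains no C, no GG and no CC, so the planted site is the
# only editable guide on either strand.
planted_cds <- function(codon, k = 8, n_codons = 100) {
  codons <- rep("ATT", n_codons)
  if (codon %in% c("CAA", "CAG", "CGA")) {
    stopifnot(k >= 2, k + 6 < n_codons)
    codons[k] <- codon
    codons[k + 6] <- "AGG"
  } else if (codon == "TGG") {
    stopifnot(k > 7, 3 * k + 2 <= 3 * n_codons)
    codons[k] <- "TGG"
    codons[k - 6] <- "CCA"
  } else {
    stop("unsupported codon")
  }
  codons[1] <- "ATG"
  codons[n_codons] <- "TAA"
  paste(codons, collapse = "")
}

# A CDS embedding a full 23-nt target site so its leftmost base lands at
# `position` (1-based), padded with ATT filler; the caller is responsible
# for picking positions whose editable codon is in frame.
embedded_cds <- function(site, position, total = NULL) {
  stopifnot(nchar(site) == 23)
  prefix_len <- position - 1
  prefix <- strrep("ATT", ceiling(prefix_len / 3))
  prefix <- substr(prefix, nchar(prefix) - prefix_len + 1, nchar(prefix))
  body <- paste0(prefix, site)
  total <- total %||% (3 * ceiling((nchar(body) + 30) / 3))
  pad <- total - nchar(body) - 3
  stopifnot(pad >= 0)
  # poly-T tail: no codon overlapping it can be a stop (those end in A/G)
  paste0(body, strrep("T", pad), "TAA")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One-gene genome panel wrapping the given coding sequences directly.
cds_panel <- function(cds_list, gene = "gag") {
  labs <- names(cds_list) %||% paste0("G", seq_along(cds_list))
  genome_panel(
    tibble::tibble(label = labs, residues = unlist(unname(cds_list))),
    tibble::tibble(label = labs, gene = gene, start = 1L,
                   end = nchar(cds_list[[1]]), strand = "+")
  )
}

# Minimal GenBank flat file writer for reader tests.
write_genbank_fixture <- function(path, residues, cds = list()) {
  lines <- c(sprintf("LOCUS       TESTREC    %d bp    DNA    linear  28-SEP-2026",
                     nchar(residues)),
             "DEFINITION  synthetic test record.",
             "FEATURES             Location/Qualifiers",
             sprintf("     source          1..%d", nchar(residues)))
  for (f in cds) {
    lines <- c(lines,
               sprintf("     CDS             %s", f$location),
               sprintf("                     /gene=\"%s\"", f$gene),
               sprintf("                     /product=\"%s protein\"", f$gene))
  }
  lines <- c(lines, "ORIGIN")
  starts <- seq(1, nchar(residues), by = 60)
  for (s in starts) {
    chunk <- substr(residues, s, min(s + 59, nchar(residues)))
    tens <- substring(chunk, seq(1, nchar(chunk), by = 10),
                      pmin(seq(10, nchar(chunk) + 9, by = 10), nchar(chunk)))
    lines <- c(lines, sprintf("%9d %s", s, paste(tens, collapse = " ")))
  }
  writeLines(c(lines, "//"), path)
  path
}

# Amplicon around a "+" guide site: flank + protospacer+PAM + flank.
make_test_amplicon <- function(protospacer = "TTCAGGTTAAGAAGGGACCT", pam = "TGG",
                               flank = 80, seed = 303) {
  withr::with_seed(seed, {
    amp <- paste0(random_dna(flank), protospacer, pam, random_dna(flank))
  })
  amplicon_reference(amp, protospacer, flank + 1L, "+")
}
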