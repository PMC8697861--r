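# IUPAC nucleotide codes mapped to the set of concrete bases they accept.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

is_iupac <- function(pattern) {
  all(strsplit(pattern, "")[[1]] %in% names(IUPAC_SETS))
}

# TRUE iff `seq` (concrete A/C/G/T only) matches the IUPAC `pattern` of the
# same length.  An N (or any other ambiguity) on the *sequence* side never
# matches: an unread base cannot be confirmed as PAM-compatible.
iupac_match <- function(seq, pattern) {
  if (nchar(seq) != nchar(pattern)) return(FALSE)
  sb <- strsplit(seq, "")[[1]]
  pb <- strsplit(pattern, "")[[1]]
  all(vapply(seq_along(sb), function(i) sb[i] %in% IUPAC_SETS[[pb[i]]], logical(1)))
}

# Regex character classes for an IUPAC pattern, matching concrete bases only.
iupac_regex <- function(pattern) {
  paste0(vapply(strsplit(pattern, "")[[1]], function(cc) {
    set <- IUPAC_SETS[[cc]]
    if (length(set) == 1L) set else paste0("[", paste(set, collapse = ""), "]")
  }, character(1)), collapse = "")
}

# Round half away from zero (so 0.125 -> 0.13 at 2 digits), the convention
# used for reported percentages.
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

fmt_pct <- function(x) sprintf("%.2f", round_half_up(x, 2))

STOP_CODONS <- c("TAA", "TAG", "TGA")
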