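# Independent brute-force oracles.  These deliberately share no code with
# the package internals they check.

# Gotoh affine-gap global alignment score: match +1, mismatch -1, a gap of
# length k costs 5 + k, N scores 0 against anything, end gaps penalised.
nw_score_oracle <- function(a, b, match = 1, mismatch = -1,
                            gap_open = 5, gap_ext = 1) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  sub <- function(p, q) if (p == "N" || q == "N") 0 else if (p == q) match else mismatch
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)  # gap in y (x aligned to gap)
  Iy <- matrix(NEG, n + 1, m + 1)  # gap in x
  M[1, 1] <- 0
  for (i in 2:(n + 1)) Ix[i, 1] <- -(gap_open + gap_ext * (i - 1))
  for (j in 2:(m + 1)) Iy[1, j] <- -(gap_open + gap_ext * (j - 1))
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      M[i, j] <- sub(x[i - 1], y[j - 1]) +
        max(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1])
      Ix[i, j] <- max(M[i - 1, j] - gap_open - gap_ext, Ix[i - 1, j] - gap_ext)
      Iy[i, j] <- max(M[i, j - 1] - gap_open - gap_ext, Iy[i, j - 1] - gap_ext)
    }
  }
  max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}

# Codon-table translation via straight lookup.
translate_oracle <- function(cds) {
  stopifnot(nchar(cds) %% 3 == 0)
  gc <- Biostrings::GENETIC_CODE
  starts <- seq(1, nchar(cds), by = 3)
  codons <- substring(cds, starts, starts + 2)
  aa <- unname(gc[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

revcomp_oracle <- function(s) {
  ch <- rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]])
  paste(ch, collapse = "")
}

# Protospacer/PAM enumeration by checking every offset on both strands.
enumerate_oracle <- function(s, L = 20, pam = "NGG") {
  iupac <- list(A = "A", C = "C", G = "G", T = "T", N = c("A", "C", "G", "T"),
                R = c("A", "G"), Y = c("C", "T"))
  plen <- nchar(pam)
  pb <- strsplit(pam, "")[[1]]
  n <- nchar(s)
  rows <- list()
  scan <- function(seqs, dirn) {
    for (i in seq_len(nchar(seqs) - L - plen + 1)) {
      proto <- substr(seqs, i, i + L - 1)
      tri <- substr(seqs, i + L, i + L + plen - 1)
      if (grepl("N", proto) || grepl("N", tri)) next
      tch <- strsplit(tri, "")[[1]]
      if (!all(vapply(seq_len(plen), function(k) tch[k] %in% iupac[[pb[k]]], logical(1)))) next
      pos <- if (dirn == "+") i else n - (i + L + plen - 1) + 1
      rows[[length(rows) + 1]] <<- data.frame(
        protospacer = proto, pam = tri, direction = dirn, cds_position = pos)
    }
  }
  scan(s, "+")
  scan(revcomp_oracle(s), "-")
  if (length(rows) == 0) {
    return(data.frame(protospacer = character(), pam = character(),
                      direction = character(), cds_position = integer()))
  }
  out <- do.call(rbind, rows)
  out[order(out$cds_position, out$direction, out$protospacer), , drop = FALSE]
}

# Per-column recount of a pileup from the raw reference-space alignments.
pileup_oracle <- function(ref_space_strings, ref_len) {
  counts <- matrix(0L, nrow = 6, ncol = ref_len,
                   dimnames = list(c("A", "C", "G", "T", "N", "del"), NULL))
  for (s in ref_space_strings) {
    ch <- strsplit(s, "")[[1]]
    for (j in seq_len(ref_len)) {
      key <- if (ch[j] == "-") "del" else ch[j]
      counts[key, j] <- counts[key, j] + 1L
    }
  }
  counts
}

# Bare-hands FASTQ parser (4-line records).
parse_fastq_oracle <- function(path) {
  lines <- readLines(path)
  stopifnot(length(lines) %% 4 == 0)
  list(ids = sub("^@", "", lines[seq(1, length(lines), by = 4)]),
       reads = lines[seq(2, length(lines), by = 4)],
       quals = lines[seq(4, length(lines), by = 4)])
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")
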