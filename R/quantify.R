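#' Window-restricted C-to-T substitution from a pileup
#'
#' Maps the editing window (16-19 bp upstream of the PAM by default) onto
#' amplicon columns, strand-aware, and computes the headline statistic: the
#' percentage of aligned, window-indel-free reads whose designated target C
#' carries the conversion (C>T on a "+" guide; G>A on the reference of a
#' "-" guide).  Reads with an indel overlapping the window +/- 5 bp are
#' excluded from the denominator and reported separately (alignment near an
#' indel is ambiguous at single-base resolution), as are reads whose target
#' base was quality-masked to N.  Per-position conversion
#' percentages are also emitted so a per-site reading of the statistic is
#' recoverable.
#'
#' @param pile a [pileup()] result.
#' @param reference the [amplicon_reference()] the reads were aligned to.
#' @param profile an [editor_profile()]; defaults to the reference's own.
#' @param n_reads_total total input reads (defaults to the alignment count,
#'   but [quantify()] passes the pre-filter total).
#' @return an object of class `substitution_table`; see [tidy()] /
#'   [glance()] methods, and `$window` for the per-window-position table.
#' @export
window_substitution <- function(pile, reference, profile = NULL,
                                n_reads_total = NULL) {
  stopifnot(inherits(pile, "pileup_counts"), inherits(reference, "amplicon_reference"))
  profile <- profile %||% reference$profile
  aln <- pile$alignments
  acc <- aln[aln$accepted, , drop = FALSE]
  L0 <- nchar(reference$residues)
  n_total <- n_reads_total %||% nrow(aln)

  ws_lo <- max(1L, min(reference$window_cols) - 5L)
  ws_hi <- min(L0, max(reference$window_cols) + 5L)
  near_win <- substr(acc$ref_space, ws_lo, ws_hi)
  has_del <- grepl("-", near_win, fixed = TRUE)
  has_ins <- vapply(acc$insertions, function(ins) {
    !is.null(ins) && nrow(ins) > 0 && any(ins$pos >= ws_lo - 1L & ins$pos <= ws_hi)
  }, logical(1))
  indel_near <- has_del | has_ins
  denom_reads <- acc[!indel_near, , drop = FALSE]
  n_denom <- nrow(denom_reads)

  ref_bases <- strsplit(reference$residues, "")[[1]]
  per_window <- tibble(
    window_offset = reference$window_offsets,
    amplicon_position = reference$window_cols,
    ref_base = ref_bases[reference$window_cols],
    is_target_c = ref_bases[reference$window_cols] == reference$conv_from
  )
  # masked (N) bases carry no information: a read with N at a column is
  # excluded from that column's denominator rather than counted unconverted
  col_stats <- function(col) {
    if (n_denom == 0) return(c(conv = 0L, eff = 0L))
    b <- substr(denom_reads$ref_space, col, col)
    c(conv = sum(b == reference$conv_to), eff = sum(b != "N"))
  }
  ws <- vapply(per_window$amplicon_position, col_stats, c(conv = 0L, eff = 0L))
  per_window$n_converted <- ws["conv", ]
  per_window$n_effective <- ws["eff", ]
  per_window$percent <- ifelse(
    per_window$is_target_c & per_window$n_effective > 0,
    100 * per_window$n_converted / per_window$n_effective, NA_real_
  )

  if (is.na(reference$target_col)) {
    inform("no cytosine in the editing window: headline percentage not applicable")
    headline <- NA_real_
    n_conv <- NA_integer_
    n_denom_eff <- n_denom
  } else {
    st <- col_stats(reference$target_col)
    n_conv <- st[["conv"]]
    n_denom_eff <- st[["eff"]]
    headline <- if (n_denom_eff > 0) 100 * n_conv / n_denom_eff else NA_real_
  }

  positions <- tibble(
    position = seq_len(L0),
    ref_base = ref_bases,
    A = pile$counts["A", ], C = pile$counts["C", ], G = pile$counts["G", ],
    T = pile$counts["T", ], N = pile$counts["N", ],
    del = pile$counts["del", ], ins = pile$counts["ins", ]
  )

  structure(list(
    positions = positions,
    window = per_window,
    window_c_to_t_percent = headline,
    n_converted = n_conv,
    n_reads_total = n_total,
    n_reads_aligned = nrow(acc),
    n_reads_rejected = sum(!aln$accepted),
    n_reads_indel_near_window = sum(indel_near),
    n_denominator = n_denom_eff,
    reference = reference,
    profile = profile,
    alignments = aln
  ), class = "substitution_table")
}

#' @export
print.substitution_table <- function(x, ...) {
  cat("<substitution_table>\n")
  cat("  reads: ", x$n_reads_total, " total, ", x$n_reads_aligned, " aligned, ",
      x$n_reads_rejected, " rejected, ", x$n_reads_indel_near_window,
      " with window-proximal indel\n", sep = "")
  if (is.na(x$window_c_to_t_percent)) {
    cat("  window C-to-T: not applicable (no window C)\n")
  } else {
    cat("  window ", x$reference$conv_from, "-to-", x$reference$conv_to,
        " substitution: ", fmt_pct(x$window_c_to_t_percent), "% (",
        x$n_converted, "/", x$n_denominator, " indel-free aligned reads)\n",
        sep = "")
  }
  wc <- x$window[x$window$is_target_c, ]
  if (nrow(wc) > 0) {
    cat("  per window C (offset: %): ",
        paste0(wc$window_offset, ": ", fmt_pct(wc$percent), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' @method tidy substitution_table
#' @export
tidy.substitution_table <- function(x, ...) x$positions

#' @method glance substitution_table
#' @export
glance.substitution_table <- function(x, ...) {
  tibble(
    window_c_to_t_percent = x$window_c_to_t_percent,
    n_reads_total = x$n_reads_total,
    n_reads_aligned = x$n_reads_aligned,
    n_reads_rejected = x$n_reads_rejected,
    n_reads_indel_near_window = x$n_reads_indel_near_window,
    n_denominator = x$n_denominator,
    n_converted = x$n_converted
  )
}

# ---- FASTQ handling ---------------------------------------------------------

read_fastq_chr <- function(path) {
  set <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE),
    error = function(e) abort(paste0("not readable as FASTQ: ", path, " (",
                                     conditionMessage(e), ")"),
                              class = "crisprstop_format_error")
  )
  list(reads = as.character(set),
       quals = as.character(S4Vectors::mcols(set)$qualities))
}

# Replace bases whose Phred+33 quality is below min_phred with N.
mask_low_quality <- function(reads, quals, min_phred = 20) {
  if (length(reads) == 0) return(list(reads = reads, n_masked = 0L))
  stopifnot(all(nchar(reads) == nchar(quals)))
  big <- charToRaw(paste(reads, collapse = ""))
  bigq <- charToRaw(paste(quals, collapse = ""))
  low <- bigq < as.raw(33L + min_phred)
  n_masked <- sum(low)
  if (n_masked > 0) {
    big[low] <- charToRaw("N")
    joined <- rawToChar(big)
    ends <- cumsum(nchar(reads))
    reads <- substring(joined, c(1L, ends[-length(ends)] + 1L), ends)
  }
  list(reads = reads, n_masked = as.integer(n_masked))
}

# Merge one read pair by 3' overlap.  Candidate overlaps are located by an
# exact 16-mer seed from the end of R1 inside the reverse-complemented R2;
# the full overlap must be >= min_overlap nt at >= min_identity.  In the
# overlap the R1 base is kept unless it is masked (N) and R2 is not.
# Returns NULL when no acceptable overlap is found.
merge_pair <- function(r1, r2_rc, min_overlap = 20, min_identity = 0.9) {
  n1 <- nchar(r1); n2 <- nchar(r2_rc)
  if (n1 < 16 || n2 < min_overlap) return(NULL)
  seed <- substr(r1, n1 - 15L, n1)
  if (grepl("N", seed, fixed = TRUE)) return(NULL)
  hit <- gregexpr(seed, r2_rc, fixed = TRUE)[[1]]
  if (hit[1] == -1) return(NULL)
  best <- NULL
  for (pos in as.integer(hit)) {
    k <- pos + 15L                     # overlap length implied by this seed hit
    if (k < min_overlap || k > n1 || k > n2) next
    a <- substr(r1, n1 - k + 1L, n1)
    b <- substr(r2_rc, 1L, k)
    mm <- sum(charToRaw(a) != charToRaw(b))
    idy <- (k - mm) / k
    if (idy >= min_identity && (is.null(best) || k > best$k)) best <- list(k = k, a = a, b = b)
  }
  if (is.null(best)) return(NULL)
  ach <- strsplit(best$a, "")[[1]]
  bch <- strsplit(best$b, "")[[1]]
  ach[ach == "N" & bch != "N"] <- bch[ach == "N" & bch != "N"]
  paste0(substr(r1, 1L, n1 - best$k), paste(ach, collapse = ""),
         substr(r2_rc, best$k + 1L, n2))
}

#' Quantify window C-to-T substitution from FASTQ reads
#'
#' The full amplicon analysis: read (optionally paired) FASTQ, mask bases
#' below Phred 20 to N, merge pairs by 3' overlap (>= 20 nt at >= 90%
#' identity; unmergeable pairs fall back to R1 alone), align every read to
#' the amplicon ([align_read()] scoring), build the [pileup()], and compute
#' the [window_substitution()] table.
#'
#' @param r1 path to the R1 (or single-end) FASTQ, optionally gzipped.
#' @param reference an [amplicon_reference()].
#' @param r2 optional path to the R2 FASTQ.
#' @param profile an [editor_profile()]; defaults to the reference's.
#' @param min_phred quality-masking threshold, default 20.
#' @param min_overlap,min_overlap_identity pair-merge acceptance rule.
#' @return a `substitution_table` whose `$run` element records the merge,
#'   masking, and alignment bookkeeping plus the scoring constants.
#' @export
quantify <- function(r1, reference, r2 = NULL, profile = NULL,
                     min_phred = 20, min_overlap = 20,
                     min_overlap_identity = 0.9) {
  fq1 <- read_fastq_chr(r1)
  m1 <- mask_low_quality(fq1$reads, fq1$quals, min_phred)
  n_masked <- m1$n_masked
  reads <- m1$reads
  n_merged <- NA_integer_
  n_r1_only <- NA_integer_
  if (!is.null(r2)) {
    fq2 <- read_fastq_chr(r2)
    if (length(fq2$reads) != length(reads)) {
      abort("R1 and R2 have different read counts", class = "crisprstop_format_error")
    }
    m2 <- mask_low_quality(fq2$reads, fq2$quals, min_phred)
    n_masked <- n_masked + m2$n_masked
    r2_rc <- reverse_complement(m2$reads)
    merged <- vapply(seq_along(reads), function(i) {
      m <- merge_pair(reads[i], r2_rc[i], min_overlap, min_overlap_identity)
      m %||% NA_character_
    }, character(1))
    n_merged <- sum(!is.na(merged))
    n_r1_only <- sum(is.na(merged))
    reads <- if_else(is.na(merged), reads, merged)
  }
  res <- quantify_reads(reads, reference, profile, n_reads_total = length(reads))
  res$run <- list(
    r1 = r1, r2 = r2, n_masked_bases = n_masked,
    n_merged = n_merged, n_r1_only = n_r1_only,
    min_phred = min_phred, min_overlap = min_overlap,
    min_overlap_identity = min_overlap_identity,
    align_match = 1, align_mismatch = -1,
    align_gap_open = -ALN_GAP_OPEN, align_gap_extend = -ALN_GAP_EXT,
    align_min_identity = ALN_MIN_IDENTITY
  )
  res
}

#' Quantify window substitution from in-memory reads
#'
#' The alignment/pileup/window core of [quantify()], for reads already in
#' memory (e.g. straight from the simulator).
#'
#' @param reads character vector of reads (A/C/G/T/N).
#' @param reference an [amplicon_reference()].
#' @param profile optional [editor_profile()].
#' @param n_reads_total reported input total, defaulting to `length(reads)`.
#' @return a `substitution_table`.
#' @export
quantify_reads <- function(reads, reference, profile = NULL,
                           n_reads_total = NULL) {
  aln <- align_reads(reads, reference)
  pile <- pileup(aln, reference)
  window_substitution(pile, reference, profile,
                      n_reads_total = n_reads_total %||% length(reads))
}

#' Top read haplotypes over the guide region
#'
#' A compact text view of the most frequent aligned read sequences across
#' the protospacer+PAM span, with per-haplotype frequencies -- the usual way
#' to eyeball what an editor did at a site.
#'
#' @param tab a `substitution_table` from [quantify()].
#' @param n number of haplotypes, default 20.
#' @param flank reference bases to show either side of the site, default 5.
#' @return tibble with `haplotype`, `count`, `percent`, `is_reference`.
#' @export
top_haplotypes <- function(tab, n = 20, flank = 5) {
  ref <- tab$reference
  aln <- tab$alignments
  if (is.null(aln)) abort("substitution_table lacks alignment detail")
  lo <- max(1L, min(c(ref$window_cols, ref$guide_start)) - flank)
  hi <- min(nchar(ref$residues),
            max(c(ref$window_cols, ref$guide_start +
                  ref$profile$protospacer_length + nchar(ref$pam) - 1L)) + flank)
  acc <- aln[aln$accepted, , drop = FALSE]
  hap <- substr(acc$ref_space, lo, hi)
  tb <- sort(table(hap), decreasing = TRUE)
  out <- tibble(
    haplotype = names(tb)[seq_len(min(n, length(tb)))],
    count = as.integer(tb[seq_len(min(n, length(tb)))])
  )
  out$percent <- 100 * out$count / nrow(acc)
  out$is_reference <- out$haplotype == substr(ref$residues, lo, hi)
  out
}
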