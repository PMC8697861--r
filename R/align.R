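# Scoring used for read-to-amplicon alignment: match +1, mismatch -1, a gap
# of length k costs 5 + k; N scores 0 against anything (masked bases are
# uninformative).  Reads under 70% identity over alignment columns are
# rejected (counted, not raised).
ALN_GAP_OPEN <- 5
ALN_GAP_EXT <- 1
ALN_MIN_IDENTITY <- 0.70

aln_submat <- function() {
  m <- matrix(-1, 5, 5, dimnames = list(c("A", "C", "G", "T", "N"),
                                        c("A", "C", "G", "T", "N")))
  diag(m) <- 1
  m["N", ] <- 0
  m[, "N"] <- 0
  m
}

#' Globally align one read to an amplicon reference
#'
#' Needleman-Wunsch global alignment (match +1, mismatch -1, gap open -5,
#' gap extend -1, end gaps penalised) of the read or its reverse complement,
#' whichever scores higher.  Alignments under 70% identity over their
#' columns are rejected.
#'
#' @param read read sequence (A/C/G/T/N; masked bases as N).
#' @param reference an [amplicon_reference()] or a bare reference string.
#' @return a list: `accepted`, `score`, `identity`, `flipped`, `ref_space`
#'   (the read projected onto reference coordinates, one character per
#'   reference position, `-` for deletion), and `insertions` (data frame of
#'   `pos` = preceding reference column, `len`).
#' @export
align_read <- function(read, reference) {
  ref <- if (inherits(reference, "amplicon_reference")) reference$residues else reference
  if (nchar(read) < 30) {
    return(list(accepted = FALSE, score = NA_real_, identity = 0,
                flipped = FALSE, ref_space = NA_character_,
                insertions = data.frame(pos = integer(), len = integer())))
  }
  m <- aln_submat()
  subj <- Biostrings::DNAString(ref)
  do_aln <- function(r) {
    Biostrings::pairwiseAlignment(
      Biostrings::DNAString(r), subj, type = "global",
      substitutionMatrix = m, gapOpening = ALN_GAP_OPEN, gapExtension = ALN_GAP_EXT
    )
  }
  a_f <- do_aln(read)
  rc <- reverse_complement(read)
  a_r <- do_aln(rc)
  flipped <- Biostrings::score(a_r) > Biostrings::score(a_f)
  a <- if (flipped) a_r else a_f
  p <- strsplit(as.character(Biostrings::alignedPattern(a)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(a)), "")[[1]]
  identity <- mean(p == s & p %in% c("A", "C", "G", "T"))
  ref_space <- paste(p[s != "-"], collapse = "")
  ins_run <- rle(s == "-")
  insertions <- data.frame(pos = integer(), len = integer())
  if (any(ins_run$values)) {
    ends <- cumsum(ins_run$lengths)
    starts <- ends - ins_run$lengths + 1L
    for (k in which(ins_run$values)) {
      preceding <- sum(s[seq_len(starts[k] - 1L)] != "-")
      insertions <- rbind(insertions,
                          data.frame(pos = max(preceding, 1L), len = ins_run$lengths[k]))
    }
  }
  list(accepted = identity >= ALN_MIN_IDENTITY,
       score = Biostrings::score(a), identity = identity, flipped = flipped,
       ref_space = ref_space, insertions = insertions)
}

# Vectorised alignment of many reads.  Reads whose length equals the
# reference and whose best ungapped orientation clears the identity
# threshold skip the dynamic program entirely; the rest (length changes,
# heavy divergence) go through align_read().
align_reads <- function(reads, reference) {
  ref <- if (inherits(reference, "amplicon_reference")) reference$residues else reference
  n <- length(reads)
  L0 <- nchar(ref)
  lens <- nchar(reads)
  ref_space <- rep(NA_character_, n)
  accepted <- logical(n)
  flipped <- logical(n)
  identity <- numeric(n)
  insertions <- vector("list", n)

  mm_vs <- function(x, template) {
    # per-read Hamming mismatches of equal-length reads against template
    big <- charToRaw(paste(x, collapse = ""))
    tmp <- rep.int(charToRaw(template), length(x))
    .colSums(big != tmp, L0, length(x))
  }
  same <- which(lens == L0)
  if (length(same) > 0) {
    mf <- mm_vs(reads[same], ref)
    mr <- mm_vs(reads[same], reverse_complement(ref))
    flip <- mr < mf
    mm <- pmin(mf, mr)
    idy <- (L0 - mm) / L0
    ok <- idy >= ALN_MIN_IDENTITY
    idx <- same[ok]
    accepted[idx] <- TRUE
    flipped[idx] <- flip[ok]
    identity[idx] <- idy[ok]
    rs <- reads[idx]
    if (any(flip[ok])) rs[flip[ok]] <- reverse_complement(rs[flip[ok]])
    ref_space[idx] <- rs
    # equal-length reads that fail ungapped identity get a real alignment
    hard <- same[!ok]
  } else {
    hard <- integer(0)
  }
  hard <- c(hard, which(lens != L0))
  if (length(hard) > 0) {
    short <- hard[lens[hard] < 30]
    hard <- setdiff(hard, short)  # sub-30-nt reads are rejected outright
  }
  if (length(hard) > 0) {
    m <- aln_submat()
    subj <- Biostrings::DNAString(ref)
    batch <- function(x) {
      Biostrings::pairwiseAlignment(
        Biostrings::DNAStringSet(x), subj, type = "global",
        substitutionMatrix = m, gapOpening = ALN_GAP_OPEN, gapExtension = ALN_GAP_EXT
      )
    }
    a_f <- batch(reads[hard])
    a_r <- batch(reverse_complement(reads[hard]))
    use_r <- Biostrings::score(a_r) > Biostrings::score(a_f)
    # aligned pattern keeps insertion columns and marks deletions with '-';
    # insertion ranges are in its coordinate system
    asc <- as.character(Biostrings::aligned(Biostrings::pattern(a_f)))
    asc_r <- as.character(Biostrings::aligned(Biostrings::pattern(a_r)))
    asc[use_r] <- asc_r[use_r]
    ins_f <- Biostrings::insertion(Biostrings::indel(a_f))
    ins_r <- Biostrings::insertion(Biostrings::indel(a_r))
    for (j in seq_along(hard)) {
      i <- hard[j]
      x <- asc[j]
      ir <- if (use_r[j]) ins_r[[j]] else ins_f[[j]]
      ins <- NULL
      if (length(ir) > 0) {
        st <- BiocGenerics::start(ir)
        wd <- BiocGenerics::width(ir)
        o <- order(st)
        st <- st[o]; wd <- wd[o]
        prior <- cumsum(c(0L, wd[-length(wd)]))
        ins <- data.frame(pos = pmax(st - 1L - prior, 1L), len = wd)
        # strip insertion columns (right to left so coordinates stay valid)
        for (k in rev(seq_along(st))) {
          x <- paste0(substr(x, 1L, st[k] - 1L), substr(x, st[k] + wd[k], nchar(x)))
        }
      }
      mm <- sum(charToRaw(x) != charToRaw(ref))
      idy <- (L0 - mm) / nchar(asc[j])
      flipped[i] <- use_r[j]
      identity[i] <- idy
      accepted[i] <- idy >= ALN_MIN_IDENTITY
      if (!accepted[i]) next
      ref_space[i] <- x
      if (!is.null(ins)) insertions[[i]] <- ins
    }
  }
  tibble(read_id = seq_len(n), accepted = accepted, flipped = flipped,
         identity = identity, ref_space = ref_space, insertions = insertions)
}

#' Pile aligned reads onto reference columns
#'
#' Tallies, for every reference position, the aligned base calls (A, C, G,
#' T, N), deletions spanning the column, and insertions attributed to the
#' preceding reference column.  Only accepted alignments contribute.
#'
#' @param alignments tibble from `align_reads()` / rows shaped like
#'   [align_read()] output.
#' @param reference an [amplicon_reference()] or reference string.
#' @return an object of class `pileup_counts`: a list with `counts` (7 x L
#'   matrix, rows A, C, G, T, N, del, ins), the `alignments` tibble, and the
#'   reference.
#' @export
pileup <- function(alignments, reference) {
  ref <- if (inherits(reference, "amplicon_reference")) reference$residues else reference
  L0 <- nchar(ref)
  counts <- matrix(0L, nrow = 7, ncol = L0,
                   dimnames = list(c("A", "C", "G", "T", "N", "del", "ins"), NULL))
  acc <- alignments[alignments$accepted, , drop = FALSE]
  if (nrow(acc) > 0) {
    cm <- Biostrings::consensusMatrix(Biostrings::BStringSet(acc$ref_space))
    for (b in c("A", "C", "G", "T", "N")) {
      if (b %in% rownames(cm)) counts[b, ] <- cm[b, ]
    }
    if ("-" %in% rownames(cm)) counts["del", ] <- cm["-", ]
    ins <- dplyr::bind_rows(acc$insertions)
    if (!is.null(ins) && nrow(ins) > 0) {
      tab <- table(ins$pos)
      counts["ins", as.integer(names(tab))] <- as.integer(tab)
    }
  }
  structure(list(counts = counts, alignments = alignments, reference = reference),
            class = "pileup_counts")
}

#' @export
print.pileup_counts <- function(x, ...) {
  cat("<pileup_counts> ", sum(x$alignments$accepted), "/", nrow(x$alignments),
      " reads aligned over ", ncol(x$counts), " positions\n", sep = "")
  invisible(x)
}
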