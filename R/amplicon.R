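#' Describe an amplicon reference and its guide site
#'
#' Binds an amplicon sequence to the guide whose editing is being measured.
#' The guide coordinates are validated against the sequence: the protospacer
#' and PAM must actually occur there in the declared orientation.
#'
#' @param residues amplicon sequence (single string, A/C/G/T).
#' @param guide_seq the 20-nt protospacer (guide orientation).
#' @param guide_start 1-based position of the protospacer 5' base within the
#'   amplicon.
#' @param guide_strand `"+"` if the guide matches the amplicon strand,
#'   `"-"` if it matches its reverse complement.
#' @param profile an [editor_profile()].
#' @param target_c_offset window offset (1-based) of the designated target
#'   C.  Defaults to the single window C when there is exactly one;
#'   otherwise the 5'-most window C is used (with a message).
#' @return an object of class `amplicon_reference` carrying the window
#'   columns on the amplicon, the target column, and the conversion to count
#'   (`C>T` on a "+" guide appears as `G>A` on the reference of a "-"
#'   guide).
#' @export
amplicon_reference <- function(residues, guide_seq, guide_start,
                               guide_strand = c("+", "-"),
                               profile = editor_profile(),
                               target_c_offset = NULL) {
  guide_strand <- match.arg(guide_strand)
  residues <- normalize_residues(residues)
  L <- profile$protospacer_length
  plen <- nchar(profile$pam_pattern)
  n <- nchar(residues)
  stopifnot(nchar(guide_seq) == L)

  if (guide_strand == "+") {
    proto_cols <- guide_start + seq_len(L) - 1L
    pam_cols <- guide_start + L + seq_len(plen) - 1L
    observed <- str_sub(residues, proto_cols[1], proto_cols[L])
    pam_obs <- str_sub(residues, pam_cols[1], pam_cols[plen])
  } else {
    proto_cols <- guide_start - (seq_len(L) - 1L)
    pam_cols <- guide_start - L - (seq_len(plen) - 1L)
    observed <- reverse_complement(str_sub(residues, proto_cols[L], proto_cols[1]))
    pam_obs <- reverse_complement(str_sub(residues, min(pam_cols), max(pam_cols)))
  }
  if (any(c(proto_cols, pam_cols) < 1) || any(c(proto_cols, pam_cols) > n)) {
    abort("guide site extends outside the amplicon", class = "crisprstop_contract_error")
  }
  if (observed != guide_seq) {
    abort("protospacer does not occur at the declared amplicon coordinates",
          class = "crisprstop_contract_error")
  }
  if (!iupac_match(pam_obs, profile$pam_pattern)) {
    abort(paste0("PAM at the declared coordinates (", pam_obs,
                 ") does not match ", profile$pam_pattern),
          class = "crisprstop_contract_error")
  }

  wb <- window_bounds(profile)
  window_offsets <- seq_len(wb[2] - wb[1] + 1L)
  window_cols <- proto_cols[wb[1] + window_offsets - 1L]
  conv_from <- if (guide_strand == "+") "C" else "G"
  conv_to <- if (guide_strand == "+") "T" else "A"
  ref_bases <- substring(residues, window_cols, window_cols)
  c_offsets <- window_offsets[ref_bases == conv_from]

  if (is.null(target_c_offset)) {
    if (length(c_offsets) == 1) {
      target_c_offset <- c_offsets
    } else if (length(c_offsets) > 1) {
      target_c_offset <- c_offsets[1]
      inform(paste0("window has ", length(c_offsets),
                    " cytosines; using the 5'-most (offset ", target_c_offset,
                    ") as the designated target C"))
    } else {
      target_c_offset <- NA_integer_
    }
  } else if (!target_c_offset %in% c_offsets) {
    abort("target_c_offset does not fall on a window cytosine",
          class = "crisprstop_contract_error")
  }

  structure(list(
    residues = residues, guide_seq = guide_seq, pam = pam_obs,
    guide_start = as.integer(guide_start), guide_strand = guide_strand,
    profile = profile,
    window_offsets = window_offsets, window_cols = as.integer(window_cols),
    c_offsets = as.integer(c_offsets),
    target_c_offset = as.integer(target_c_offset),
    target_col = if (is.na(target_c_offset)) NA_integer_
                 else as.integer(window_cols[target_c_offset]),
    conv_from = conv_from, conv_to = conv_to
  ), class = "amplicon_reference")
}

#' @export
print.amplicon_reference <- function(x, ...) {
  cat("<amplicon_reference> ", nchar(x$residues), " nt; guide ", x$guide_seq,
      " (", x$guide_strand, ") at ", x$guide_start,
      "; window columns ", paste(x$window_cols, collapse = ","),
      "; target C column ", x$target_col, " (", x$conv_from, ">", x$conv_to,
      ")\n", sep = "")
  invisible(x)
}
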