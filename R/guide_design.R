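#' Enumerate protospacer+PAM sites on both strands of a coding sequence
#'
#' Every position (on either strand) where a `protospacer_length`-mer is
#' immediately followed 3' by a PAM-matching trimer yields one candidate.
#' Candidates whose protospacer or PAM contains `N` are dropped: an unread
#' base can be confirmed neither as an editable C nor as PAM-compatible.
#'
#' Coordinates: `cds_position` is the 1-based position, within the supplied
#' sequence, of the leftmost (forward-strand 5') base of the full
#' protospacer+PAM site.  For "+" candidates that is the protospacer's 5'
#' base; for "-" candidates it is the 5' base of the PAM as it reads on the
#' forward strand.  This single left-coordinate convention keeps plus- and
#' minus-strand sites directly comparable, as in interval formats.
#'
#' @param cds coding sequence as a single string (coding orientation), or a
#'   one-row tibble with a `residues` column.
#' @param profile an [editor_profile()].
#' @return tibble with one row per candidate: `protospacer`, `pam`,
#'   `direction`, `cds_position`, `window`, `window_c_offsets` (list of
#'   1-based offsets of each C within the window), and the forward-strand
#'   site span `site_start`, `site_end`.  Ordered by `site_start`, then
#'   direction ("+" first).  A sequence shorter than protospacer+PAM yields
#'   an empty tibble.
#' @export
enumerate_protospacers <- function(cds, profile = editor_profile()) {
  if (is.data.frame(cds)) cds <- cds$residues[1]
  stopifnot(is.character(cds), length(cds) == 1)
  L <- profile$protospacer_length
  plen <- nchar(profile$pam_pattern)
  site_len <- L + plen
  n <- nchar(cds)
  empty <- tibble(
    protospacer = character(), pam = character(), direction = character(),
    cds_position = integer(), window = character(),
    window_c_offsets = list(), site_start = integer(), site_end = integer()
  )
  if (n < site_len) return(empty)

  scan_strand <- function(s) {
    # candidate protospacer starts: every i whose trailing trimer matches the
    # PAM (overlap-tolerant lookahead scan)
    pam_re <- paste0("(?=", iupac_regex(profile$pam_pattern), ")")
    hits <- gregexpr(pam_re, s, perl = TRUE)[[1]]
    j <- as.integer(hits[hits > 0])
    i <- j - L
    i <- i[i >= 1 & (j + plen - 1L) <= nchar(s)]
    if (length(i) == 0) return(NULL)
    proto <- substring(s, i, i + L - 1L)
    pam <- substring(s, i + L, i + site_len - 1L)
    clean <- !grepl("N", proto, fixed = TRUE) & !grepl("N", pam, fixed = TRUE)
    if (!any(clean)) return(NULL)
    tibble(start = i[clean], protospacer = proto[clean], pam = pam[clean])
  }

  rows <- list()
  fwd <- scan_strand(cds)
  if (!is.null(fwd)) {
    rows[["+"]] <- fwd |>
      mutate(direction = "+", site_start = .data$start,
             site_end = .data$start + site_len - 1L,
             cds_position = .data$start)
  }
  rev <- scan_strand(reverse_complement(cds))
  if (!is.null(rev)) {
    # protospacer occupies rc [start, start+L-1], PAM rc [start+L, start+site_len-1];
    # forward-strand leftmost base of the site is the PAM's last rc base.
    rows[["-"]] <- rev |>
      mutate(direction = "-",
             site_start = n - (.data$start + site_len - 1L) + 1L,
             site_end = n - .data$start + 1L,
             cds_position = .data$site_start)
  }
  if (length(rows) == 0) return(empty)
  out <- bind_rows(rows) |> select(-"start")
  wb <- window_bounds(profile)
  out$window <- str_sub(out$protospacer, wb[1], wb[2])
  out$window_c_offsets <- lapply(strsplit(out$window, ""), function(ch) which(ch == "C"))
  out |>
    arrange(.data$site_start, match(.data$direction, c("+", "-"))) |>
    select("protospacer", "pam", "direction", "cds_position", "window",
           "window_c_offsets", "site_start", "site_end")
}

#' Extract the editing window of a guide
#'
#' With the default Target-AID profile this is the protospacer substring at
#' positions 2-5 (5'->3'), i.e. 16-19 bp upstream of the PAM.
#'
#' @param candidate a candidate row from [enumerate_protospacers()], a list
#'   with a `protospacer` element, or a bare protospacer string (vectorised).
#' @param profile an [editor_profile()].
#' @return tibble with columns `window` and `c_offsets` (list column of
#'   1-based offsets of every C within the window).
#' @export
extract_window <- function(candidate, profile = editor_profile()) {
  proto <- if (is.character(candidate)) candidate else candidate$protospacer
  stopifnot(all(nchar(proto) == profile$protospacer_length))
  wb <- window_bounds(profile)
  window <- str_sub(proto, wb[1], wb[2])
  tibble(window = window,
         c_offsets = lapply(strsplit(window, ""), function(ch) which(ch == "C")))
}

#' Enumerate candidate edit outcomes for a guide window
#'
#' The deaminase may convert any window C; the outcomes modelled are each
#' single-C conversion plus the all-C conversion (deduplicated, so a
#' single-C window yields one set).  A window without C yields an empty list.
#'
#' @param candidate as in [extract_window()] (single guide).
#' @param profile an [editor_profile()].
#' @return list of integer vectors of window offsets.
#' @export
simulate_edits <- function(candidate, profile = editor_profile()) {
  w <- extract_window(candidate, profile)
  offs <- w$c_offsets[[1]]
  if (length(offs) == 0) return(list())
  sets <- c(lapply(offs, identity), list(offs))
  unique(sets)
}

#' Predict whether a window edit creates a premature stop codon
#'
#' Applies C-to-T conversion at the given window offsets on the guide strand
#' (equivalently G-to-A on the coding strand for "-" guides), re-translates
#' the whole coding sequence, and reports whether a new in-frame stop
#' appears strictly before the terminal codon.  Route labels follow the
#' CRISPR-STOP convention: sense guides are labelled by the pre-edit codon
#' (CAA/CAG/CGA), antisense guides by the guide-strand trinucleotide of the
#' pre-edit codon (CCA for a coding-strand TGG).
#'
#' @param cds the full in-frame coding sequence (single string).
#' @param candidate one candidate row/list with `protospacer`, `pam`,
#'   `direction`, `cds_position` as produced by [enumerate_protospacers()]
#'   on the same sequence.
#' @param edit_set integer vector of window offsets to convert.
#' @param profile an [editor_profile()].
#' @return one-row tibble: `edited_c_positions` (list), `codon_index`,
#'   `pre_codon`, `post_codon`, `creates_stop`, `stop_codon`, `route_label`.
#' @export
predict_stop <- function(cds, candidate, edit_set, profile = editor_profile()) {
  if (is.data.frame(candidate)) candidate <- as.list(candidate[1, ])
  L <- profile$protospacer_length
  plen <- nchar(candidate$pam %||% profile$pam_pattern)
  n <- nchar(cds)
  if (n %% 3 != 0) abort("cds length must be a multiple of 3", class = "crisprstop_contract_error")
  pos <- candidate$cds_position
  dirn <- candidate$direction
  site_end <- pos + L + plen - 1L
  if (!(pos >= 1 && site_end <= n)) {
    abort("candidate site not contained in the coding sequence",
          class = "crisprstop_contract_error")
  }
  # verify the candidate really sits at its declared coordinates
  site <- str_sub(cds, pos, site_end)
  expected <- if (dirn == "+") paste0(candidate$protospacer, candidate$pam)
              else reverse_complement(paste0(candidate$protospacer, candidate$pam))
  if (site != expected) {
    abort("candidate sequence does not match the coding sequence at its declared position",
          class = "crisprstop_contract_error")
  }

  wb <- window_bounds(profile)
  stopifnot(length(edit_set) >= 1, all(edit_set >= 1),
            all(edit_set <= wb[2] - wb[1] + 1L))
  proto_pos <- wb[1] + as.integer(edit_set) - 1L
  fwd_pos <- if (dirn == "+") pos + proto_pos - 1L
             else pos + plen + L - proto_pos
  from <- if (dirn == "+") "C" else "G"
  to <- if (dirn == "+") "T" else "A"
  if (!all(substring(cds, fwd_pos, fwd_pos) == from)) {
    abort("edit offsets do not fall on window cytosines", class = "crisprstop_contract_error")
  }
  # an edit can only change the codons it touches, so the re-translated CDS
  # differs from the original at exactly those codon indices
  n_codons <- n %/% 3L
  affected <- sort(unique((fwd_pos - 1L) %/% 3L + 1L))
  cfroms <- 3L * affected - 2L
  pre_codons <- substring(cds, cfroms, cfroms + 2L)
  post_codons <- vapply(seq_along(affected), function(j) {
    codon <- strsplit(pre_codons[j], "")[[1]]
    within <- fwd_pos[fwd_pos >= cfroms[j] & fwd_pos <= cfroms[j] + 2L]
    codon[within - cfroms[j] + 1L] <- to
    paste(codon, collapse = "")
  }, character(1))
  is_new_stop <- post_codons %in% STOP_CODONS & !(pre_codons %in% STOP_CODONS) &
    affected < n_codons  # strictly before the terminal codon
  creates <- any(is_new_stop)

  pick <- if (creates) which(is_new_stop)[1] else 1L
  codon_index <- affected[pick]
  pre_codon <- pre_codons[pick]
  post_codon <- post_codons[pick]
  tibble(
    edited_c_positions = list(as.integer(edit_set)),
    codon_index = codon_index,
    pre_codon = pre_codon,
    post_codon = post_codon,
    creates_stop = creates,
    stop_codon = if (creates) post_codon else "",
    route_label = if (dirn == "+") pre_codon else reverse_complement(pre_codon)
  )
}

ROUTE_ORDER <- c("CAA", "CAG", "CGA", "CCA", "TCA", "CTA")

#' Design premature-stop guides for one gene across a genome panel
#'
#' The CRISPR-STOP filter: enumerate protospacers over the gene's coding
#' sequence in every panel genome, extract each editing window, apply every
#' candidate C-to-T edit set in silico, and retain the guides for which some
#' edit set creates a premature stop codon.  Sense guides convert in-frame
#' CAA/CAG/CGA to TAA/TAG/TGA; antisense guides convert the coding strand's
#' TGG (via guide-strand C-to-T, coding G-to-A) to TAG/TGA.
#'
#' @param panel a [genome_panel()].
#' @param gene_name gene to target (must be annotated in every panel entry).
#' @param profile an [editor_profile()].
#' @return tibble with one row per stop-creating guide per genome: `label`,
#'   `gene`, `direction`, `stop_route`, `protospacer`, `pam`, `window`,
#'   `cds_position`, `target_c_offset` (window offset of the designated
#'   target C: the single-C edit that creates the stop, when one exists),
#'   `edit_sets` (all stop-creating sets, semicolon-separated offsets with
#'   `+` joining co-edited Cs), `stop_codon`.  Rows are ordered by route
#'   class (CAA, CAG, CGA, then antisense labels), position, direction.
#' @export
design_stop_guides <- function(panel, gene_name, profile = editor_profile()) {
  out <- list()
  for (label in panel$genomes$label) {
    cds <- cds_sequence(panel, label, gene_name)
    cands <- enumerate_protospacers(cds, profile)
    if (nrow(cands) == 0) next
    for (k in seq_len(nrow(cands))) {
      cand <- as.list(cands[k, ])
      cand$window_c_offsets <- cands$window_c_offsets[[k]]
      sets <- simulate_edits(cand$protospacer, profile)
      if (length(sets) == 0) next
      preds <- lapply(sets, function(es) predict_stop(cds, cand, es, profile))
      hit <- vapply(preds, function(p) p$creates_stop, logical(1))
      if (!any(hit)) next
      hits <- preds[hit]
      sizes <- vapply(sets[hit], length, integer(1))
      chosen <- hits[[which.min(sizes)]]
      target_c <- if (min(sizes) == 1L) sets[hit][[which.min(sizes)]][1] else NA_integer_
      out[[length(out) + 1L]] <- tibble(
        label = label, gene = gene_name,
        direction = cand$direction,
        stop_route = chosen$route_label,
        protospacer = cand$protospacer, pam = cand$pam,
        window = cand$window, cds_position = cand$cds_position,
        target_c_offset = target_c,
        edit_sets = paste(vapply(sets[hit], paste, character(1), collapse = "+"),
                          collapse = ";"),
        stop_codon = chosen$stop_codon
      )
    }
  }
  if (length(out) == 0) {
    return(tibble(label = character(), gene = character(), direction = character(),
                  stop_route = character(), protospacer = character(), pam = character(),
                  window = character(), cds_position = integer(),
                  target_c_offset = integer(), edit_sets = character(),
                  stop_codon = character()))
  }
  bind_rows(out) |>
    mutate(.route_rank = match(.data$stop_route, ROUTE_ORDER),
           .route_rank = if_else(is.na(.route_rank), length(ROUTE_ORDER) + 1L, .route_rank),
           .dir_rank = match(.data$direction, c("+", "-"))) |>
    arrange(.data$.route_rank, .data$cds_position, .data$.dir_rank) |>
    select(-".route_rank", -".dir_rank")
}
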