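# Minimal GenBank flat-file reader: ORIGIN sequence plus CDS features with
# /gene and /product qualifiers.  Only simple `a..b` and `complement(a..b)`
# locations are interpreted; anything else (join, fuzzy ends) falls through
# to the ORF fallback.  No installed R package parses GenBank feature tables
# from local files, hence this reader.

parse_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  o <- grep("^ORIGIN", lines)
  if (length(o) == 0) abort(paste0("no ORIGIN block in ", path), class = "crisprstop_format_error")
  end <- grep("^//", lines)
  end <- if (length(end)) end[end > o[1]][1] else length(lines) + 1
  seq_lines <- lines[(o[1] + 1):(end - 1)]
  residues <- paste(gsub("[ 0-9/]", "", seq_lines), collapse = "")
  residues <- suppressWarnings(normalize_residues(residues))
  if (nchar(residues) == 0) abort(paste0("empty sequence in ", path), class = "crisprstop_format_error")

  id <- sub("^LOCUS +(\\S+).*$", "\\1", grep("^LOCUS", lines, value = TRUE)[1])
  if (is.na(id)) id <- basename(path)

  feat_start <- grep("^FEATURES", lines)
  cds <- list()
  if (length(feat_start)) {
    flines <- lines[(feat_start[1] + 1):(o[1] - 1)]
    is_key <- grepl("^ {5}\\S", flines)
    key_idx <- which(is_key)
    for (k in seq_along(key_idx)) {
      key <- sub("^ {5}(\\S+).*$", "\\1", flines[key_idx[k]])
      if (key != "CDS") next
      to <- if (k < length(key_idx)) key_idx[k + 1] - 1 else length(flines)
      block <- flines[key_idx[k]:to]
      body <- sub("^ {5}\\S+ +", "", block[1])
      qual_at <- grep("^ +/", block)
      loc_end <- if (length(qual_at)) qual_at[1] - 1 else length(block)
      if (loc_end > 1) body <- paste0(body, paste(trimws(block[2:loc_end]), collapse = ""))
      quals <- paste(trimws(block[seq_along(block) > loc_end]), collapse = " ")
      get_q <- function(name) {
        m <- regmatches(quals, regexec(paste0("/", name, "=\"([^\"]*)\""), quals))[[1]]
        if (length(m) == 2) m[2] else NA_character_
      }
      cds[[length(cds) + 1]] <- list(location = body, gene = get_q("gene"),
                                     product = get_q("product"))
    }
  }
  list(id = id, residues = residues, cds = cds)
}

parse_gb_location <- function(loc) {
  strand <- if (grepl("^complement\\(", loc)) "-" else "+"
  inner <- gsub("^complement\\(|\\)$", "", loc)
  m <- regmatches(inner, regexec("^<?([0-9]+)\\.\\.>?([0-9]+)$", inner))[[1]]
  if (length(m) != 3) return(NULL)
  list(start = as.integer(m[2]), end = as.integer(m[3]), strand = strand)
}

#' Read a CDS for one gene from a GenBank flat file
#'
#' Looks for a `CDS` feature whose `/gene` or `/product` qualifier contains
#' `gene_name` (case-insensitive substring).  When no annotated CDS matches,
#' falls back to the longest open reading frame of at least `min_orf` nt on
#' either strand and flags the result as inferred (retroviral core genes
#' exceed 1 kb, so the default threshold suppresses spurious short ORFs).
#'
#' @param path GenBank flat file.
#' @param gene_name gene to look up (e.g. `"gag"`).
#' @param min_orf minimum ORF length (nt) for the fallback, default 900.
#' @return a list with `id`, `residues` (the genome) and `region`, a one-row
#'   tibble with columns `gene`, `start`, `end`, `strand`, `inferred`.
#' @export
read_genbank_cds <- function(path, gene_name, min_orf = 900) {
  gb <- parse_genbank(path)
  region <- NULL
  for (f in gb$cds) {
    hay <- tolower(paste(f$gene %||% "", f$product %||% ""))
    if (!grepl(tolower(gene_name), hay, fixed = TRUE)) next
    loc <- parse_gb_location(f$location)
    if (is.null(loc)) next
    if ((loc$end - loc$start + 1) %% 3 != 0) next
    region <- tibble(gene = gene_name, start = loc$start, end = loc$end,
                     strand = loc$strand, inferred = FALSE)
    break
  }
  if (is.null(region)) {
    orf <- longest_orf(gb$residues, min_len = min_orf)
    if (is.null(orf)) {
      abort(paste0("no annotated CDS matching '", gene_name,
                   "' and no ORF of >= ", min_orf, " nt in ", path),
            class = "crisprstop_lookup_error")
    }
    inform(paste0("no annotated CDS for '", gene_name,
                  "'; using longest ORF (", orf$end - orf$start + 1, " nt, ",
                  orf$strand, " strand) as an inferred coding region"))
    region <- tibble(gene = gene_name, start = orf$start, end = orf$end,
                     strand = orf$strand, inferred = TRUE)
  }
  list(id = gb$id, residues = gb$residues, region = region)
}

# Longest ATG..stop open reading frame (stop codon included) over both
# strands; forward-strand coordinates.  NULL when none reaches min_len.
longest_orf <- function(residues, min_len = 900) {
  n <- nchar(residues)
  best <- NULL
  for (strand in c("+", "-")) {
    s <- if (strand == "+") residues else reverse_complement(residues)
    for (frame in 0:2) {
      starts <- seq(1 + frame, n - 2, by = 3)
      if (length(starts) == 0) next
      codons <- substring(s, starts, starts + 2)
      is_stop <- codons %in% STOP_CODONS
      is_atg <- codons == "ATG"
      stop_pos <- c(which(is_stop), length(codons) + 1L)
      for (a in which(is_atg)) {
        nxt <- stop_pos[stop_pos > a][1]
        if (nxt > length(codons)) next  # runs off the end: not a complete ORF
        len <- (nxt - a + 1L) * 3L
        if (len >= min_len && (is.null(best) || len > best$len)) {
          from <- starts[a]; to <- starts[nxt] + 2L
          if (strand == "+") {
            best <- list(start = from, end = to, strand = strand, len = len)
          } else {
            best <- list(start = n - to + 1L, end = n - from + 1L, strand = strand, len = len)
          }
        }
      }
    }
  }
  best
}
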