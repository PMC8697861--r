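# Sense codons (no stops), the sampling pool for simulated coding sequence.
SENSE_CODONS <- {
  b <- c("A", "C", "G", "T")
  all3 <- as.vector(outer(as.vector(outer(b, b, paste0)), b, paste0))
  setdiff(all3, c("TAA", "TAG", "TGA"))
}

normalize_site_subtypes <- function(subtypes, labels) {
  if (is.null(subtypes) || length(subtypes) == 0 || all(is.na(subtypes))) return(labels)
  unlist(strsplit(subtypes, ","))
}

#' Generate a family of diverged proviral-like genomes with planted guide sites
#'
#' Emulates a set of homologous viral subtypes sharing conserved editable
#' sites: an ancestral genome is drawn with stop-free coding sequences, each
#' requested site plants an in-frame editable codon (CAA/CAG/CGA on the
#' sense strand, or TGG for an antisense guide) with an NGG PAM at the
#' spacing that puts the target C in the 16-19 bp editing window, and each
#' subtype is then derived by random substitutions at the requested
#' divergence.  Mutations never touch a carried site +/- 23 bp, and any
#' substitution that would create a premature stop codon is reverted, so
#' every subtype CDS stays translatable.  Sites can be restricted to a
#' subset of subtypes; non-carrying subtypes get the site's PAM destroyed.
#'
#' Site geometry (for [editor_profile()] defaults): a sense codon at codon
#' index k occupies protospacer positions 3-5, with the PAM written into
#' codon k+6; a TGG site is targeted from the antisense strand with the PAM
#' written (as CCA) into codon k-6.  The divergence sweep is nested: at the
#' same seed, every site mutated at divergence d1 is also mutated at any
#' d2 > d1.
#'
#' @param seed integer seed; the generator uses one seeded stream and
#'   restores the caller's RNG state.
#' @param n_subtypes number of subtypes, default 3.
#' @param genome_length ancestral genome length, default 3600 nt.
#' @param genes tibble of `gene`, `start`, `length` (CDS layout; lengths
#'   multiples of 3).  The default lays out three core genes (gag, pol,
#'   env-like) at desk scale.
#' @param divergence per-site substitution rate per subtype; scalar or one
#'   value per subtype.  Default 0.05.
#' @param conserved_sites tibble of `gene`, `codon_index`, `codon` (one of
#'   CAA, CAG, CGA, TGG) and optional `subtypes` (comma-separated labels;
#'   NA = carried by all).
#' @param labels subtype labels, default `S1..Sn`.
#' @return list with `panel` (a [genome_panel()]) and `truth` (a `sim_truth`
#'   list recording the seed, parameters, and each planted site's expected
#'   protospacer/PAM and carriers).
#' @export
make_provirus_family <- function(seed,
                                 n_subtypes = 3,
                                 genome_length = 3600,
                                 genes = NULL,
                                 divergence = 0.05,
                                 conserved_sites = NULL,
                                 labels = NULL) {
  withr::local_seed(seed)
  labels <- labels %||% paste0("S", seq_len(n_subtypes))
  stopifnot(length(labels) == n_subtypes)
  genes <- genes %||% tibble(
    gene = c("gag", "pol", "env"),
    start = c(201L, 1201L, 2501L),
    length = c(900L, 1200L, 900L)
  )
  conserved_sites <- conserved_sites %||% tibble(
    gene = c("gag", "pol"), codon_index = c(30L, 40L),
    codon = c("CAG", "CAG"), subtypes = NA_character_
  )
  if (!"subtypes" %in% names(conserved_sites)) conserved_sites$subtypes <- NA_character_
  divergence <- rep_len(divergence, n_subtypes)
  stopifnot(all(divergence >= 0 & divergence <= 1))
  if (any(genes$length %% 3 != 0)) abort("gene lengths must be multiples of 3",
                                         class = "crisprstop_generation_error")
  if (any(genes$start + genes$length - 1 > genome_length)) {
    abort("gene layout exceeds genome_length", class = "crisprstop_generation_error")
  }

  bases <- c("A", "C", "G", "T")
  anc <- sample(bases, genome_length, replace = TRUE)
  # stop-free CDSs with a terminal TAA
  for (i in seq_len(nrow(genes))) {
    nc <- genes$length[i] / 3L
    codons <- c(sample(SENSE_CODONS, nc - 1L, replace = TRUE), "TAA")
    anc[genes$start[i] + seq_len(genes$length[i]) - 1L] <-
      unlist(strsplit(codons, ""))
  }

  set_codon <- function(anc, cds_start, k, codon) {
    anc[cds_start + 3L * (k - 1L) + 0:2] <- strsplit(codon, "")[[1]]
    anc
  }

  # Overwrite the codons spanning the site +/- pad with inert ATT (no C, no
  # GG/CC), so the planted guide is the only editable site inside its
  # mutation-protected neighbourhood; the terminal stop codon is never
  # touched.
  sanitize_cassette <- function(anc, g, site_start_cds, site_end_cds, pad = 24L) {
    lo_pos <- max(1L, site_start_cds - pad)
    hi_pos <- min(g$length, site_end_cds + pad)
    k_lo <- (lo_pos - 1L) %/% 3L + 1L
    k_hi <- min((hi_pos - 1L) %/% 3L + 1L, g$length / 3L - 1L)
    for (k in k_lo:k_hi) anc <- set_codon(anc, g$start, k, "ATT")
    anc
  }

  # plant sites and record their footprints
  site_truth <- list()
  footprints <- list()
  for (i in seq_len(nrow(conserved_sites))) {
    s <- conserved_sites[i, ]
    g <- genes[genes$gene == s$gene, ]
    if (nrow(g) == 0) abort(paste0("site gene not in layout: ", s$gene),
                            class = "crisprstop_generation_error")
    nc <- g$length / 3L
    k <- s$codon_index
    if (s$codon %in% c("CAA", "CAG", "CGA")) {
      if (k < 2L || k + 6L >= nc) {
        abort("sense site codon_index out of feasible range",
              class = "crisprstop_generation_error")
      }
      site_start_cds <- 3L * k - 4L                    # protospacer 5' base
      anc <- sanitize_cassette(anc, g, site_start_cds, site_start_cds + 22L)
      anc <- set_codon(anc, g$start, k, s$codon)
      anc <- set_codon(anc, g$start, k + 6L, "AGG")   # the NGG PAM, in frame
      direction <- "+"
      pam_codon_index <- k + 6L
    } else if (s$codon == "TGG") {
      if (k <= 7L || 3L * k + 2L > g$length) {
        abort("antisense (TGG) site codon_index out of feasible range",
              class = "crisprstop_generation_error")
      }
      site_start_cds <- 3L * k - 20L                   # forward leftmost base (PAM)
      anc <- sanitize_cassette(anc, g, site_start_cds, site_start_cds + 22L)
      anc <- set_codon(anc, g$start, k, "TGG")
      anc <- set_codon(anc, g$start, k - 6L, "CCA")   # reads as NGG on the antisense strand
      direction <- "-"
      pam_codon_index <- k - 6L
    } else {
      abort(paste0("unsupported site codon: ", s$codon),
            class = "crisprstop_generation_error")
    }
    fw_start <- g$start + site_start_cds - 1L
    fw_end <- fw_start + 22L
    carriers <- normalize_site_subtypes(s$subtypes, labels)
    fp <- list(gene = s$gene, codon_index = k, codon = s$codon,
               direction = direction, cds_position = site_start_cds,
               fw_start = fw_start, fw_end = fw_end,
               pam_codon_index = pam_codon_index, cds_start = g$start,
               carriers = carriers)
    for (other in footprints) {
      if (fp$fw_start <= other$fw_end + 50L && other$fw_start <= fp$fw_end + 50L) {
        abort("conserved sites overlap (footprints within 50 bp): infeasible layout",
              class = "crisprstop_generation_error")
      }
    }
    footprints[[length(footprints) + 1L]] <- fp
  }
  # fill in the planted guide sequences now the ancestor is final
  anc_str <- paste(anc, collapse = "")
  for (j in seq_along(footprints)) {
    fp <- footprints[[j]]
    site <- str_sub(anc_str, fp$fw_start, fp$fw_end)
    if (fp$direction == "+") {
      fp$protospacer <- str_sub(site, 1, 20)
      fp$pam <- str_sub(site, 21, 23)
    } else {
      rc <- reverse_complement(site)
      fp$protospacer <- str_sub(rc, 1, 20)
      fp$pam <- str_sub(rc, 21, 23)
    }
    footprints[[j]] <- fp
    site_truth[[j]] <- tibble(
      gene = fp$gene, codon = fp$codon, direction = fp$direction,
      codon_index = fp$codon_index, cds_position = fp$cds_position,
      protospacer = fp$protospacer, pam = fp$pam,
      carriers = paste(fp$carriers, collapse = ",")
    )
  }

  # per-subtype divergence via per-site uniforms (nested across divergences)
  u <- matrix(stats::runif(n_subtypes * genome_length), nrow = n_subtypes)
  alt_pick <- matrix(sample.int(3L, n_subtypes * genome_length, replace = TRUE),
                     nrow = n_subtypes)
  genomes <- character(n_subtypes)
  for (st in seq_len(n_subtypes)) {
    gchars <- anc
    protected <- rep(FALSE, genome_length)
    for (fp in footprints) {
      if (labels[st] %in% fp$carriers) {
        lo <- max(1L, fp$fw_start - 23L)
        hi <- min(genome_length, fp$fw_end + 23L)
        protected[lo:hi] <- TRUE
      }
    }
    mut <- which(u[st, ] < divergence[st] & !protected)
    for (pos in mut) {
      alts <- setdiff(bases, gchars[pos])
      gchars[pos] <- alts[alt_pick[st, pos]]
    }
    # destroy the PAM of sites this subtype does not carry
    for (fp in footprints) {
      if (!labels[st] %in% fp$carriers) {
        repl <- if (fp$direction == "+") "AAG" else "ACA"
        idx <- fp$cds_start + 3L * (fp$pam_codon_index - 1L) + 0:2
        gchars[idx] <- strsplit(repl, "")[[1]]
      }
    }
    # revert any substitution that created a premature stop
    for (i in seq_len(nrow(genes))) {
      idx <- genes$start[i] + seq_len(genes$length[i]) - 1L
      cod_start <- idx[seq(1, length(idx), by = 3)]
      codons <- paste0(gchars[cod_start], gchars[cod_start + 1L], gchars[cod_start + 2L])
      bad <- which(codons %in% STOP_CODONS)
      bad <- bad[bad < length(codons)]
      if (!codons[length(codons)] %in% STOP_CODONS) bad <- c(bad, length(codons))
      for (b in bad) {
        gchars[cod_start[b] + 0:2] <- anc[cod_start[b] + 0:2]
      }
    }
    genomes[st] <- paste(gchars, collapse = "")
  }

  regions <- tidyr::crossing(label = labels, genes) |>
    mutate(end = .data$start + .data$length - 1L, strand = "+") |>
    select("label", "gene", "start", "end", "strand")
  panel <- genome_panel(tibble(label = labels, residues = genomes), regions)
  truth <- structure(list(
    seed = seed, n_subtypes = n_subtypes, labels = labels,
    genome_length = genome_length, divergence = divergence,
    genes = genes, sites = bind_rows(site_truth)
  ), class = "sim_truth")
  list(panel = panel, truth = truth)
}

write_fastq_file <- function(ids, reads, quals, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(as.vector(rbind(paste0("@", ids), reads, "+", quals)), con)
  invisible(path)
}

#' Simulate amplicon deep-sequencing reads with known editing truth
#'
#' Emulates a targeted amplicon run over an edited cell population: each
#' read descends from an edited molecule with probability `edit_fraction`
#' (target C converted; each secondary window C co-converted independently
#' with probability `co_conversion`), receives a 1-3 nt indel within the
#' editing window +/- 5 bp with probability `indel_fraction`, and uniform
#' substitution error at `error_rate` per base (uniform over the three
#' alternative bases).  Base qualities are constant Q37 except for bases
#' corrupted via `low_quality_rate`, which are randomised and tagged Q2 (to
#' exercise quality masking).  Reads are emitted either single-end over the
#' whole molecule or as a 3'-overlapping pair.
#'
#' @param reference an [amplicon_reference()].
#' @param n_reads number of reads (or read pairs).
#' @param edit_fraction injected per-target-C edit fraction in `[0, 1]`.
#' @param seed integer seed; identical seed and parameters give
#'   byte-identical FASTQ output.
#' @param co_conversion probability that an edited molecule also converts
#'   each secondary window C, default 0.3.
#' @param error_rate uniform per-base substitution error, default 0.001.
#' @param indel_fraction fraction of reads carrying a window-proximal 1-3 nt
#'   indel, default 0.01.
#' @param low_quality_rate fraction of bases corrupted and tagged Q2,
#'   default 0.
#' @param paired emit an overlapping R1/R2 pair instead of one full-length
#'   read, default `FALSE`.
#' @param read_length mate length in paired mode; default 60% of the
#'   amplicon (guaranteeing a mergeable overlap).
#' @param dir output directory (created if needed), default `tempdir()`.
#' @param prefix file-name prefix, default `"sim"`.
#' @return list with `r1`, `r2` (NULL if single-end), `truth_path`, and
#'   `truth`: the parameters plus realised counts (`n_injected_edited`,
#'   `n_indel_reads`, `n_final_converted_no_indel` -- the number of
#'   indel-free reads whose final target base, after sequencing error, is
#'   converted).
#' @export
simulate_amplicon_reads <- function(reference, n_reads, edit_fraction, seed,
                                    co_conversion = 0.3, error_rate = 0.001,
                                    indel_fraction = 0.01,
                                    low_quality_rate = 0,
                                    paired = FALSE, read_length = NULL,
                                    dir = tempdir(), prefix = "sim") {
  stopifnot(inherits(reference, "amplicon_reference"), n_reads >= 1,
            edit_fraction >= 0, edit_fraction <= 1,
            error_rate >= 0, error_rate <= 1,
            indel_fraction >= 0, indel_fraction <= 1)
  if (length(reference$c_offsets) < 1) {
    abort("reference window has no C to edit", class = "crisprstop_contract_error")
  }
  withr::local_seed(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  amp <- reference$residues
  L <- nchar(amp)
  bases <- c("A", "C", "G", "T")

  mol <- rep(amp, n_reads)
  edited <- stats::runif(n_reads) < edit_fraction
  tcol <- reference$target_col
  substr(mol[edited], tcol, tcol) <- reference$conv_to
  secondary <- setdiff(reference$c_offsets, reference$target_c_offset)
  for (off in secondary) {
    col <- reference$window_cols[off]
    co <- edited & (stats::runif(n_reads) < co_conversion)
    substr(mol[co], col, col) <- reference$conv_to
  }

  # uniform per-base substitution error
  n_err <- stats::rbinom(n_reads, L, error_rate)
  for (i in which(n_err > 0)) {
    pos <- sample.int(L, n_err[i])
    ch <- strsplit(mol[i], "")[[1]]
    for (p in pos) ch[p] <- sample(setdiff(bases, ch[p]), 1)
    mol[i] <- paste(ch, collapse = "")
  }

  # window-proximal indels
  ws_lo <- max(1L, min(reference$window_cols) - 5L)
  ws_hi <- min(L, max(reference$window_cols) + 5L)
  has_indel <- stats::runif(n_reads) < indel_fraction
  for (i in which(has_indel)) {
    len <- sample.int(3L, 1)
    at <- sample(ws_lo:ws_hi, 1)
    if (stats::runif(1) < 0.5) {  # deletion
      mol[i] <- paste0(substr(mol[i], 1, at - 1),
                       substr(mol[i], min(at + len, nchar(mol[i]) + 1), nchar(mol[i])))
    } else {                      # insertion after `at`
      ins <- paste(sample(bases, len, replace = TRUE), collapse = "")
      mol[i] <- paste0(substr(mol[i], 1, at), ins,
                       substr(mol[i], at + 1, nchar(mol[i])))
    }
  }

  lens <- nchar(mol)
  quals <- strrep("F", lens)  # Phred+33 'F' = Q37
  if (low_quality_rate > 0) {
    n_low <- stats::rbinom(n_reads, lens, low_quality_rate)
    for (i in which(n_low > 0)) {
      pos <- sample.int(lens[i], n_low[i])
      ch <- strsplit(mol[i], "")[[1]]
      qc <- strsplit(quals[i], "")[[1]]
      for (p in pos) { ch[p] <- sample(bases, 1); qc[p] <- "#" }  # '#' = Q2
      mol[i] <- paste(ch, collapse = "")
      quals[i] <- paste(qc, collapse = "")
    }
  }

  n_final_conv <- sum(!has_indel &
                      substr(mol, tcol, tcol) == reference$conv_to)

  ids <- sprintf("%s_read%06d", prefix, seq_len(n_reads))
  rl <- NA_integer_
  if (paired) {
    rl <- as.integer(read_length %||% ceiling(0.6 * L))
    lens <- nchar(mol)
    r1 <- substr(mol, 1, pmin(rl, lens))
    r2 <- reverse_complement(substr(mol, pmax(1, lens - rl + 1), lens))
    q1 <- strrep("F", nchar(r1)); q2 <- strrep("F", nchar(r2))
    r1_path <- file.path(dir, paste0(prefix, "_R1.fastq"))
    r2_path <- file.path(dir, paste0(prefix, "_R2.fastq"))
    write_fastq_file(paste0(ids, "/1"), r1, q1, r1_path)
    write_fastq_file(paste0(ids, "/2"), r2, q2, r2_path)
  } else {
    r1_path <- file.path(dir, paste0(prefix, ".fastq"))
    r2_path <- NULL
    write_fastq_file(ids, mol, quals, r1_path)
  }

  truth <- list(
    seed = seed, n_reads = n_reads, edit_fraction = edit_fraction,
    co_conversion = co_conversion, error_rate = error_rate,
    indel_fraction = indel_fraction, low_quality_rate = low_quality_rate,
    paired = paired, read_length = rl,
    amplicon_length = L, guide_seq = reference$guide_seq,
    guide_start = reference$guide_start, guide_strand = reference$guide_strand,
    target_col = tcol, conv_to = reference$conv_to,
    n_injected_edited = sum(edited),
    n_indel_reads = sum(has_indel),
    n_final_converted_no_indel = n_final_conv
  )
  truth_path <- file.path(dir, paste0(prefix, "_truth.json"))
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA, null = "null")
  list(r1 = r1_path, r2 = r2_path, truth_path = truth_path, truth = truth)
}
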