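test_that("alignment accepts identical and reverse-complement reads", {
  ref <- make_test_amplicon()
  a <- align_read(ref$residues, ref)
  expect_true(a$accepted)
  expect_equal(a$identity, 1)
  expect_false(a$flipped)
  expect_equal(a$ref_space, ref$residues)

  b <- align_read(reverse_complement(ref$residues), ref)
  expect_true(b$accepted)
  expect_true(b$flipped)
  expect_equal(b$ref_space, ref$residues)

  expect_false(align_read(strrep("A", 25), ref)$accepted)  # too short
})

test_that("alignment scores match an independent dynamic-programming oracle", {
  withr::local_seed(51)
  for (i in 1:25) {
    ref <- random_dna(sample(60:90, 1))
    ch <- strsplit(ref, "")[[1]]
    # random substitutions
    nsub <- sample(0:6, 1)
    if (nsub > 0) {
      at <- sample(length(ch), nsub)
      ch[at] <- vapply(ch[at], function(b) sample(setdiff(c("A","C","G","T"), b), 1), "x")
    }
    # maybe an indel
    if (runif(1) < 0.5) {
      at <- sample(length(ch) - 5, 1) + 2
      if (runif(1) < 0.5) ch <- ch[-(at:(at + sample(0:2, 1)))]
      else ch <- append(ch, sample(c("A","C","G","T"), sample(1:3, 1), replace = TRUE), after = at)
    }
    # maybe a masked base
    if (runif(1) < 0.3) ch[sample(length(ch), 1)] <- "N"
    read <- paste(ch, collapse = "")
    got <- align_read(read, ref)
    want <- nw_score_oracle(read, ref)
    expect_equal(got$score, want)
  }
})

test_that("batch alignment agrees with single-read alignment on gapped reads", {
  ref <- make_test_amplicon(flank = 40)
  amp <- ref$residues
  reads <- c(
    amp,
    paste0(substr(amp, 1, 60), substr(amp, 63, nchar(amp))),            # 2 nt del
    paste0(substr(amp, 1, 70), "ACGT", substr(amp, 71, nchar(amp))),    # 4 nt ins
    reverse_complement(paste0(substr(amp, 1, 50), substr(amp, 52, nchar(amp))))
  )
  batch <- crisprstop:::align_reads(reads, ref)
  for (i in seq_along(reads)) {
    single <- align_read(reads[i], ref)
    expect_equal(batch$ref_space[i], single$ref_space)
    expect_equal(batch$flipped[i], single$flipped)
    expect_equal(batch$identity[i], single$identity, tolerance = 1e-12)
    bi <- batch$insertions[[i]]
    if (!is.null(bi)) expect_equal(as.data.frame(bi), as.data.frame(single$insertions))
    else expect_equal(nrow(single$insertions), 0)
  }
})

test_that("pileup counts every aligned base, deletion, and insertion", {
  ref <- make_test_amplicon(flank = 30)
  amp <- ref$residues
  reads <- rep(amp, 10)
  aln <- crisprstop:::align_reads(reads, ref)
  pile <- pileup(aln, ref)
  refb <- strsplit(amp, "")[[1]]
  for (j in c(1, 25, 83)) {
    expect_equal(unname(pile$counts[refb[j], j]), 10)
  }
  # column sums: base counts + deletions == aligned reads
  colsum <- colSums(pile$counts[c("A", "C", "G", "T", "N", "del"), ])
  expect_true(all(colsum == 10))

  # one read with a C>T at the target column
  tcol <- ref$target_col
  edited <- amp
  substr(edited, tcol, tcol) <- "T"
  pile2 <- pileup(crisprstop:::align_reads(c(rep(amp, 9), edited), ref), ref)
  expect_equal(unname(pile2$counts["C", tcol]), 9)
  expect_equal(unname(pile2$counts["T", tcol]), 1)
})

test_that("pileup matches a naive per-column recount on messy simulated reads", {
  withr::local_seed(52)
  ref <- make_test_amplicon(flank = 35)
  sim <- simulate_amplicon_reads(ref, 120, 0.4, seed = 53,
                                 error_rate = 0.01, indel_fraction = 0.1)
  reads <- parse_fastq_oracle(sim$r1)$reads
  aln <- crisprstop:::align_reads(reads, ref)
  pile <- pileup(aln, ref)
  want <- pileup_oracle(aln$ref_space[aln$accepted], nchar(ref$residues))
  expect_equal(pile$counts[rownames(want), ], want)
})

test_that("hand-counted read sets give exact window percentages", {
  ref <- make_test_amplicon(flank = 30)
  amp <- ref$residues
  tcol <- ref$target_col
  edited <- amp
  substr(edited, tcol, tcol) <- "T"
  # 3 of 10 reads converted
  tab <- quantify_reads(c(rep(edited, 3), rep(amp, 7)), ref)
  expect_equal(tab$window_c_to_t_percent, 30)
  expect_equal(tab$n_denominator, 10)

  # two additional reads with a deletion inside the window: excluded from
  # the denominator, headline unchanged
  del <- paste0(substr(amp, 1, tcol - 1), substr(amp, tcol + 1, nchar(amp)))
  tab2 <- quantify_reads(c(rep(edited, 3), rep(amp, 7), rep(del, 2)), ref)
  expect_equal(tab2$window_c_to_t_percent, 30)
  expect_equal(tab2$n_reads_indel_near_window, 2)
  expect_equal(tab2$n_reads_aligned, 12)

  # an indel far from the window does not reduce the denominator
  far <- paste0(substr(amp, 1, 5), substr(amp, 7, nchar(amp)))
  tab3 <- quantify_reads(c(rep(edited, 3), rep(amp, 7), far), ref)
  expect_equal(tab3$n_denominator, 11)

  # unedited, error-free reads: exactly zero
  tab0 <- quantify_reads(rep(amp, 10), ref)
  expect_equal(tab0$window_c_to_t_percent, 0)
})

test_that("a window without C yields NA headline but a full position table", {
  withr::local_seed(54)
  # guide whose window (positions 2-5) has no C
  proto <- paste0("TA", "AGGT", substr(random_dna(30), 1, 14))
  proto <- paste0("TAAGGT", random_dna(14))
  amp <- paste0(random_dna(40), proto, "TGG", random_dna(40))
  ref <- amplicon_reference(amp, proto, 41, "+")
  expect_true(is.na(ref$target_col))
  expect_message(tab <- quantify_reads(rep(amp, 5), ref), "not applicable")
  expect_true(is.na(tab$window_c_to_t_percent))
  expect_equal(nrow(tab$positions), nchar(amp))
})

test_that("injected fractions are recovered within binomial sampling error", {
  ref <- make_test_amplicon()
  f <- 0.35
  n <- 20000
  sim <- simulate_amplicon_reads(ref, n, f, seed = 55)
  tab <- quantify(sim$r1, ref)
  se <- sqrt(f * (1 - f) / n) * 100
  expect_lt(abs(tab$window_c_to_t_percent - 100 * f), 3 * se + 0.1)
  # estimator against the generator's own realised truth is even tighter
  realised <- 100 * sim$truth$n_final_converted_no_indel /
    (n - sim$truth$n_indel_reads)
  expect_lt(abs(tab$window_c_to_t_percent - realised), 0.15)
})

test_that("uniform sequencing error biases the estimate by less than the error rate", {
  ref <- make_test_amplicon()
  f <- 0.30; e <- 0.005; n <- 20000
  sim <- simulate_amplicon_reads(ref, n, f, seed = 56, error_rate = e,
                                 indel_fraction = 0)
  tab <- quantify(sim$r1, ref)
  se <- sqrt(f * (1 - f) / n) * 100
  expect_lt(abs(tab$window_c_to_t_percent - 100 * f), e * 100 + 3 * se)
})

test_that("estimates sharpen as read depth grows", {
  ref <- make_test_amplicon()
  f <- 0.5
  mae <- vapply(c(500, 50000), function(n) {
    errs <- vapply(1:4, function(k) {
      sim <- simulate_amplicon_reads(ref, n, f, seed = 5600 + k)
      abs(quantify(sim$r1, ref)$window_c_to_t_percent - 100 * f)
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  expect_lt(mae[2], mae[1])
})

test_that("minus-strand guides count G>A and mirror the plus-strand analysis", {
  withr::local_seed(57)
  proto <- "TTCAGGTTAAGAAGGGACCT"
  site_rc <- reverse_complement(paste0(proto, "TGG"))  # CCA...GAA on the forward strand
  amp <- paste0(random_dna(60), site_rc, random_dna(60))
  gs <- 60 + 23  # protospacer 5' base = rightmost base of the site span
  ref_minus <- amplicon_reference(amp, proto, gs, "-")
  expect_equal(ref_minus$conv_from, "G")
  expect_equal(ref_minus$conv_to, "A")

  # indel-free reads: gap placement under alignment tie-breaks is the one
  # step that is not strictly mirror-symmetric
  sim <- simulate_amplicon_reads(ref_minus, 3000, 0.42, seed = 58,
                                 indel_fraction = 0)
  tab_minus <- quantify(sim$r1, ref_minus)

  # same reads against the reverse-complemented reference with a "+" guide
  amp2 <- reverse_complement(amp)
  ref_plus <- amplicon_reference(amp2, proto, nchar(amp) - gs + 1, "+")
  reads <- parse_fastq_oracle(sim$r1)$reads
  tab_plus <- quantify_reads(reads, ref_plus)

  expect_equal(tab_minus$window_c_to_t_percent, tab_plus$window_c_to_t_percent)
  expect_equal(tab_minus$n_denominator, tab_plus$n_denominator)
  # per-position counts mirror: column j maps to L - j + 1 with complement
  L <- nchar(amp)
  expect_equal(unname(tab_minus$positions$G[ref_minus$target_col]),
               unname(tab_plus$positions$C[L - ref_minus$target_col + 1]))
})

test_that("quality masking removes corrupted calls instead of miscounting them", {
  ref <- make_test_amplicon()
  f <- 0.40
  sim <- simulate_amplicon_reads(ref, 8000, f, seed = 59, error_rate = 0,
                                 indel_fraction = 0, low_quality_rate = 0.05)
  masked <- quantify(sim$r1, ref)  # quantify() masks Phred<20 to N
  fq <- parse_fastq_oracle(sim$r1)
  unmasked <- quantify_reads(fq$reads, ref)
  expect_lt(abs(masked$window_c_to_t_percent - 100 * f),
            abs(unmasked$window_c_to_t_percent - 100 * f))
  expect_lt(abs(masked$window_c_to_t_percent - 100 * f), 1.5)
  expect_lt(masked$n_denominator, unmasked$n_denominator)
})

test_that("paired reads merge by overlap and quantify like single-end reads", {
  ref <- make_test_amplicon()
  f <- 0.25
  sim <- simulate_amplicon_reads(ref, 1500, f, seed = 60, paired = TRUE)
  expect_false(is.null(sim$r2))
  tab <- quantify(sim$r1, ref, r2 = sim$r2)
  expect_gt(tab$run$n_merged / 1500, 0.95)
  se <- sqrt(f * (1 - f) / 1500) * 100
  expect_lt(abs(tab$window_c_to_t_percent - 100 * f), 3 * se + 0.3)
})

test_that("extreme fractions quantify exactly under a noise-free generator", {
  ref <- make_test_amplicon()
  s0 <- simulate_amplicon_reads(ref, 400, 0, seed = 61, error_rate = 0,
                                indel_fraction = 0)
  expect_equal(quantify(s0$r1, ref)$window_c_to_t_percent, 0)
  s1 <- simulate_amplicon_reads(ref, 400, 1, seed = 62, error_rate = 0,
                                indel_fraction = 0)
  expect_equal(quantify(s1$r1, ref)$window_c_to_t_percent, 100)
})

test_that("substitution tables tidy, glance, summarise and plot", {
  ref <- make_test_amplicon()
  sim <- simulate_amplicon_reads(ref, 500, 0.5, seed = 63)
  tab <- quantify(sim$r1, ref)
  td <- tidy(tab)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), nchar(ref$residues))
  gl <- glance(tab)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$window_c_to_t_percent, tab$window_c_to_t_percent)
  haps <- top_haplotypes(tab, n = 5)
  expect_lte(nrow(haps), 5)
  expect_true(any(haps$is_reference) || all(haps$count >= 1))
  p <- autoplot(tab)
  expect_s3_class(p, "ggplot")
})
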