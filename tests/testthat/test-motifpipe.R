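test_that("SNP-containing motif occurrences are found on both strands", {
  motif <- "CCTCCCT"
  # forward occurrence: SNP at the T in position 3 of the motif
  ref <- c(chrA = "AACCTCCCTAA")
  snps <- tibble::tibble(seq_id = "chrA", pos = 5, allele1 = "T",
                         allele2 = "C")
  occ <- find_motif_occurrences_with_snp(ref, motif, snps)
  expect_identical(nrow(occ), 1L)
  expect_identical(occ$strand, "+")
  expect_identical(occ$start, 3L)
  expect_identical(occ$preserving_allele, "T")
  expect_identical(occ$disrupting_allele, "C")
  expect_identical(occ$snp_offset, 3L)
  expect_identical(occ$disrupted_text, "CCCCCCT")
  expect_false(occ$ref_mismatch)
  # reverse-complement occurrence (AGGGAGG on the forward strand)
  ref2 <- c(chrB = "TTAGGGAGGCA")
  snps2 <- tibble::tibble(seq_id = "chrB", pos = 7, allele1 = "A",
                          allele2 = "G")
  occ2 <- find_motif_occurrences_with_snp(ref2, motif, snps2)
  expect_identical(nrow(occ2), 1L)
  expect_identical(occ2$strand, "-")
  # window offset 5 maps to offset 3 on the motif strand
  expect_identical(occ2$snp_offset, 3L)
  expect_identical(occ2$preserving_allele, "A")
  # no motif anywhere
  occ3 <- find_motif_occurrences_with_snp(c(x = "AAAAAAAAAA"), motif,
                                          tibble::tibble(seq_id = "x", pos = 5,
                                                         allele1 = "A",
                                                         allele2 = "C"))
  expect_identical(nrow(occ3), 0L)
})

test_that("multi-SNP windows are excluded and reference mismatches flagged", {
  motif <- "CCTCCCT"
  ref <- c(chrA = "AACCTCCCTAA")
  two <- tibble::tibble(seq_id = "chrA", pos = c(5, 7),
                        allele1 = c("T", "C"), allele2 = c("C", "A"))
  expect_message(occ <- find_motif_occurrences_with_snp(ref, motif, two),
                 "more than one SNP")
  expect_identical(nrow(occ), 0L)
  # reference base matching neither allele is flagged, not dropped
  mm <- tibble::tibble(seq_id = "chrA", pos = 5, allele1 = "G", allele2 = "C")
  # allele G completes nothing; C gives CCCCCCT (no match) -> no occurrence
  expect_identical(nrow(find_motif_occurrences_with_snp(ref, motif, mm)), 0L)
  # reference carries A at the SNP, matching neither allele; allele T
  # still completes the motif, so the occurrence is flagged, not dropped
  ref_mm <- c(chrA = "AACCACCCTAA")
  mm2 <- tibble::tibble(seq_id = "chrA", pos = 5, allele1 = "G", allele2 = "T")
  occ2 <- find_motif_occurrences_with_snp(ref_mm, motif, mm2)
  expect_identical(nrow(occ2), 1L)
  expect_true(occ2$ref_mismatch)
  expect_identical(occ2$preserving_allele, "T")
})

test_that("strand duality: scanning the reverse-complemented reference swaps strands", {
  motif <- "CCTCCCT"
  ref <- c(chrA = "AACCTCCCTAAGTC")
  L <- unname(nchar(ref))
  snps <- tibble::tibble(seq_id = "chrA", pos = 5, allele1 = "T",
                         allele2 = "C")
  occ <- find_motif_occurrences_with_snp(ref, motif, snps)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(ref)))
  names(rc) <- "chrA"
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  snps_rc <- tibble::tibble(seq_id = "chrA", pos = L - snps$pos + 1,
                            allele1 = unname(comp[snps$allele1]),
                            allele2 = unname(comp[snps$allele2]))
  occ_rc <- find_motif_occurrences_with_snp(rc, motif, snps_rc)
  expect_identical(nrow(occ_rc), 1L)
  expect_identical(occ_rc$strand, "-")
  expect_identical(occ_rc$start, L - occ$end + 1L)
  expect_identical(occ_rc$snp_offset, occ$snp_offset)
})

test_that("snp_flank_sequences cuts centered, truncated and degenerate windows", {
  ref <- c(chr1 = random_dna(1, 400, seed = 2))
  snps <- tibble::tibble(seq_id = "chr1", pos = c(200, 11))
  win <- snp_flank_sequences(ref, snps, flank = 50)
  expect_identical(nchar(win$sequence[1]), 101L)
  expect_identical(substr(win$sequence[1], 51, 51),
                   unname(substr(ref, 200, 200)))
  expect_false(win$truncated[1])
  expect_identical(nchar(win$sequence[2]), 61L) # 10 left + SNP + 50 right
  expect_true(win$truncated[2])
  expect_identical(win$snp_index[2], 11L)
  z <- snp_flank_sequences(ref, snps[1, ], flank = 0)
  expect_identical(nchar(z$sequence), 1L)
  expect_error(snp_flank_sequences(ref, tibble::tibble(seq_id = "chr1",
                                                       pos = 999)),
               "off contig")
})

test_that("plant_motifs inserts motifs spanning the SNP and only in causal records", {
  motif <- "ACTATCGATCTAG"
  win <- snp_flank_sequences(c(chr1 = random_dna(1, 500, seed = 3)),
                             tibble::tibble(seq_id = "chr1",
                                            pos = c(100, 200, 300)),
                             flank = 50)
  out <- plant_motifs(win, motif, causal_ids = win$id[c(1, 3)])
  expect_identical(nchar(out$sequence), rep(101L, 3))
  expect_identical(out$sequence[2], win$sequence[2])
  for (i in c(1, 3)) {
    at <- regexpr(motif, out$sequence[i], fixed = TRUE)
    expect_gt(at, 0)
    expect_true(at <= 51 && at + nchar(motif) - 1 >= 51) # spans the SNP
  }
  # empty causal set leaves the input untouched
  expect_identical(plant_motifs(win, motif, character(0))$sequence,
                   win$sequence)
  # planting then scanning recovers the coordinates
  planted <- out$sequence[1]
  at <- as.integer(regexpr(motif, planted, fixed = TRUE))
  snp_in <- tibble::tibble(seq_id = "w", pos = 51,
                           allele1 = substr(planted, 51, 51),
                           allele2 = setdiff(c("A", "C", "G", "T"),
                                             substr(planted, 51, 51))[1])
  occ <- find_motif_occurrences_with_snp(c(w = planted), motif, snp_in)
  expect_true(any(occ$start == at & occ$strand == "+"))
})

test_that("oops_em recovers a planted motif and keeps a monotone objective", {
  motif <- "ACTATCGATCTAG"
  recs <- random_dna(40, 80, seed = 5)
  set.seed(6)
  for (i in 1:30) {
    at <- sample(80 - 13 + 1, 1)
    substr(recs[i], at, at + 12) <- motif
  }
  fit <- oops_em(recs, width = 13, n_restarts = 6, seed = 7)
  expect_gte(consensus_match(fit, motif), 0.8)
  expect_true(all(diff(fit$objective_trace) > -1e-6))
  expect_equal(colSums(fit$prob), rep(1, 13), tolerance = 1e-9)
  # determinism
  fit2 <- oops_em(recs, width = 13, n_restarts = 6, seed = 7)
  expect_identical(fit$prob, fit2$prob)
})

test_that("oops_em on identical records returns their consensus", {
  rec <- random_dna(1, 40, seed = 9)
  recs <- rep(rec, 20)
  fit <- oops_em(recs, width = 13, n_restarts = 3, seed = 1)
  expect_gte(consensus_match(fit, rec), 0.95)
})

test_that("oops_em rejects impossible widths and tiny corpora", {
  expect_error(oops_em(random_dna(5, 12, seed = 1), width = 13), "width")
  expect_error(oops_em(random_dna(1, 50, seed = 1), width = 10),
               "at least 2")
})

test_that("the top discovered motif localizes two disjointly planted motifs", {
  # With two similar motifs planted in disjoint halves of the corpus, the
  # one-site-per-sequence model blends their instances into the top-rank
  # PWM; the scientific property is that its confident sites land on the
  # planted spans of both motifs, not on background sequence.
  m1 <- "ACTATCGATCTAG"; m2 <- "ATGATGTAATGGT"
  win <- random_dna(40, 101, seed = 31)
  names(win) <- paste0("w", seq_along(win))
  set.seed(32)
  at_v <- integer(40)
  for (i in 1:40) {
    at_v[i] <- 40 + (i %% 8)
    substr(win[i], at_v[i], at_v[i] + 12) <- if (i <= 20) m1 else m2
  }
  ms <- discover_motifs(win, n_motifs = 1, width_min = 10, width_max = 16,
                        min_sites = 10, n_restarts = 8, seed = 4)
  expect_gte(length(ms), 1L)
  top <- ms[[1]]
  st <- top$sites[top$sites$posterior > 0.5, ]
  on_plant <- mapply(function(rec, pos) {
    a <- at_v[rec]
    (min(pos + top$width - 1, a + 12) - max(pos, a) + 1) >= 8
  }, st$record, st$position)
  expect_gte(mean(on_plant), 0.8)
  # sites from both planted subsets are represented
  expect_gte(sum(st$record[on_plant] <= 20), 10)
  expect_gte(sum(st$record[on_plant] > 20), 10)
  # a pure-random corpus yields lower information content
  rnd <- random_dna(40, 101, seed = 33)
  ms_rnd <- discover_motifs(rnd, n_motifs = 1, width_min = 10, width_max = 16,
                            min_sites = 10, n_restarts = 8, seed = 4)
  if (length(ms_rnd) > 0) {
    expect_lt(ms_rnd[[1]]$ic, top$ic)
    expect_lt(max(consensus_match(ms_rnd[[1]], m1),
                  consensus_match(ms_rnd[[1]], m2)), 0.8)
  }
})

test_that("consensus_match has the analytic anchors and strand symmetry", {
  onehot <- function(motif) {
    e <- match(strsplit(motif, "")[[1]], c("A", "C", "G", "T"))
    m <- matrix(0, 4, length(e)); m[cbind(e, seq_along(e))] <- 1
    rownames(m) <- c("A", "C", "G", "T")
    structure(list(prob = m, width = length(e)), class = "pwm")
  }
  expect_equal(consensus_match(onehot("ACGTACGT"), "ACGTACGT"), 1)
  unif <- structure(list(prob = matrix(0.25, 4, 8), width = 8), class = "pwm")
  expect_equal(consensus_match(unif, "ACGTACGT"), 0.25)
  # reverse complement of both arguments leaves the score unchanged
  expect_equal(consensus_match(onehot("AACGTT"), "TTTAAC"),
               consensus_match(onehot("AACGTT"), "GTTAAA"))
  # a shorter consensus fully contained in a wider PWM scores fully
  expect_equal(consensus_match(onehot("AACGTTAC"), "CGTT"), 1)
})

test_that("FASTA and MEME outputs round-trip / parse", {
  recs <- tibble::tibble(id = c("a", "b"), sequence = c("ACGT", "GGGTTT"))
  f <- tempfile(fileext = ".fa")
  write_fasta(recs, f)
  back <- read_fasta(f)
  expect_identical(back$id, recs$id)
  expect_identical(back$sequence, recs$sequence)
  fit <- oops_em(random_dna(6, 30, seed = 2), width = 10, n_restarts = 2,
                 seed = 3)
  mf <- tempfile(fileext = ".txt")
  write_meme_pwm(fit, mf)
  txt <- readLines(mf)
  expect_true(any(grepl("^MEME version", txt)))
  expect_true(any(grepl("letter-probability matrix: alength= 4 w= 10", txt)))
})
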