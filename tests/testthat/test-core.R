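test_that("split_by_allele partitions the rows and respects relabeling", {
  set.seed(21)
  a <- matrix(rbinom(180 * 6, 1, 0.5), 180, 6)
  a[, 3] <- rep(c(0L, 1L), each = 90)
  p <- haplotype_panel(a, sort(sample(2e5, 6)))
  sp <- split_by_allele(p, 3)
  expect_identical(n_haps(sp[["0"]]), 90L)
  expect_identical(n_haps(sp[["1"]]), 90L)
  # row union equals the original rows, no duplicates, order preserved
  expect_identical(sort(c(sp[["0"]]$labels, sp[["1"]]$labels)),
                   sort(p$labels))
  expect_identical(sp[["0"]]$labels, p$labels[a[, 3] == 0])
  # allele relabeling swaps the outputs exactly
  q <- haplotype_panel(a, positions(p))
  q$alleles[, 3] <- 1L - q$alleles[, 3]
  sq <- split_by_allele(q, 3)
  expect_identical(sq[["1"]]$labels, sp[["0"]]$labels)
  expect_identical(sq[["0"]]$labels, sp[["1"]]$labels)
  expect_identical(sq[["1"]]$alleles[, -3], sp[["0"]]$alleles[, -3])
  # monomorphic site cannot be split
  p$alleles[, 2] <- 0L
  expect_error(split_by_allele(p, 2), "monomorphic")
})

test_that("delta_rho implements the normalized difference exactly", {
  expect_equal(delta_rho(3, 1), 0.5)
  expect_equal(delta_rho(5, 0), 1)
  expect_equal(delta_rho(0, 5), -1)
  expect_equal(delta_rho(0, 0), 0)
  x <- runif(50, 0, 10)
  expect_equal(delta_rho(x, x), rep(0, 50))
  expect_error(delta_rho(-1, 2), "non-negative")
})

test_that("identical allele subpopulations give delta 0 and p = 1", {
  set.seed(8)
  base <- matrix(rbinom(12 * 5, 1, 0.5), 12, 5)
  base[, 3] <- rbinom(12, 1, 0.5)
  a <- base[rep(seq_len(12), each = 2), ] # duplicate each row
  a[seq(1, 24, by = 2), 3] <- 0L          # one copy allele 0
  a[seq(2, 24, by = 2), 3] <- 1L          # the twin allele 1
  p <- haplotype_panel(a, sort(sample(2e5, 5)))
  st <- split_test(p, 3, c(positions(p)[2], positions(p)[4]),
                   config = cfg_min(), n_perm = 19, seed = 2)
  expect_identical(st$delta_rho, 0)
  expect_identical(st$p_value, 1)
})

test_that("two-sided p-values are invariant to allele relabeling at the split SNP", {
  p <- oracle_panel(6, 4, split_site = 2, seed0 = 30)
  q <- haplotype_panel(p$alleles, positions(p))
  q$alleles[, 2] <- 1L - q$alleles[, 2]
  hs <- c(positions(p)[1], positions(p)[4])
  st_p <- split_test(p, 2, hs, config = cfg_min(), method = "exhaustive")
  st_q <- split_test(q, 2, hs, config = cfg_min(), method = "exhaustive")
  expect_equal(st_q$delta_rho, -st_p$delta_rho)
  expect_identical(st_q$p_value, st_p$p_value)
})

test_that("Monte-Carlo p approaches the exhaustive p as permutations grow", {
  p <- oracle_panel(6, 4, split_site = 1, seed0 = 77)
  hs <- c(positions(p)[2], positions(p)[4])
  ex <- split_test(p, 1, hs, config = cfg_min(), method = "exhaustive")
  mc <- split_test(p, 1, hs, config = cfg_min(), n_perm = 400, seed = 3)
  expect_lt(abs(mc$p_value - ex$p_value), 0.12)
})

test_that("scan_hotspot filters by MAF and keeps the observed statistic permutation-free", {
  b <- simulate_benchmark(sim_config("desk", n_subsets = 1), seed = 501)
  panel <- b$panels[[1]]
  n_qual <- length(candidate_sites(panel, 0.30))
  sc <- scan_hotspot(panel, HOTSPOT, config = cfg_min(), n_perm = 9, seed = 1)
  expect_identical(nrow(tidy(sc)), n_qual)
  expect_true(all(tidy(sc)$p_value > 0 & tidy(sc)$p_value <= 1))
  expect_true(!is.unsorted(tidy(sc)$position_bp))
  expect_identical(tidy(sc)$n0 + tidy(sc)$n1, rep(n_haps(panel), n_qual))
  # permutation seed changes p but not the observed delta
  sc2 <- scan_hotspot(panel, HOTSPOT, config = cfg_min(), n_perm = 9, seed = 2)
  expect_identical(tidy(sc2)$delta_rho, tidy(sc)$delta_rho)
  expect_identical(tidy(sc2)$rho0, tidy(sc)$rho0)
  # an impossible threshold gives an empty scan with a warning
  expect_warning(empty <- scan_hotspot(panel, HOTSPOT, maf_min = 0.51,
                                       config = cfg_min(), n_perm = 9),
                 "MAF")
  expect_identical(nrow(tidy(empty)), 0L)
  # glance summarizes the table
  g <- glance(sc)
  expect_identical(g$n_candidates, n_qual)
})

test_that("scan tables export with the documented columns", {
  b <- simulate_benchmark(sim_config("desk", n_subsets = 1), seed = 502)
  sc <- scan_hotspot(b$panels[[1]], HOTSPOT, config = cfg_min(), n_perm = 9,
                     seed = 1)
  f <- tempfile(fileext = ".tsv")
  write_scan_tsv(sc, f)
  tab <- read.table(f, header = TRUE, sep = "\t")
  expect_identical(names(tab),
                   c("position", "rs_label", "n0", "n1", "rho0", "rho1",
                     "delta_rho", "p_value", "n_perm", "seed"))
  expect_identical(nrow(tab), nrow(tidy(sc)))
})

test_that("classify_motif_allele follows strengths, ties and flips", {
  res <- structure(list(rho0 = 2, rho1 = 1), class = "split_result")
  occ <- list(preserving_allele = "T", disrupting_allele = "C")
  map <- c("0" = "T", "1" = "C")
  expect_identical(classify_motif_allele(res, occ, map), "positive")
  # swapping which allele preserves flips the class
  occ2 <- list(preserving_allele = "C", disrupting_allele = "T")
  expect_identical(classify_motif_allele(res, occ2, map), "negative")
  # ties are negative by convention
  res_tie <- structure(list(rho0 = 1, rho1 = 1), class = "split_result")
  expect_message(cls <- classify_motif_allele(res_tie, occ, map), "tie")
  expect_identical(cls, "negative")
  # allele mismatch with the panel coding errors
  expect_error(classify_motif_allele(res, list(preserving_allele = "G",
                                               disrupting_allele = "C"), map),
               "coding")
})
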