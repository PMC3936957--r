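test_that("pac_loglik equals brute-force path enumeration on small panels", {
  for (seed in 1:6) {
    n <- sample(3:5, 1)
    L <- sample(2:4, 1)
    p <- random_panel(n, L, seed + 40)
    rho <- exp(runif(L - 1, log(0.05), log(20)))
    expect_equal(pac_loglik(p, rho), brute_pac(p, rho), tolerance = 1e-10)
    ord <- sample(n)
    expect_equal(pac_loglik(p, rho, ordering = ord),
                 brute_pac(p, rho, ordering = ord), tolerance = 1e-10)
  }
})

test_that("two identical haplotypes give a likelihood flat in rho", {
  a <- rbind(c(0L, 1L, 0L, 1L), c(0L, 1L, 0L, 1L))
  p <- haplotype_panel(a, c(1, 5, 9, 20), unit = "kb")
  lls <- vapply(c(0.01, 1, 50), function(r) pac_loglik(p, rep(r, 3)),
                numeric(1))
  expect_equal(max(lls) - min(lls), 0, tolerance = 1e-12)
})

test_that("pac_loglik is invariant under global 0/1 relabeling", {
  p <- random_panel(6, 5, seed = 11)
  q <- haplotype_panel(1L - p$alleles, positions(p))
  rho <- c(0.2, 3, 0.5, 10)
  expect_equal(pac_loglik(p, rho), pac_loglik(q, rho))
})

test_that("estimate_profile is deterministic and respects the grid", {
  p <- random_panel(20, 15, seed = 2)
  cfg <- cfg_light(seed = 9)
  pr1 <- estimate_profile(p, cfg)
  pr2 <- estimate_profile(p, cfg)
  expect_identical(tidy(pr1), tidy(pr2))
  g <- exp(seq(log(cfg$rho_min), log(cfg$rho_max), length.out = cfg$n_grid))
  expect_true(all(vapply(tidy(pr1)$rho_per_kb,
                         function(r) any(abs(log(r) - log(g)) < 1e-9),
                         logical(1))))
  # different ordering seed may differ, but stays reproducible
  pr3 <- estimate_profile(p, cfg_light(seed = 10))
  expect_identical(nrow(tidy(pr3)), nrow(tidy(pr1)))
})

test_that("monomorphic and missing sites are dropped and re-expanded", {
  p <- random_panel(12, 10, seed = 5)
  p$alleles[, 4] <- 1L # monomorphic
  pr <- estimate_profile(p, cfg_light())
  expect_identical(nrow(tidy(pr)), 9L) # full coordinate set
  p$alleles[2, 7] <- NA_integer_
  expect_warning(pr2 <- estimate_profile(p, cfg_light()), "missing")
  expect_identical(nrow(tidy(pr2)), 9L)
})

test_that("duplicating every haplotype leaves the argmax interval unchanged", {
  b <- simulate_benchmark(sim_config("desk", n_subsets = 1), seed = 208)
  p <- b$panels[[1]]
  dup <- haplotype_panel(p$alleles[rep(seq_len(n_haps(p)), 2), ],
                         positions(p))
  cfg <- cfg_light()
  am1 <- which.max(tidy(estimate_profile(p, cfg))$rho_per_kb)
  am2 <- which.max(tidy(estimate_profile(dup, cfg))$rho_per_kb)
  # same interval, or a bordering one (k-dependent switch-rate tolerance)
  expect_lte(abs(am2 - am1), 1)
})

test_that("hotspot_strength integrates rho over the interval", {
  prof <- rec_profile(seq(0, 10000, by = 1000), rep(1, 10))
  expect_equal(hotspot_strength(prof, c(2000, 4000)), 2)
  # one inter-SNP gap
  prof2 <- rec_profile(c(0, 1500, 4000, 9000), c(2, 0.5, 3))
  expect_equal(hotspot_strength(prof2, c(1500, 4000)), 0.5 * 2.5)
  # additivity over a partition
  whole <- hotspot_strength(prof2, c(500, 8000))
  expect_equal(hotspot_strength(prof2, c(500, 4000)) +
                 hotspot_strength(prof2, c(4000, 8000)), whole)
  # linear in rescaling
  prof3 <- rec_profile(c(0, 1500, 4000, 9000), 2 * c(2, 0.5, 3))
  expect_equal(hotspot_strength(prof3, c(500, 8000)), 2 * whole)
  expect_error(hotspot_strength(prof, c(20000, 30000)), "overlap")
})

test_that("detect_hotspots finds rectangular bumps and nothing in flat profiles", {
  pos <- seq(0, 50000, by = 500)
  flat <- rec_profile(pos, rep(0.3, length(pos) - 1))
  expect_identical(nrow(detect_hotspots(flat)), 0L)
  rho <- rep(0.2, length(pos) - 1)
  rho[41:44] <- 2 # 10x background over 2 kb (20000..22000)
  one <- detect_hotspots(rec_profile(pos, rho), fold = 5)
  expect_identical(nrow(one), 1L)
  expect_equal(c(one$start_bp, one$end_bp), c(20000, 22000))
  rho[81:84] <- 2
  two <- detect_hotspots(rec_profile(pos, rho), fold = 5, merge_gap_bp = 1000)
  expect_identical(nrow(two), 2L)
  merged <- detect_hotspots(rec_profile(pos, rho), fold = 5,
                            merge_gap_bp = 50000)
  expect_identical(nrow(merged), 1L)
})

test_that("average_aligned_profiles re-grids and averages correctly", {
  pos <- seq(0, 20000, by = 1000)
  rho <- c(rep(0.1, 9), 5, 5, rep(0.1, 9))
  prof <- rec_profile(pos, rho)
  one <- average_aligned_profiles(list(prof), centers = 10000,
                                  span_bp = 5000, bin_bp = 1000)
  expect_equal(one$mean_rho[one$bin_mid_bp == 500], 5)
  expect_equal(one$mean_rho[one$bin_mid_bp == -4500], 0.1)
  # N copies equal the single re-gridding
  many <- average_aligned_profiles(rep(list(prof), 4), centers = rep(10000, 4),
                                   span_bp = 5000, bin_bp = 1000)
  expect_equal(many$mean_rho, one$mean_rho)
  # mirror-image profiles average to a symmetric profile
  prof_m <- rec_profile(pos, rev(rho))
  both <- average_aligned_profiles(list(prof, prof_m), centers = c(10000, 10000),
                                   span_bp = 5000, bin_bp = 1000)
  expect_equal(both$mean_rho, rev(both$mean_rho))
  expect_error(average_aligned_profiles(list(), numeric(0), 1000, 100),
               "no profiles")
})

test_that("estimated hotspot strength responds monotonically to the simulated crossover rate", {
  levels <- c(0.001, 0.003, 0.01)
  strength <- c(); lev <- c()
  for (li in seq_along(levels)) {
    for (r in 1:5) {
      b <- simulate_benchmark(
        sim_config("desk", p_xover_hot = levels[li], n_subsets = 1),
        seed = 400 + 10 * li + r)
      prof <- estimate_profile(b$panels[[1]], cfg_light())
      strength <- c(strength, hotspot_strength(prof, HOTSPOT))
      lev <- c(lev, levels[li])
    }
  }
  expect_gt(stats::cor(lev, strength, method = "spearman"), 0)
  m <- tapply(strength, lev, mean)
  expect_gt(m[["0.01"]], m[["0.001"]])
})
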