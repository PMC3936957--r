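# Shared fixtures and configurations for the test suite.
#
# Estimator configurations: `cfg_light()` is the desk-scale working
# config (fewer orderings/sweeps than the package default, same grid and
# penalty); `cfg_min()` is the cheapest valid config, used where only the
# exchangeability of the statistic matters (permutation calibration),
# not its accuracy.
cfg_light <- function(seed = 1) {
  estimator_config(n_orderings = 2, max_sweeps = 2, seed = seed)
}
cfg_min <- function(seed = 1) {
  estimator_config(n_orderings = 1, max_sweeps = 1, n_grid = 13, seed = seed)
}

# the true hotspot interval of the simulator presets (bp)
HOTSPOT <- c(99000, 101000)

random_panel <- function(n, L, seed, missing = 0) {
  set.seed(seed)
  a <- matrix(rbinom(n * L, 1L, runif(L, 0.2, 0.8)[rep(seq_len(L), each = n)]),
              n, L)
  if (missing > 0) a[sample(length(a), missing)] <- NA_integer_
  pos <- sort(sample(seq_len(200000), L))
  haplotype_panel(a, pos)
}

# A small panel suitable for exhaustive permutation oracles: the split
# site has n0 zero-alleles and *every* size-(n0, n-n0) split leaves both
# subpanels with at least 2 segregating sites outside the split column
# (which the test statistic excludes), so no estimation can fail
# mid-enumeration.
oracle_panel <- function(n, L, split_site, n0 = n %/% 2, seed0 = 1) {
  for (seed in seq(seed0, seed0 + 20000)) {
    set.seed(seed)
    a <- matrix(rbinom(n * L, 1L, 0.5), n, L)
    if (sum(a[, split_site] == 0L) != n0) next
    a2 <- a[, -split_site, drop = FALSE]
    ok <- TRUE
    for (cols in utils::combn(n, n0, simplify = FALSE)) {
      for (rows in list(cols, setdiff(seq_len(n), cols))) {
        f <- colMeans(a2[rows, , drop = FALSE])
        if (sum(f > 0 & f < 1) < 2) { ok <- FALSE; break }
      }
      if (!ok) break
    }
    if (ok) {
      pos <- sort(sample(seq(5000, 195000, by = 500), L))
      return(haplotype_panel(a, pos))
    }
  }
  stop("no oracle panel found")
}

# Brute-force PAC likelihood by enumerating every copy path (independent
# of the forward algorithm under test).
brute_pac <- function(panel, rho, ordering = seq_len(n_haps(panel)),
                      theta = watterson_theta(n_haps(panel))) {
  A <- panel$alleles[ordering, , drop = FALSE]
  n <- nrow(A); L <- ncol(A)
  d <- diff(panel$positions_kb)
  ll <- L * log(0.5)
  for (k in 2:n) {
    K <- k - 1
    mu <- theta / (2 * (k + theta))
    s <- 1 - exp(-rho * d / k)
    paths <- as.matrix(expand.grid(rep(list(seq_len(K)), L)))
    tot <- 0
    for (p in seq_len(nrow(paths))) {
      path <- paths[p, ]
      pr <- 1 / K
      for (j in seq_len(L)) {
        if (j > 1) {
          pr <- pr * if (path[j] == path[j - 1])
            (1 - s[j - 1]) + s[j - 1] / K else s[j - 1] / K
        }
        pr <- pr * if (A[path[j], j] == A[k, j]) 1 - mu else mu
      }
      tot <- tot + pr
    }
    ll <- ll + log(tot)
  }
  ll
}

# ---- heavy shared fixture: desk-scale benchmark datasets and scans ----
# 10 independent conditioned populations x 5 sampled panels each, every
# panel scanned at the true hotspot. Built once per test run on first use.
.fixture_cache <- new.env(parent = emptyenv())

desk_benchmark <- function() {
  if (!is.null(.fixture_cache$bench)) return(.fixture_cache$bench)
  pops <- lapply(1:10, function(p) {
    simulate_benchmark(sim_config("desk", n_subsets = 5), seed = 7000 + p)
  })
  scans <- list(); causal <- integer(0); pop_of <- integer(0)
  for (p in seq_along(pops)) {
    ci <- pops[[p]]$manifest$causal_index
    for (j in 1:5) {
      scans[[length(scans) + 1]] <- suppressWarnings(scan_hotspot(
        pops[[p]]$panels[[j]], HOTSPOT,
        config = cfg_light(seed = 1), n_perm = 49,
        seed = 8000 + 100 * p + j))
      causal <- c(causal, ci)
      pop_of <- c(pop_of, p)
    }
  }
  .fixture_cache$bench <- list(pops = pops, scans = scans, causal = causal,
                               pop_of = pop_of)
  .fixture_cache$bench
}
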