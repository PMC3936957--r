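#' Estimator configuration
#'
#' Settings for the penalized PAC composite-likelihood profile estimator.
#' The per-interval population recombination rate (rho per kb, i.e. 4Ner
#' scaled) is searched on a log-spaced grid, with a smoothness penalty
#' `smoothing_lambda * sum (delta log rho)^2` coupling adjacent intervals,
#' and the composite likelihood averaged over `n_orderings` random
#' haplotype orderings. The defaults span the dynamic range of human
#' hotspots (roughly 10-100 fold over background).
#'
#' @param rho_min,rho_max grid bounds, per kb (must be positive).
#' @param n_grid number of log-spaced grid values.
#' @param smoothing_lambda penalty weight on squared differences of
#'   adjacent log-rates.
#' @param n_orderings number of random haplotype orderings averaged in the
#'   composite likelihood.
#' @param theta per-site mutation parameter; default `NULL` uses the
#'   Watterson-style value `1 / sum(1/(1:(n-1)))` from the panel.
#' @param max_sweeps maximum coordinate-ascent sweeps over the intervals.
#' @param tol stop when the objective improves by less than this.
#' @param seed integer seed for the random orderings; recorded in outputs.
#' @return An object of class `estimator_config`.
#' @export
estimator_config <- function(rho_min = 1e-2, rho_max = 1e2, n_grid = 25,
                             smoothing_lambda = 1, n_orderings = 10,
                             theta = NULL, max_sweeps = 3, tol = 1e-3,
                             seed = 1) {
  stopifnot(rho_min > 0, rho_max > rho_min, is_count(n_grid), n_grid >= 2,
            smoothing_lambda >= 0, is_count(n_orderings), is_count(max_sweeps),
            tol >= 0, is_count(seed) || seed == 0)
  structure(list(rho_min = rho_min, rho_max = rho_max,
                 n_grid = as.integer(n_grid),
                 smoothing_lambda = smoothing_lambda,
                 n_orderings = as.integer(n_orderings), theta = theta,
                 max_sweeps = as.integer(max_sweeps), tol = tol,
                 seed = as.integer(seed)),
            class = "estimator_config")
}

rho_grid <- function(config) {
  exp(seq(log(config$rho_min), log(config$rho_max),
          length.out = config$n_grid))
}

#' Watterson-style per-site mutation parameter
#'
#' @param n number of haplotypes.
#' @return `1 / sum(1/(1:(n-1)))`.
#' @export
watterson_theta <- function(n) {
  stopifnot(n >= 2)
  1 / sum(1 / seq_len(n - 1))
}

#' PAC composite log-likelihood of a haplotype panel
#'
#' Product-of-approximate-conditionals (haplotype copying) likelihood:
#' haplotype `k` in the ordering is modelled as an imperfect mosaic copy of
#' the `k - 1` haplotypes before it. The copying template switches across
#' interval `j` with probability `1 - exp(-rho_j * d_j / k)` (`d_j` the
#' interval length in kb) and each copied site mismatches with probability
#' `theta / (2 * (k + theta))`. The first haplotype contributes
#' `L * log(1/2)`, a constant in rho.
#'
#' @param panel a complete (no missing calls) [haplotype_panel()].
#' @param interval_rho non-negative rates per kb, one per adjacent-site
#'   interval (`L - 1` values).
#' @param ordering permutation of `1:n` giving the conditioning order;
#'   default identity.
#' @param theta per-site mutation parameter; default Watterson-style.
#' @return Log-likelihood (finite scalar).
#' @export
pac_loglik <- function(panel, interval_rho, ordering = NULL, theta = NULL) {
  stopifnot(inherits(panel, "hap_panel"))
  if (anyNA(panel$alleles))
    abort("pac_loglik requires a complete panel (no missing calls)")
  n <- n_haps(panel); L <- n_sites(panel)
  if (L < 2) abort("need at least 2 sites")
  interval_rho <- as.numeric(interval_rho)
  if (length(interval_rho) != L - 1)
    abort("interval_rho must have length L - 1")
  if (any(interval_rho < 0) || any(!is.finite(interval_rho)))
    abort("interval_rho must be finite and non-negative")
  if (is.null(ordering)) ordering <- seq_len(n)
  stopifnot(length(ordering) == n, !anyDuplicated(ordering),
            all(ordering %in% seq_len(n)))
  if (is.null(theta)) theta <- watterson_theta(n)
  d_kb <- diff(panel$positions_kb)
  pac_loglik_cpp(panel$alleles, d_kb, interval_rho,
                 as.integer(ordering) - 1L, theta)
}

# Fast internal estimator: complete allele matrix + positions in kb.
# Drops monomorphic sites, maximizes the penalized objective on the grid,
# and re-expands to one rate per original interval (dropped sites inherit
# the rate of the enclosing informative interval). Returns the rho vector
# with objective/sweeps/kept attributes.
.estimate_rho <- function(alleles, positions_kb, config,
                          on_degenerate = c("error", "flat")) {
  on_degenerate <- match.arg(on_degenerate)
  n <- nrow(alleles)
  if (n < 2) abort("estimation needs at least 2 haplotypes")
  f <- colMeans(alleles)
  keep <- which(f > 0 & f < 1)
  if (length(keep) < 2) {
    if (on_degenerate == "flat") {
      # no detectable recombination signal: a flat map at the grid floor
      rho <- rep(config$rho_min, length(positions_kb) - 1)
      attr(rho, "objective") <- NA_real_
      attr(rho, "sweeps") <- 0L
      attr(rho, "kept_sites") <- integer(0)
      return(rho)
    }
    abort(paste0("fewer than 2 segregating sites after filtering; ",
                 "supply a panel with more variation"))
  }
  theta <- config$theta %||% watterson_theta(n)
  orderings <- with_seed(config$seed, {
    t(replicate(config$n_orderings, sample.int(n)))
  })
  storage.mode(orderings) <- "integer"
  fit <- estimate_profile_cpp(alleles[, keep, drop = FALSE],
                              diff(positions_kb[keep]),
                              rho_grid(config), config$smoothing_lambda,
                              orderings - 1L, theta,
                              config$max_sweeps, config$tol)
  red_rho <- fit$rho
  L <- length(positions_kb)
  # map each original interval to the informative interval containing it
  mid <- (positions_kb[-L] + positions_kb[-1]) / 2
  idx <- findInterval(mid, positions_kb[keep])
  idx <- pmin(pmax(idx, 1L), length(red_rho))
  rho <- red_rho[idx]
  attr(rho, "objective") <- fit$objective
  attr(rho, "sweeps") <- fit$sweeps
  attr(rho, "kept_sites") <- keep
  rho
}

#' Estimate a recombination-rate profile from a haplotype panel
#'
#' Deterministic coordinate-ascent maximizer of the mean PAC composite
#' log-likelihood over random haplotype orderings, minus a smoothness
#' penalty on adjacent log-rates, searched on a per-interval log grid and
#' initialized at the best constant-rate fit (so a panel carrying no
#' recombination signal stays at its flat optimum instead of inheriting an
#' arbitrary anchor).
#' Monomorphic sites and sites with missing calls carry no copying signal
#' and are dropped before estimation (with a warning for missing data);
#' the returned profile is re-expanded to the full coordinate set, dropped
#' intervals inheriting the rate of the informative interval that spans
#' them. Reproducible bit-for-bit given `(panel, config)`.
#'
#' @param panel a [haplotype_panel()] with at least 2 haplotypes.
#' @param config an [estimator_config()].
#' @return An object of class `rec_profile`: per-interval rates accessible
#'   with [tidy()], plus `positions_bp`, `objective` and the config.
#' @examples
#' sim <- simulate_benchmark(sim_config("desk", n_subsets = 1), seed = 7)
#' prof <- estimate_profile(sim$panels[[1]],
#'                          estimator_config(n_orderings = 2))
#' tidy(prof)
#' @export
estimate_profile <- function(panel, config = estimator_config()) {
  stopifnot(inherits(panel, "hap_panel"), inherits(config, "estimator_config"))
  a <- panel$alleles
  pos_kb <- panel$positions_kb
  miss <- which(colSums(is.na(a)) > 0)
  if (length(miss) > 0) {
    warn(sprintf("dropping %d site(s) with missing calls before estimation",
                 length(miss)))
    if (ncol(a) - length(miss) < 2)
      abort("fewer than 2 complete sites; cannot estimate")
    a <- a[, -miss, drop = FALSE]
    pos_red <- pos_kb[-miss]
  } else pos_red <- pos_kb
  rho_red <- .estimate_rho(a, pos_red, config)
  # re-expand over the original coordinates (missing-dropped sites too)
  L <- length(pos_kb)
  mid <- (pos_kb[-L] + pos_kb[-1]) / 2
  idx <- findInterval(mid, pos_red)
  # intervals of the reduced profile are between consecutive pos_red
  idx <- pmin(pmax(idx, 1L), length(rho_red))
  rho <- as.numeric(rho_red)[idx]
  structure(list(
    intervals = tibble::tibble(
      start_bp = pos_kb[-L] * 1000,
      end_bp = pos_kb[-1] * 1000,
      rho_per_kb = rho
    ),
    positions_bp = pos_kb * 1000,
    objective = attr(rho_red, "objective"),
    sweeps = attr(rho_red, "sweeps"),
    n_haps = n_haps(panel),
    config = config
  ), class = "rec_profile")
}

#' Construct a recombination profile from known rates
#'
#' Builds a `rec_profile` directly from per-interval rates — useful for
#' constructing analytic profiles (e.g. rectangular hotspots) and for
#' importing rates estimated elsewhere.
#'
#' @param positions site positions, strictly increasing.
#' @param interval_rho rates per kb, one per adjacent-site interval.
#' @param unit unit of `positions`: `"bp"` (default) or `"kb"`.
#' @return A `rec_profile`.
#' @export
rec_profile <- function(positions, interval_rho, unit = c("bp", "kb")) {
  unit <- match.arg(unit)
  positions <- as.numeric(positions)
  pos_bp <- if (unit == "kb") positions * 1000 else positions
  interval_rho <- as.numeric(interval_rho)
  if (length(interval_rho) != length(positions) - 1)
    abort("need one rate per adjacent-site interval (length L - 1)")
  if (any(interval_rho < 0) || any(!is.finite(interval_rho)))
    abort("rates must be finite and non-negative")
  if (any(diff(pos_bp) <= 0)) abort("positions must be strictly increasing")
  structure(list(
    intervals = tibble::tibble(
      start_bp = pos_bp[-length(pos_bp)],
      end_bp = pos_bp[-1],
      rho_per_kb = interval_rho
    ),
    positions_bp = pos_bp,
    objective = NA_real_, sweeps = 0L, n_haps = NA_integer_,
    config = estimator_config()
  ), class = "rec_profile")
}

#' @export
print.rec_profile <- function(x, ...) {
  cat(sprintf("<rec_profile> %d intervals over %.1f-%.1f kb (n = %d, seed = %d)\n",
              nrow(x$intervals), min(x$positions_bp) / 1000,
              max(x$positions_bp) / 1000, x$n_haps, x$config$seed))
  cat(sprintf("  rho/kb: median %.3g, max %.3g\n",
              median(x$intervals$rho_per_kb), max(x$intervals$rho_per_kb)))
  invisible(x)
}

#' @export
tidy.rec_profile <- function(x, ...) x$intervals

#' @export
autoplot.rec_profile <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df) +
    ggplot2::geom_step(ggplot2::aes(x = .data$start_bp / 1000,
                                    y = .data$rho_per_kb)) +
    ggplot2::labs(x = "position (kb)", y = expression(rho ~ "per kb")) +
    ggplot2::theme_minimal()
}

#' Hotspot strength: integrated rate over an interval
#'
#' The strength of a hotspot is the integral of the profile over the
#' interval, `sum_j rho_j * overlap_kb_j` — a dimensionless 4Ner total.
#'
#' @param profile a `rec_profile` from [estimate_profile()].
#' @param interval `c(start_bp, end_bp)`; must overlap the profile span.
#' @return Non-negative scalar.
#' @export
hotspot_strength <- function(profile, interval) {
  stopifnot(inherits(profile, "rec_profile"), length(interval) == 2,
            interval[2] > interval[1])
  .strength(profile$intervals$rho_per_kb, profile$positions_bp / 1000,
            interval / 1000)
}

# rho per interval, positions and interval in kb
.strength <- function(rho, pos_kb, interval_kb) {
  lo <- pmax(pos_kb[-length(pos_kb)], interval_kb[1])
  hi <- pmin(pos_kb[-1], interval_kb[2])
  ov <- pmax(hi - lo, 0)
  if (all(ov == 0)) abort("interval does not overlap the profile span")
  sum(rho * ov)
}

#' Detect hotspot intervals in a profile
#'
#' Contiguous runs of intervals whose rate is at least `fold` times the
#' median rate, merged when separated by gaps shorter than `merge_gap_bp`,
#' and filtered to a minimum width.
#'
#' @inheritParams hotspot_strength
#' @param fold fold-over-median threshold (default 5).
#' @param min_width_bp drop called intervals narrower than this.
#' @param merge_gap_bp merge calls separated by gaps at most this wide.
#' @return Tibble with columns `start_bp`, `end_bp`, `peak_rho`,
#'   `strength`; zero rows if nothing exceeds the threshold.
#' @export
detect_hotspots <- function(profile, fold = 5, min_width_bp = 0,
                            merge_gap_bp = 0) {
  stopifnot(inherits(profile, "rec_profile"), fold > 0)
  iv <- profile$intervals
  thr <- fold * median(iv$rho_per_kb)
  empty <- tibble::tibble(start_bp = numeric(), end_bp = numeric(),
                          peak_rho = numeric(), strength = numeric())
  hot <- iv$rho_per_kb >= thr & iv$rho_per_kb > 0
  if (!any(hot)) return(empty)
  r <- rle(hot)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- tibble::tibble(from = starts[r$values], to = ends[r$values])
  out <- list()
  cur <- c(runs$from[1], runs$to[1])
  if (nrow(runs) > 1) {
    for (i in 2:nrow(runs)) {
      gap <- iv$start_bp[runs$from[i]] - iv$end_bp[cur[2]]
      if (gap <= merge_gap_bp) cur[2] <- runs$to[i]
      else { out[[length(out) + 1]] <- cur; cur <- c(runs$from[i], runs$to[i]) }
    }
  }
  out[[length(out) + 1]] <- cur
  res <- purrr::map_dfr(out, function(r2) {
    tibble::tibble(
      start_bp = iv$start_bp[r2[1]], end_bp = iv$end_bp[r2[2]],
      peak_rho = max(iv$rho_per_kb[r2[1]:r2[2]]),
      strength = .strength(profile$intervals$rho_per_kb,
                           profile$positions_bp / 1000,
                           c(iv$start_bp[r2[1]], iv$end_bp[r2[2]]) / 1000)
    )
  })
  res <- dplyr::filter(res, .data$end_bp - .data$start_bp >= min_width_bp)
  dplyr::arrange(res, .data$start_bp)
}

#' Average profiles aligned at given centers
#'
#' Re-grids each profile to common bins centered at 0 (its own center
#' subtracted), then averages per bin, ignoring bins a profile does not
#' cover. Used to overlay allele-specific hotspot shapes across loci.
#'
#' @param profiles list of `rec_profile` objects.
#' @param centers alignment centers in bp, one per profile.
#' @param span_bp half-width of the common grid around each center.
#' @param bin_bp bin width.
#' @return Tibble with `bin_mid_bp` (relative to center), `mean_rho` and
#'   `n_profiles` contributing per bin.
#' @export
average_aligned_profiles <- function(profiles, centers, span_bp, bin_bp) {
  if (length(profiles) == 0) abort("no profiles supplied")
  stopifnot(length(centers) == length(profiles), span_bp > 0, bin_bp > 0)
  edges <- seq(-span_bp, span_bp, by = bin_bp)
  if (length(edges) < 2) abort("span_bp must cover at least one bin")
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  acc <- matrix(NA_real_, nrow = length(profiles), ncol = length(mids))
  for (i in seq_along(profiles)) {
    p <- profiles[[i]]
    stopifnot(inherits(p, "rec_profile"))
    pos <- p$positions_bp - centers[i]
    if (centers[i] < min(p$positions_bp) || centers[i] > max(p$positions_bp))
      abort(sprintf("center %d lies outside its profile span", i))
    rho <- p$intervals$rho_per_kb
    for (b in seq_along(mids)) {
      lo <- pmax(pos[-length(pos)], edges[b])
      hi <- pmin(pos[-1], edges[b + 1])
      ov <- pmax(hi - lo, 0)
      if (sum(ov) > 0) acc[i, b] <- sum(rho * ov) / sum(ov)
    }
  }
  tibble::tibble(
    bin_mid_bp = mids,
    mean_rho = colMeans(acc, na.rm = TRUE),
    n_profiles = colSums(!is.na(acc))
  )
}
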