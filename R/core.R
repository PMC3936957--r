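#' Split a haplotype panel by the alleles of a SNP
#'
#' Partitions the haplotypes into the two allele-defined subpopulations at
#' `site`: the first panel holds carriers of allele 0, the second carriers
#' of allele 1, both preserving the input row order. Haplotypes with a
#' missing call at `site` are excluded (with a message).
#'
#' @param panel a [haplotype_panel()].
#' @param site index of a biallelic site with both alleles present.
#' @return List of two `hap_panel` objects, named `"0"` and `"1"`.
#' @export
split_by_allele <- function(panel, site) {
  stopifnot(inherits(panel, "hap_panel"), is_count(site),
            site <= n_sites(panel))
  a <- panel$alleles[, site]
  if (anyNA(a)) {
    inform(sprintf("excluding %d haplotype(s) with a missing call at site %d",
                   sum(is.na(a)), site))
  }
  r0 <- which(!is.na(a) & a == 0L)
  r1 <- which(!is.na(a) & a == 1L)
  if (length(r0) == 0 || length(r1) == 0)
    abort(sprintf("site %d is monomorphic; cannot split by allele", site))
  list("0" = subset_panel(panel, rows = r0),
       "1" = subset_panel(panel, rows = r1))
}

#' Normalized difference of hotspot strengths
#'
#' `(rho0 - rho1) / (rho0 + rho1)`, the allele-split statistic. Lies in
#' `[-1, 1]`; defined as 0 when both strengths are 0 (no evidence of a
#' difference). Vectorized.
#'
#' @param rho0,rho1 non-negative hotspot strengths.
#' @return Numeric in `[-1, 1]`.
#' @examples
#' delta_rho(3, 1) # 0.5
#' @export
delta_rho <- function(rho0, rho1) {
  if (any(rho0 < 0) || any(rho1 < 0))
    abort("hotspot strengths must be non-negative")
  s <- rho0 + rho1
  out <- ifelse(s == 0, 0, (rho0 - rho1) / s)
  as.numeric(out)
}

# strength of one row subset over the hotspot interval (kb coords).
# "relative": the hotspot's share of the subset's total map length —
# invariant to subset-wide level shifts of the estimated rates, which
# genealogically clustered subsets produce even without any causal
# effect. "integral": the raw rho-distance integral. "peak": the maximum
# interval rate inside the hotspot.
.subset_strength <- function(alleles, pos_kb, rows, interval_kb, config,
                             measure = "relative") {
  rho <- as.numeric(.estimate_rho(alleles[rows, , drop = FALSE], pos_kb,
                                  config, on_degenerate = "flat"))
  s <- .strength(rho, pos_kb, interval_kb)
  switch(measure,
    relative = s / sum(rho * diff(pos_kb)),
    integral = s,
    peak = {
      lo <- pos_kb[-length(pos_kb)]; hi <- pos_kb[-1]
      ov <- pmin(hi, interval_kb[2]) - pmax(lo, interval_kb[1])
      max(rho[ov > 0])
    })
}

#' Permutation test of allele-split association with a hotspot
#'
#' Computes the observed statistic `delta_rho(rho0, rho1)` from the allele
#' split at `site` (each subpopulation's recombination profile is
#' estimated independently and summarized over `hotspot_interval` by the
#' chosen strength measure), then
#' compares it against the null distribution of the same statistic under
#' random splits of the haplotypes into pseudo-populations of the observed
#' sizes `(n0, n1)`. The p-value uses the add-one estimator
#' `(1 + #permutations at least as extreme) / (n_perm + 1)`, so it is never
#' exactly zero. Reproducible given `seed`; every estimation (observed and
#' permuted) uses the identical estimator configuration. A subpanel with
#' fewer than two segregating sites carries no recombination signal and is
#' treated as a flat map at the grid floor (its relative strength is then
#' the hotspot's share of the window length); the same convention applies
#' to every permuted split, keeping the comparison like-for-like.
#'
#' @param panel a [haplotype_panel()].
#' @param site candidate SNP index (should pass the MAF filter).
#' @param hotspot_interval `c(start_bp, end_bp)` of the hotspot whose
#'   strength is compared.
#' @param config an [estimator_config()] used for every profile estimate.
#' @param n_perm number of random splits (ignored for
#'   `method = "exhaustive"`).
#' @param seed integer seed for the permutation draws.
#' @param method `"sample"` (Monte-Carlo, default) or `"exhaustive"`
#'   (enumerate all distinct splits; only sensible for small panels).
#' @param alternative `"two.sided"` (default, on `|delta rho|`) or
#'   `"greater"` (directional, for the motif-disruption use case).
#' @param strength hotspot-strength measure entering `delta_rho`:
#'   `"relative"` (default; the hotspot interval's share of the
#'   subpopulation's total integrated map length — robust to
#'   subpopulation-wide level shifts of the estimated rates, which
#'   genealogically clustered subsets produce even in the absence of any
#'   causal effect), `"integral"` (the raw rho-distance integral, as in
#'   [hotspot_strength()]) or `"peak"` (maximum interval rate inside the
#'   hotspot).
#' @return An object of class `split_result`; see [tidy()] for the one-row
#'   summary. Contains the full permutation sample in `null_deltas`.
#' @export
split_test <- function(panel, site, hotspot_interval,
                       config = estimator_config(), n_perm = 200, seed = 1,
                       method = c("sample", "exhaustive"),
                       alternative = c("two.sided", "greater"),
                       strength = c("relative", "integral", "peak")) {
  method <- match.arg(method)
  alternative <- match.arg(alternative)
  strength <- match.arg(strength)
  stopifnot(inherits(panel, "hap_panel"), is_count(site),
            site <= n_sites(panel), length(hotspot_interval) == 2)
  a <- panel$alleles[, site]
  keep <- which(!is.na(a))
  if (length(keep) < n_haps(panel)) {
    inform(sprintf("excluding %d haplotype(s) missing at site %d",
                   n_haps(panel) - length(keep), site))
    panel <- subset_panel(panel, rows = keep)
    a <- a[keep]
  }
  n <- length(a)
  r0 <- which(a == 0L)
  n0 <- length(r0); n1 <- n - n0
  if (n0 == 0 || n1 == 0)
    abort(sprintf("site %d is monomorphic; cannot split by allele", site))
  # The tested site's own column is excluded from every estimation:
  # within the observed allele split it is monomorphic (no information),
  # and leaving it in the permuted splits only would bias the null.
  alleles <- panel$alleles[, -site, drop = FALSE]
  pos_kb <- panel$positions_kb[-site]
  interval_kb <- as.numeric(hotspot_interval) / 1000
  stat <- function(rows0, what) {
    rows0 <- sort(rows0)
    rows1 <- setdiff(seq_len(n), rows0)
    tryCatch({
      s0 <- .subset_strength(alleles, pos_kb, rows0, interval_kb, config,
                             strength)
      s1 <- .subset_strength(alleles, pos_kb, rows1, interval_kb, config,
                             strength)
      c(s0, s1)
    }, error = function(e) {
      abort(sprintf("estimation failed for %s: %s", what, conditionMessage(e)),
            parent = e)
    })
  }
  obs <- stat(r0, "the observed allele split")
  d_obs <- delta_rho(obs[1], obs[2])
  if (method == "exhaustive") {
    sets <- combn(n, n0)
    if (n0 == n1 && alternative == "two.sided") {
      sets <- sets[, sets[1, ] == 1L, drop = FALSE]
    }
    splits <- lapply(seq_len(ncol(sets)), function(i) sets[, i])
    n_perm <- length(splits)
  } else {
    splits <- with_seed(seed, {
      lapply(seq_len(n_perm), function(i) sample.int(n, n0))
    })
  }
  if (abs(d_obs) < 1e-9) d_obs <- 0 # floating-point dust on an exact tie
  null_deltas <- vapply(seq_along(splits), function(b) {
    s <- stat(splits[[b]], sprintf("permutation %d", b))
    delta_rho(s[1], s[2])
  }, numeric(1))
  # compare at 1e-9 resolution: equal true statistics must count as ties
  # regardless of arithmetic noise
  exceed <- if (alternative == "two.sided") {
    sum(round(abs(null_deltas), 9) >= round(abs(d_obs), 9))
  } else {
    sum(round(null_deltas, 9) >= round(d_obs, 9))
  }
  p <- (1 + exceed) / (n_perm + 1)
  structure(list(
    site = as.integer(site),
    position_bp = positions(panel, "bp")[site],
    n0 = n0, n1 = n1,
    rho0 = obs[1], rho1 = obs[2],
    delta_rho = d_obs,
    p_value = p,
    n_permutations = as.integer(n_perm),
    null_deltas = null_deltas,
    method = method,
    alternative = alternative,
    strength = strength,
    hotspot_interval = as.numeric(hotspot_interval),
    seed = as.integer(seed)
  ), class = "split_result")
}

#' @export
print.split_result <- function(x, ...) {
  cat(sprintf(
    "<split_result> site %d @ %.0f bp  (%d/%d haplotypes)\n  rho0 = %.4g, rho1 = %.4g, delta_rho = %.4f, p = %.4g (%d perms, %s)\n",
    x$site, x$position_bp, x$n0, x$n1, x$rho0, x$rho1, x$delta_rho,
    x$p_value, x$n_permutations, x$alternative))
  invisible(x)
}

#' @export
tidy.split_result <- function(x, ...) {
  tibble::tibble(
    site = x$site, position_bp = x$position_bp, n0 = x$n0, n1 = x$n1,
    rho0 = x$rho0, rho1 = x$rho1, delta_rho = x$delta_rho,
    p_value = x$p_value, n_perm = x$n_permutations, seed = x$seed
  )
}

#' @export
glance.split_result <- function(x, ...) {
  tibble::tibble(
    p_value = x$p_value, delta_rho = x$delta_rho,
    n_perm = x$n_permutations, alternative = x$alternative,
    null_mean = mean(x$null_deltas), null_sd = stats::sd(x$null_deltas)
  )
}

#' Scan every qualifying SNP for association with a hotspot
#'
#' Runs [split_test()] on every site whose minor allele frequency is at
#' least `maf_min` (default 0.30), producing one row per candidate SNP,
#' sorted by position. The whole-panel recombination profile is estimated
#' once and stored for display/export.
#'
#' @inheritParams split_test
#' @param maf_min candidate MAF threshold.
#' @return An object of class `hotspot_scan`; [tidy()] returns the
#'   per-SNP table, [glance()] a one-row summary.
#' @export
scan_hotspot <- function(panel, hotspot_interval, maf_min = 0.30,
                         config = estimator_config(), n_perm = 200, seed = 1,
                         alternative = c("two.sided", "greater"),
                         strength = c("relative", "integral", "peak")) {
  alternative <- match.arg(alternative)
  strength <- match.arg(strength)
  stopifnot(inherits(panel, "hap_panel"))
  cand <- candidate_sites(panel, maf_min)
  profile <- estimate_profile(panel, config)
  if (length(cand) == 0) {
    warn("no sites pass the MAF filter; returning an empty scan")
    results <- tibble::tibble(
      site = integer(), position_bp = numeric(), n0 = integer(),
      n1 = integer(), rho0 = numeric(), rho1 = numeric(),
      delta_rho = numeric(), p_value = numeric(), n_perm = integer(),
      seed = integer())
  } else {
    seeds <- derive_seeds(seed, length(cand))
    results <- purrr::map2_dfr(cand, seeds, function(s, sd) {
      tryCatch(
        tidy(split_test(panel, s, hotspot_interval, config = config,
                        n_perm = n_perm, seed = sd,
                        alternative = alternative, strength = strength)),
        error = function(e) {
          warn(sprintf("candidate site %d skipped (estimation failure): %s",
                       s, conditionMessage(e)))
          NULL
        })
    })
    results <- dplyr::arrange(results, .data$position_bp)
  }
  structure(list(
    results = results,
    profile = profile,
    hotspot_interval = as.numeric(hotspot_interval),
    maf_min = maf_min,
    alternative = alternative,
    strength = strength,
    n_perm = as.integer(n_perm),
    seed = as.integer(seed),
    panel_hash = rlang::hash(panel),
    config_hash = rlang::hash(config)
  ), class = "hotspot_scan")
}

#' @export
print.hotspot_scan <- function(x, ...) {
  cat(sprintf("<hotspot_scan> %d candidate SNPs (MAF >= %.2f), hotspot %.1f-%.1f kb\n",
              nrow(x$results), x$maf_min, x$hotspot_interval[1] / 1000,
              x$hotspot_interval[2] / 1000))
  if (nrow(x$results) > 0)
    cat(sprintf("  min p = %.4g at %.0f bp; %d significant at p < 0.05\n",
                min(x$results$p_value),
                x$results$position_bp[which.min(x$results$p_value)],
                sum(x$results$p_value < 0.05)))
  invisible(x)
}

#' @export
tidy.hotspot_scan <- function(x, ...) x$results

#' @export
glance.hotspot_scan <- function(x, ...) {
  tibble::tibble(
    n_candidates = nrow(x$results),
    n_significant = sum(x$results$p_value < 0.05),
    min_p = if (nrow(x$results)) min(x$results$p_value) else NA_real_,
    top_position_bp = if (nrow(x$results))
      x$results$position_bp[which.min(x$results$p_value)] else NA_real_,
    maf_min = x$maf_min, n_perm = x$n_perm, seed = x$seed
  )
}

#' @export
autoplot.hotspot_scan <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position_bp / 1000,
                                   y = -log10(.data$p_value))) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = -log10(0.05), linetype = 2) +
    ggplot2::annotate("rect", xmin = object$hotspot_interval[1] / 1000,
                      xmax = object$hotspot_interval[2] / 1000,
                      ymin = -Inf, ymax = Inf, alpha = 0.15) +
    ggplot2::labs(x = "position (kb)", y = expression(-log[10] ~ p)) +
    ggplot2::theme_minimal()
}

#' Export a scan table as TSV
#'
#' Columns: `position`, `rs_label`, `n0`, `n1`, `rho0`, `rho1`,
#' `delta_rho`, `p_value`, `n_perm`, `seed`.
#'
#' @param scan a `hotspot_scan`.
#' @param path output file.
#' @param labels optional rs labels, one per scan row.
#' @return Invisibly, the exported data frame.
#' @export
write_scan_tsv <- function(scan, path, labels = NULL) {
  stopifnot(inherits(scan, "hotspot_scan"))
  df <- scan$results
  out <- data.frame(
    position = df$position_bp,
    rs_label = labels %||% rep(NA_character_, nrow(df)),
    n0 = df$n0, n1 = df$n1, rho0 = df$rho0, rho1 = df$rho1,
    delta_rho = df$delta_rho, p_value = df$p_value,
    n_perm = df$n_perm, seed = df$seed
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' Classify a SNP as motif-preserving-positive or negative
#'
#' A hotspot-SNP pair is "positive" when the allele preserving the motif
#' has the higher estimated hotspot strength than the allele disrupting
#' it, "negative" otherwise. Ties are classified negative (with a
#' message), since they carry no evidence that the intact motif
#' stimulates the hotspot.
#'
#' @param result a [split_test()] result at the SNP.
#' @param occurrence one motif occurrence (a row of
#'   [find_motif_occurrences_with_snp()] output) at the same SNP.
#' @param allele_map named character vector mapping panel allele codes to
#'   bases, e.g. `c("0" = "T", "1" = "C")`.
#' @return `"positive"` or `"negative"`.
#' @export
classify_motif_allele <- function(result, occurrence, allele_map) {
  stopifnot(inherits(result, "split_result"))
  occurrence <- as.list(occurrence)
  stopifnot(!is.null(occurrence$preserving_allele),
            !is.null(occurrence$disrupting_allele))
  if (!all(c("0", "1") %in% names(allele_map)))
    abort("allele_map must name codes '0' and '1'")
  pres <- occurrence$preserving_allele
  disr <- occurrence$disrupting_allele
  if (!all(c(pres, disr) %in% allele_map) ||
      !setequal(c(pres, disr), unname(allele_map)))
    abort("occurrence alleles do not match the panel allele coding")
  pres_code <- names(allele_map)[match(pres, allele_map)]
  s_pres <- if (pres_code == "0") result$rho0 else result$rho1
  s_disr <- if (pres_code == "0") result$rho1 else result$rho0
  if (s_pres == s_disr) {
    inform("equal strengths under both alleles; tie classified negative")
    return("negative")
  }
  if (s_pres > s_disr) "positive" else "negative"
}
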