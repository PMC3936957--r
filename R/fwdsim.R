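#' Simulation configuration
#'
#' Parameters of the forward-time diploid Wright-Fisher benchmark
#' simulator. A population of `pop_size` diploids evolves for
#' `generations` non-overlapping generations over a `window_length_bp`
#' region carrying `n_sites` biallelic SNPs. A hotspot sits at the window
#' center: each transmitted gamete experiences at most one crossover, with
#' probability `p_xover_hot` per meiosis when the hot allele of the causal
#' SNP is present and `p_xover_background` otherwise; the crossover
#' position is drawn from a Normal centered at the hotspot (sd defaulting
#' to half the hotspot width), truncated to the window. "Present" is read
#' at the transmitted segment by default (`penetrance = "cis"`): the donor
#' haplotype — the one contributing the causal-site side of the gamete —
#' determines the rate, so a gamete's crossover history is linked to the
#' causal allele it transmits with the full hot/cold contrast, the regime
#' in which allele-split mapping is informative. Parent-genotype readings
#' (`"dominant"`: any hot allele in the parent; `"additive"`: heterozygote
#' intermediate) are selectable; once the hot allele is common they
#' decouple a gamete's allele from its crossover history almost entirely. The hot allele starts near fixation
#' (`init_hot_freq`) and is driven to `final_hot_freq_target` by genic
#' selection against it (the forward-time analogue of hotspot self-erosion
#' via biased gene conversion), with rejection conditioning on the
#' achieved final frequency. The default `"controlled"` mechanism sizes
#' the per-generation coefficient proportionally to the logit distance of
#' the current frequency from the target (gain `control_gain`, default
#' `10 / generations`, coefficient capped at 0.5), so the path descends to
#' the target and stabilizes there; a constant-coefficient mode
#' (`"selection"`) and a neutral mode (`"drift"`) are selectable.
#'
#' The `"table1"` preset is the full benchmark scale (5000 diploids, 3000
#' generations, 200 SNPs, subsets of 90 individuals = 180 haplotypes); the
#' `"desk"` preset (500 diploids, 300 generations, 40 SNPs, subsets of 45
#' individuals = 90 haplotypes) is the scaled twin used throughout the
#' test suite.
#'
#' @param preset `"table1"` (default) or `"desk"`.
#' @param pop_size,generations,window_length_bp,n_sites,causal_pos_bp,hotspot_center_bp,hotspot_width_bp,p_xover_background,p_xover_hot,xover_sd_bp,init_hot_freq,final_hot_freq_target,final_tol,n_subsets,subset_individuals
#'   overrides of the preset values; see Details above.
#' @param xover_dist `"normal"` (hotspot) or `"uniform"` (flat crossover
#'   density over the window, the no-hotspot control).
#' @param penetrance `"cis"` (default: rate keyed to the donor
#'   haplotype's causal allele), `"dominant"` (raised when the parent
#'   carries >= 1 hot allele) or `"additive"` (heterozygote intermediate).
#' @param mechanism `"controlled"` (default, see above), `"selection"`
#'   (constant coefficient sized to traverse the logit path in
#'   expectation) or `"drift"` (neutral causal site). Every mode is
#'   followed by rejection conditioning in [run_conditioned()].
#' @param selection_s genic selection coefficient against the hot allele
#'   for the `"selection"` mode; default computed from the frequency path.
#' @param control_gain proportional gain of the `"controlled"` mechanism;
#'   default `10 / generations`.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(preset = c("table1", "desk"),
                       pop_size = NULL, generations = NULL,
                       window_length_bp = 200000, n_sites = NULL,
                       causal_pos_bp = 100000, hotspot_center_bp = 100000,
                       hotspot_width_bp = 2000,
                       p_xover_background = 0.001, p_xover_hot = 0.01,
                       xover_sd_bp = NULL,
                       xover_dist = c("normal", "uniform"),
                       penetrance = c("cis", "dominant", "additive"),
                       init_hot_freq = 0.99, final_hot_freq_target = 0.50,
                       final_tol = 0.05,
                       mechanism = c("controlled", "selection", "drift"),
                       selection_s = NULL, control_gain = NULL,
                       n_subsets = 10, subset_individuals = NULL) {
  preset <- match.arg(preset)
  xover_dist <- match.arg(xover_dist)
  penetrance <- match.arg(penetrance)
  mechanism <- match.arg(mechanism)
  defaults <- switch(preset,
    table1 = list(pop_size = 5000, generations = 3000, n_sites = 200,
                  subset_individuals = 90),
    desk = list(pop_size = 500, generations = 300, n_sites = 40,
                subset_individuals = 45))
  pop_size <- pop_size %||% defaults$pop_size
  generations <- generations %||% defaults$generations
  n_sites <- n_sites %||% defaults$n_sites
  subset_individuals <- subset_individuals %||% defaults$subset_individuals
  xover_sd_bp <- xover_sd_bp %||% (hotspot_width_bp / 2)
  stopifnot(p_xover_background >= 0, p_xover_background <= 1,
            p_xover_hot >= 0, p_xover_hot <= 1,
            causal_pos_bp > 0, causal_pos_bp < window_length_bp,
            subset_individuals <= pop_size, n_sites >= 2)
  if (!is.na(init_hot_freq))
    stopifnot(init_hot_freq > 0, init_hot_freq < 1)
  if (mechanism == "selection" && is.null(selection_s)) {
    selection_s <- if (is.na(init_hot_freq)) 0 else
      (stats::qlogis(init_hot_freq) - stats::qlogis(final_hot_freq_target)) /
        generations
  }
  control_gain <- control_gain %||% (10 / generations)
  structure(list(
    preset = preset, pop_size = as.integer(pop_size),
    generations = as.integer(generations),
    window_length_bp = window_length_bp, n_sites = as.integer(n_sites),
    causal_pos_bp = causal_pos_bp, hotspot_center_bp = hotspot_center_bp,
    hotspot_width_bp = hotspot_width_bp,
    p_xover_background = p_xover_background, p_xover_hot = p_xover_hot,
    xover_sd_bp = xover_sd_bp, xover_dist = xover_dist,
    penetrance = penetrance,
    init_hot_freq = init_hot_freq,
    final_hot_freq_target = final_hot_freq_target, final_tol = final_tol,
    mechanism = mechanism, selection_s = selection_s %||% 0,
    control_gain = control_gain,
    n_subsets = as.integer(n_subsets),
    subset_individuals = as.integer(subset_individuals)
  ), class = "sim_config")
}

#' Initialize a diploid population
#'
#' Sites get integer bp positions drawn uniformly over the window (the
#' causal SNP exactly at `causal_pos_bp`); non-causal initial allele-1
#' frequencies are independent uniform(0.1, 0.9) draws and haplotypes are
#' drawn site-independently (standing variation with no initial LD — LD
#' subsequently accumulates by drift). The causal site starts at
#' `init_hot_freq` (hot allele coded 1); `init_hot_freq = NA` makes the
#' causal site exchangeable with the rest (the null configuration).
#'
#' @param config a [sim_config()].
#' @param seed integer seed; two runs with equal seeds are identical.
#' @return An object of class `wf_population`.
#' @export
initialize_population <- function(config, seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed, {
    L <- config$n_sites
    N <- config$pop_size
    others <- sort(sample(setdiff(seq_len(config$window_length_bp - 1L),
                                  as.integer(config$causal_pos_bp)),
                          L - 1L))
    pos <- sort(c(others, as.integer(config$causal_pos_bp)))
    ci <- which(pos == as.integer(config$causal_pos_bp))
    freq <- runif(L, 0.1, 0.9)
    if (!is.na(config$init_hot_freq)) freq[ci] <- config$init_hot_freq
    haps <- vapply(freq, function(f) rbinom(2L * N, 1L, f),
                   integer(2L * N))
    storage.mode(haps) <- "integer"
    structure(list(
      haps = haps, positions_bp = as.numeric(pos), causal_index = ci,
      config = config, generation = 0L,
      freq_trace = mean(haps[, ci])
    ), class = "wf_population")
  })
}

#' @export
print.wf_population <- function(x, ...) {
  cat(sprintf("<wf_population> %d diploids x %d sites, generation %d, hot-allele freq %.3f\n",
              nrow(x$haps) / 2, ncol(x$haps), x$generation,
              tail(x$freq_trace, 1)))
  invisible(x)
}

# crossover probability per gamete; `donor_allele` is the causal allele
# of the haplotype donating the causal-site side, `dosage` the parent's
# hot-allele count
.xover_prob <- function(dosage, donor_allele, config) {
  switch(config$penetrance,
    cis = ifelse(donor_allele == 1L, config$p_xover_hot,
                 config$p_xover_background),
    dominant = ifelse(dosage > 0, config$p_xover_hot,
                      config$p_xover_background),
    additive = c(config$p_xover_background,
                 (config$p_xover_background + config$p_xover_hot) / 2,
                 config$p_xover_hot)[dosage + 1L])
}

# vectorized truncated draw of crossover positions
.xover_positions <- function(n, config) {
  if (config$xover_dist == "uniform")
    return(runif(n, 0, config$window_length_bp))
  flo <- pnorm(0, config$hotspot_center_bp, config$xover_sd_bp)
  fhi <- pnorm(config$window_length_bp, config$hotspot_center_bp,
               config$xover_sd_bp)
  qnorm(runif(n, flo, fhi), config$hotspot_center_bp, config$xover_sd_bp)
}

#' One meiosis: transmit a gamete from a diploid parent
#'
#' A fair coin picks the donor haplotype. With the crossover probability
#' given by the penetrance mode (`"cis"`: `p_xover_hot` when the donor
#' carries the hot allele at the causal SNP, else background;
#' `"dominant"`/`"additive"`: keyed to the parent's genotype) a single
#' crossover occurs at a position drawn from the truncated
#' Normal(hotspot_center, xover_sd) (or uniform, per `xover_dist`); the
#' gamete is then the donor haplotype on the causal-site side of the
#' crossover and the homolog on the far side. Without a crossover the
#' donor haplotype is transmitted intact. Uses the current RNG stream.
#'
#' @param parent 2 x L integer matrix, the parent's two haplotypes.
#' @param config a [sim_config()].
#' @param positions_bp site positions (bp), length L.
#' @param causal_index column index of the causal SNP.
#' @return Integer gamete of length L with attributes `crossover`
#'   (logical) and `xover_pos` (bp or `NA`).
#' @export
meiosis <- function(parent, config, positions_bp, causal_index) {
  dosage <- sum(parent[, causal_index])
  first <- if (runif(1) < 0.5) 1L else 2L
  p <- .xover_prob(dosage, parent[first, causal_index], config)
  causal_pos <- positions_bp[causal_index]
  if (runif(1) < p) {
    xpos <- .xover_positions(1L, config)
    g <- parent[first, ]
    other <- 3L - first
    swap_side <- if (causal_pos <= xpos) positions_bp > xpos
                 else positions_bp <= xpos
    g[swap_side] <- parent[other, swap_side]
    attr(g, "crossover") <- TRUE
    attr(g, "xover_pos") <- xpos
  } else {
    g <- parent[first, ]
    attr(g, "crossover") <- FALSE
    attr(g, "xover_pos") <- NA_real_
  }
  g
}

#' Evolve a population forward in time
#'
#' Non-overlapping generations: each offspring is formed from two distinct
#' parents drawn (with fitness weights under the selection mechanism:
#' weight `(1 - s)^dosage` in the hot allele) uniformly at random, each
#' transmitting one gamete via [meiosis()] (vectorized internally).
#' Population size stays constant; the causal-allele frequency trace is
#' appended every generation. A run in which the causal allele fixes or is
#' lost is flagged (attribute `fixed`), never silently restarted.
#'
#' @param pop a [initialize_population()] result.
#' @param config a [sim_config()] (defaults to the population's).
#' @param generations number of generations (defaults to the config's).
#' @param seed integer seed.
#' @return The evolved `wf_population`.
#' @export
evolve <- function(pop, config = pop$config,
                   generations = config$generations, seed = 1) {
  stopifnot(inherits(pop, "wf_population"))
  N <- config$pop_size
  L <- ncol(pop$haps)
  ci <- pop$causal_index
  pos <- pop$positions_bp
  haps <- pop$haps
  trace <- numeric(generations)
  with_seed(seed, {
    for (g in seq_len(generations)) {
      dosage <- haps[seq(1L, 2L * N, by = 2L), ci] +
        haps[seq(2L, 2L * N, by = 2L), ci]
      s_now <- if (config$mechanism == "selection") {
        config$selection_s
      } else if (config$mechanism == "controlled") {
        p <- mean(dosage) / 2
        if (p <= 0 || p >= 1) 0 else
          max(min(config$control_gain *
                    (stats::qlogis(p) -
                       stats::qlogis(config$final_hot_freq_target)),
                  0.5), -0.5)
      } else 0
      w <- if (s_now != 0) (1 - s_now)^dosage else NULL
      mom <- sample.int(N, N, replace = TRUE, prob = w)
      dad <- sample.int(N, N, replace = TRUE, prob = w)
      same <- which(mom == dad)
      while (length(same) > 0) {
        dad[same] <- sample.int(N, length(same), replace = TRUE, prob = w)
        same <- same[mom[same] == dad[same]]
      }
      parent <- as.vector(rbind(mom, dad)) # gamete i from parent[i]
      swap <- as.integer(runif(2L * N) < 0.5)
      rowA <- 2L * parent - 1L + swap # donor haplotype
      rowB <- 2L * parent - swap
      pxo <- .xover_prob(dosage[parent], haps[rowA, ci], config)
      xo <- runif(2L * N) < pxo
      G <- haps[rowA, , drop = FALSE]
      if (any(xo)) {
        sub <- which(xo)
        xpos <- .xover_positions(length(sub), config)
        B <- haps[rowB[sub], , drop = FALSE]
        Gs <- G[sub, , drop = FALSE]
        # homolog takes over on the side of the crossover away from the
        # causal site
        donor_keeps_left <- pos[ci] <= xpos
        right <- outer(xpos, pos, `<`)
        take <- right
        take[!donor_keeps_left, ] <- !right[!donor_keeps_left, , drop = FALSE]
        Gs[take] <- B[take]
        G[sub, ] <- Gs
      }
      haps <- G
      trace[g] <- mean(haps[, ci])
    }
  })
  pop$haps <- haps
  pop$generation <- pop$generation + generations
  pop$freq_trace <- c(pop$freq_trace, trace)
  attr(pop, "fixed") <- any(pop$freq_trace %in% c(0, 1))
  pop
}

#' Run the simulator conditioned on the final hot-allele frequency
#'
#' Repeats [initialize_population()] + [evolve()] with fresh sub-seeds
#' derived from `seed` until the final causal-allele frequency lies within
#' `final_hot_freq_target +/- final_tol`, returning the first accepted run
#' (attributes record the attempts). Errors after `max_attempts`, listing
#' every attempted seed and final frequency.
#'
#' @param config a [sim_config()].
#' @param seed master seed.
#' @param max_attempts give up after this many rejected runs.
#' @return An accepted `wf_population` with attributes `attempts` and
#'   `accepted_seed`.
#' @export
run_conditioned <- function(config, seed = 1, max_attempts = 50) {
  stopifnot(inherits(config, "sim_config"))
  seeds <- derive_seeds(seed, max_attempts)
  finals <- numeric(0)
  for (i in seq_len(max_attempts)) {
    sub <- derive_seeds(seeds[i], 2)
    pop <- initialize_population(config, sub[1])
    pop <- evolve(pop, config, seed = sub[2])
    f <- tail(pop$freq_trace, 1)
    finals <- c(finals, f)
    if (abs(f - config$final_hot_freq_target) <= config$final_tol) {
      attr(pop, "attempts") <- i
      attr(pop, "accepted_seed") <- seeds[i]
      attr(pop, "attempt_finals") <- finals
      return(pop)
    }
  }
  abort(sprintf(
    "no run reached final frequency %.2f +/- %.2f in %d attempts (seeds %s; finals %s)",
    config$final_hot_freq_target, config$final_tol, max_attempts,
    paste(seeds, collapse = ","),
    paste(sprintf("%.3f", finals), collapse = ",")))
}

#' Sample benchmark haplotype panels from a population
#'
#' Draws `n_subsets` panels, each of `subset_individuals` diploids sampled
#' without replacement (within a subset), i.e. `2 * subset_individuals`
#' haplotypes. Monomorphic sites are retained — filtering is the
#' analysis's job.
#'
#' @param pop an evolved `wf_population`.
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return List of [haplotype_panel()] objects.
#' @export
sample_panels <- function(pop, config = pop$config, seed = 1) {
  stopifnot(inherits(pop, "wf_population"))
  N <- nrow(pop$haps) / 2
  if (config$subset_individuals > N)
    abort("subset larger than the population")
  seeds <- derive_seeds(seed, config$n_subsets)
  lapply(seq_len(config$n_subsets), function(s) {
    with_seed(seeds[s], {
      idx <- sample.int(N, config$subset_individuals)
      rows <- as.vector(rbind(2L * idx - 1L, 2L * idx))
      labels <- as.vector(rbind(paste0("ind", idx, "_a"),
                                paste0("ind", idx, "_b")))
      haplotype_panel(pop$haps[rows, , drop = FALSE], pop$positions_bp,
                      labels = labels, unit = "bp")
    })
  })
}

#' Simulate a full benchmark: conditioned run plus sampled panels
#'
#' @param config a [sim_config()].
#' @param seed master seed controlling conditioning and subset sampling.
#' @param max_attempts passed to [run_conditioned()].
#' @return List with `panels` (list of [haplotype_panel()]), `population`,
#'   and a `manifest` (config echo, seeds, final frequency, attempts,
#'   causal site index).
#' @export
simulate_benchmark <- function(config = sim_config(), seed = 1,
                               max_attempts = 50) {
  sub <- derive_seeds(seed, 2)
  pop <- run_conditioned(config, seed = sub[1], max_attempts = max_attempts)
  panels <- sample_panels(pop, config, seed = sub[2])
  list(
    panels = panels,
    population = pop,
    manifest = list(
      config = unclass(config),
      seed = seed,
      final_hot_freq = tail(pop$freq_trace, 1),
      attempts = attr(pop, "attempts"),
      causal_index = pop$causal_index,
      causal_pos_bp = pop$positions_bp[pop$causal_index]
    )
  )
}
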