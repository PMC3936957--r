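# Motif-centric stage: SNP-containing motif occurrences, flank windows,
# benchmark motif planting, and a one-occurrence-per-sequence (OOPS) EM
# motif finder with both-strand site models.

DNA <- c("A", "C", "G", "T")

.as_seqs <- function(x) {
  if (inherits(x, "DNAStringSet")) x <- as.character(x)
  if (tibble::is_tibble(x) || is.data.frame(x)) {
    stopifnot(all(c("id", "sequence") %in% names(x)))
    x <- setNames(as.character(x$sequence), as.character(x$id))
  }
  stopifnot(is.character(x))
  if (is.null(names(x))) names(x) <- paste0("seq_", seq_along(x))
  toupper(x)
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# integer encoding A=1 C=2 G=3 T=4
.encode <- function(s) {
  v <- match(strsplit(s, "")[[1]], DNA)
  if (anyNA(v)) abort("sequences must be over A/C/G/T")
  v
}

#' Read and write FASTA
#'
#' Thin wrappers over Biostrings that present records as a tibble with
#' columns `id` and `sequence`.
#'
#' @param path file path.
#' @param x a tibble with `id`/`sequence`, a named character vector, or a
#'   `DNAStringSet`.
#' @return `read_fasta()`: tibble; `write_fasta()`: the path, invisibly.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  tibble::tibble(id = names(ss), sequence = unname(as.character(ss)))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(x, path) {
  s <- .as_seqs(x)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(s), path)
  invisible(path)
}

#' Random DNA sequences
#'
#' @param n number of sequences.
#' @param width sequence length.
#' @param seed integer seed.
#' @param freqs base frequencies (A, C, G, T).
#' @return Character vector of length `n`.
#' @export
random_dna <- function(n, width, seed = 1, freqs = rep(0.25, 4)) {
  with_seed(seed, {
    vapply(seq_len(n), function(i) {
      paste(sample(DNA, width, replace = TRUE, prob = freqs), collapse = "")
    }, character(1))
  })
}

#' Find motif occurrences that contain a SNP
#'
#' Scans the reference for every window where, on either strand,
#' substituting one allele of a SNP completes an exact match to `motif`
#' while the other allele breaks it. Windows containing two or more of the
#' supplied SNPs are excluded (their count is reported via a message). A
#' record whose reference base agrees with neither allele is flagged
#' (`ref_mismatch`), not dropped.
#'
#' @param reference named character vector, tibble (`id`, `sequence`) or
#'   `DNAStringSet` of reference sequences.
#' @param motif exact motif string (no IUPAC degeneracy), e.g. the PRDM9
#'   core heptamer `"CCTCCCT"`.
#' @param snps tibble with columns `seq_id`, `pos` (1-based), `allele1`,
#'   `allele2`.
#' @return Tibble with one row per occurrence: `seq_id`, `start`, `end`
#'   (1-based, inclusive, on the forward strand), `strand`, `motif`,
#'   `snp_pos`, `snp_offset` (position of the SNP within the motif, on the
#'   motif's strand), `preserving_allele`, `disrupting_allele` (forward
#'   strand bases), `disrupted_text` (the broken motif, on the motif's
#'   strand) and `ref_mismatch`.
#' @export
find_motif_occurrences_with_snp <- function(reference, motif, snps) {
  seqs <- .as_seqs(reference)
  motif <- toupper(motif)
  w <- nchar(motif)
  stopifnot(all(c("seq_id", "pos", "allele1", "allele2") %in% names(snps)))
  out <- list()
  n_multi <- 0L
  for (r in seq_len(nrow(snps))) {
    sid <- as.character(snps$seq_id[r])
    pos <- snps$pos[r]
    if (!sid %in% names(seqs)) abort(sprintf("unknown sequence id '%s'", sid))
    s <- seqs[[sid]]
    if (pos < 1 || pos > nchar(s)) abort("SNP position outside the sequence")
    al <- toupper(c(snps$allele1[r], snps$allele2[r]))
    ref_base <- substr(s, pos, pos)
    mismatch <- !(ref_base %in% al)
    for (start in max(1, pos - w + 1):min(pos, nchar(s) - w + 1)) {
      inside <- snps$seq_id == snps$seq_id[r] &
        snps$pos >= start & snps$pos <= start + w - 1
      if (sum(inside) > 1) { n_multi <- n_multi + 1L; next }
      win <- substr(s, start, start + w - 1)
      off <- pos - start + 1
      v1 <- win; substr(v1, off, off) <- al[1]
      v2 <- win; substr(v2, off, off) <- al[2]
      for (strand in c("+", "-")) {
        m1 <- if (strand == "+") v1 else .revcomp(v1)
        m2 <- if (strand == "+") v2 else .revcomp(v2)
        hit1 <- m1 == motif
        hit2 <- m2 == motif
        if (xor(hit1, hit2)) {
          pres <- if (hit1) al[1] else al[2]
          disr <- if (hit1) al[2] else al[1]
          disrupted <- if (hit1) m2 else m1
          out[[length(out) + 1]] <- tibble::tibble(
            seq_id = sid, start = as.integer(start),
            end = as.integer(start + w - 1),
            strand = strand, motif = motif, snp_pos = pos,
            snp_offset = as.integer(if (strand == "+") off else w - off + 1),
            preserving_allele = pres, disrupting_allele = disr,
            disrupted_text = disrupted, ref_mismatch = mismatch
          )
        }
      }
    }
  }
  if (n_multi > 0)
    inform(sprintf("excluded %d window(s) containing more than one SNP",
                   n_multi))
  if (length(out) == 0) {
    return(tibble::tibble(
      seq_id = character(), start = integer(), end = integer(),
      strand = character(), motif = character(), snp_pos = numeric(),
      snp_offset = integer(), preserving_allele = character(),
      disrupting_allele = character(), disrupted_text = character(),
      ref_mismatch = logical()))
  }
  dplyr::bind_rows(out)
}

#' Extract fixed-width sequence windows around SNPs
#'
#' Cuts `2 * flank + 1`-base windows from the reference centered on each
#' SNP (the screening pipeline uses 101-base windows, `flank = 50`).
#' Windows truncated at a contig end are flagged.
#'
#' @inheritParams find_motif_occurrences_with_snp
#' @param flank bases kept on each side of the SNP.
#' @return Tibble with `id` (`seq_id:pos`), `seq_id`, `snp_pos`,
#'   `snp_index` (1-based SNP offset within the window), `sequence`,
#'   `truncated`.
#' @export
snp_flank_sequences <- function(reference, snps, flank = 50) {
  seqs <- .as_seqs(reference)
  stopifnot(all(c("seq_id", "pos") %in% names(snps)), flank >= 0)
  purrr::map_dfr(seq_len(nrow(snps)), function(r) {
    sid <- as.character(snps$seq_id[r])
    pos <- snps$pos[r]
    if (!sid %in% names(seqs)) abort(sprintf("unknown sequence id '%s'", sid))
    s <- seqs[[sid]]
    if (pos < 1 || pos > nchar(s))
      abort(sprintf("SNP position %s off contig '%s'", pos, sid))
    lo <- max(1, pos - flank)
    hi <- min(nchar(s), pos + flank)
    tibble::tibble(
      id = paste0(sid, ":", pos), seq_id = sid, snp_pos = pos,
      snp_index = as.integer(pos - lo + 1),
      sequence = substr(s, lo, hi),
      truncated = (hi - lo + 1) < (2 * flank + 1)
    )
  })
}

#' Plant a benchmark motif into selected records
#'
#' Overwrites bases of each causal record with `motif` at an offset that
#' makes the motif span the record's SNP position; other records are
#' untouched. Record length is preserved.
#'
#' @param records tibble from [snp_flank_sequences()] (columns `id`,
#'   `sequence`, optionally `snp_index`) or a named character vector (SNP
#'   assumed at the central base).
#' @param motif motif text to insert.
#' @param causal_ids ids of the records to modify.
#' @param offset_policy `"center"` (motif centered on the SNP, default) or
#'   `"random"` (uniform among offsets spanning the SNP, seeded).
#' @param seed used by the random offset policy.
#' @return Records in the input shape with modified sequences.
#' @export
plant_motifs <- function(records, motif, causal_ids,
                         offset_policy = c("center", "random"), seed = 1) {
  offset_policy <- match.arg(offset_policy)
  motif <- toupper(motif)
  w <- nchar(motif)
  tab <- if (is.character(records)) {
    tibble::tibble(id = names(.as_seqs(records)),
                   sequence = unname(.as_seqs(records)))
  } else records
  stopifnot(all(c("id", "sequence") %in% names(tab)))
  if (!"snp_index" %in% names(tab))
    tab$snp_index <- (nchar(tab$sequence) + 1L) %/% 2L
  if (any(w > nchar(tab$sequence))) abort("motif longer than a record")
  missing_ids <- setdiff(causal_ids, tab$id)
  if (length(missing_ids) > 0)
    abort(sprintf("unknown causal id(s): %s", paste(missing_ids, collapse = ", ")))
  offsets <- with_seed(seed, {
    vapply(seq_len(nrow(tab)), function(i) {
      if (!tab$id[i] %in% causal_ids) return(NA_integer_)
      L <- nchar(tab$sequence[i])
      snp <- tab$snp_index[i]
      lo <- max(1L, snp - w + 1L)
      hi <- min(snp, L - w + 1L)
      if (lo > hi) abort(sprintf("record '%s' too short to span its SNP with the motif", tab$id[i]))
      if (offset_policy == "center") {
        as.integer(min(max(snp - w %/% 2L, lo), hi))
      } else {
        as.integer(sample(lo:hi, 1))
      }
    }, integer(1))
  })
  for (i in which(!is.na(offsets))) {
    s <- tab$sequence[i]
    substr(s, offsets[i], offsets[i] + w - 1L) <- motif
    tab$sequence[i] <- s
  }
  if (is.character(records)) return(setNames(tab$sequence, tab$id))
  tab
}

# position log-odds scores of a log-PWM over one encoded sequence;
# returns matrix (positions x strands kept separate by the caller)
.site_scores <- function(x, logmat, w) {
  m <- length(x) - w + 1L
  sc <- numeric(m)
  for (k in seq_len(w)) {
    sc <- sc + logmat[k, x[k:(k + m - 1L)]]
  }
  sc
}

#' One-occurrence-per-sequence EM motif discovery
#'
#' Fits a position weight matrix of the given width under the OOPS model:
#' every sequence carries exactly one motif site at an unknown position
#' (and, by default, unknown strand), all other positions following a
#' 0-order background estimated from the records. Starting points are
#' seeded from observed sites: a pool of `4 * n_restarts` site-seeded
#' candidates is screened with two EM iterations, the best `n_restarts`
#' run to convergence, and the restart with the best final observed-data
#' log-likelihood wins. Column updates use Dirichlet
#' pseudocounts (0.1 per base), so the monotone EM objective is the
#' penalized log-likelihood stored in `objective_trace`.
#'
#' @param records character vector / tibble (`id`, `sequence`) /
#'   `DNAStringSet`; at least 2 records, each at least `width` long.
#' @param width motif width.
#' @param n_restarts number of EM restarts.
#' @param seed integer seed (restart initializations).
#' @param revcomp score sites on both strands (default `TRUE`).
#' @param pseudocount Dirichlet pseudocount per base in PWM updates.
#' @param max_iter,tol EM stopping rule (relative objective change).
#' @return An object of class `pwm`: `prob` (4 x width matrix), `sites`
#'   (per-record max-posterior site), `loglik`, `objective_trace`,
#'   `consensus`, `ic` (information content, bits), `background`.
#' @export
oops_em <- function(records, width, n_restarts = 5, seed = 1,
                    revcomp = TRUE, pseudocount = 0.1, max_iter = 200,
                    tol = 1e-7, init = NULL) {
  seqs <- .as_seqs(records)
  n <- length(seqs)
  if (n < 2) abort("need at least 2 records")
  if (any(nchar(seqs) < width)) abort("width exceeds the shortest record")
  enc <- lapply(seqs, .encode)
  bg <- tabulate(unlist(enc), 4)
  bg <- (bg + 1) / sum(bg + 4)
  logbg <- log(bg)
  # constant background term of the observed-data log-likelihood
  bg_ll <- sum(vapply(enc, function(x) sum(logbg[x]), numeric(1)))
  comp <- c(4L, 3L, 2L, 1L)
  equal <- length(unique(nchar(seqs))) == 1L
  if (equal) {
    X <- do.call(rbind, enc)
    m_eq <- ncol(X) - width + 1L
  }
  n_strand <- if (revcomp) 2L else 1L

  # One E-step at `pwm`: expected base counts (with pseudocounts), the
  # observed-data log-likelihood at `pwm`, and per-record best sites.
  estep <- function(pwm, want_sites = FALSE) {
    lom <- t(log(pwm) - logbg)                   # width x 4
    lom_rc <- lom[width:1, comp, drop = FALSE]   # reverse-complement PWM
    counts <- matrix(pseudocount, 4, width)
    if (equal) {
      m <- m_eq
      Sf <- matrix(0, n, m)
      Sr <- if (revcomp) matrix(0, n, m)
      for (k in seq_len(width)) {
        idx <- X[, k:(k + m - 1L), drop = FALSE]
        Sf <- Sf + matrix(lom[k, idx], n, m)
        if (revcomp) Sr <- Sr + matrix(lom_rc[k, idx], n, m)
      }
      mx <- Sf[, 1]
      for (j in seq_len(m)) mx <- pmax(mx, Sf[, j])
      if (revcomp) for (j in seq_len(m)) mx <- pmax(mx, Sr[, j])
      Pf <- exp(Sf - mx)
      Pr <- if (revcomp) exp(Sr - mx)
      tot <- rowSums(Pf) + if (revcomp) rowSums(Pr) else 0
      ll <- bg_ll + sum(mx + log(tot)) - n * log(n_strand * m)
      Pf <- Pf / tot
      if (revcomp) Pr <- Pr / tot
      for (k in seq_len(width)) {
        idx <- X[, k:(k + m - 1L), drop = FALSE]
        for (b in 1:4) counts[b, k] <- counts[b, k] + sum(Pf[idx == b])
        if (revcomp) {
          idr <- X[, (width - k + 1L):(width - k + m), drop = FALSE]
          for (b in 1:4)
            counts[b, k] <- counts[b, k] + sum(Pr[idr == comp[b]])
        }
      }
      sites <- NULL
      if (want_sites) {
        P <- if (revcomp) cbind(Pf, Pr) else Pf
        bidx <- max.col(P, ties.method = "first")
        sites <- tibble::tibble(
          record = seq_len(n), id = names(seqs),
          position = ifelse(bidx <= m, bidx, bidx - m),
          strand = ifelse(bidx <= m, "+", "-"),
          posterior = P[cbind(seq_len(n), bidx)]
        )
      }
      return(list(counts = counts, ll = ll, sites = sites))
    }
    # unequal record lengths: per-record loop
    ll <- bg_ll
    sites <- if (want_sites) vector("list", n)
    for (i in seq_len(n)) {
      x <- enc[[i]]
      m <- length(x) - width + 1L
      sc <- .site_scores(x, lom, width)
      if (revcomp) sc <- c(sc, .site_scores(x, lom_rc, width))
      mx <- max(sc)
      post <- exp(sc - mx)
      tot <- sum(post)
      post <- post / tot
      ll <- ll + mx + log(tot) - log(length(sc))
      fwd <- post[seq_len(m)]
      for (k in seq_len(width)) {
        bases <- x[k:(k + m - 1L)]
        for (b in 1:4) counts[b, k] <- counts[b, k] + sum(fwd[bases == b])
      }
      if (revcomp) {
        rv <- post[m + seq_len(m)]
        for (k in seq_len(width)) {
          # motif column k reads the complement of forward position
          # j + width - k
          bases <- comp[x[(width - k + 1L):(width - k + m)]]
          for (b in 1:4) counts[b, k] <- counts[b, k] + sum(rv[bases == b])
        }
      }
      if (want_sites) {
        b <- which.max(post)
        sites[[i]] <- tibble::tibble(
          record = i, id = names(seqs)[i],
          position = if (b <= m) b else b - m,
          strand = if (b <= m) "+" else "-",
          posterior = post[b]
        )
      }
    }
    list(counts = counts, ll = ll,
         sites = if (want_sites) dplyr::bind_rows(sites))
  }

  run_em <- function(pwm0, iters = max_iter) {
    pwm <- pwm0
    trace <- numeric(0)
    ll <- -Inf
    for (it in seq_len(iters)) {
      e <- estep(pwm)
      # MAP-EM objective at the *current* pwm: non-decreasing across
      # iterations because the M-step adds the Dirichlet pseudocounts
      obj <- e$ll + pseudocount * sum(log(pwm))
      trace <- c(trace, obj)
      ll <- e$ll
      if (it > 1 && abs(obj - trace[it - 1]) <= tol * (abs(obj) + 1)) break
      pwm <- sweep(e$counts, 2, colSums(e$counts), "/")
    }
    list(pwm = pwm, loglik = ll, trace = trace)
  }

  init_from_site <- function(s) {
    with_seed(s, {
      i <- sample.int(n, 1)
      x <- enc[[i]]
      j <- sample.int(length(x) - width + 1L, 1)
      site <- x[j:(j + width - 1L)]
      if (revcomp && runif(1) < 0.5) site <- comp[rev(site)]
      pwm <- matrix(0.15, 4, width)
      pwm[cbind(site, seq_len(width))] <- 0.55
      pwm
    })
  }

  # screen site-seeded starting points (plus a user-supplied init, if
  # any) with a short EM burst; run the most promising to convergence
  seeds <- derive_seeds(seed, 4L * n_restarts)
  starts <- lapply(seeds, init_from_site)
  if (!is.null(init)) {
    stopifnot(is.matrix(init), dim(init) == c(4L, width))
    starts <- c(list(init), starts)
  }
  screened <- lapply(starts, function(p0) run_em(p0, iters = 2))
  keep <- order(vapply(screened, `[[`, numeric(1), "loglik"),
                decreasing = TRUE)[seq_len(min(n_restarts, length(screened)))]
  if (!is.null(init) && !(1L %in% keep)) keep <- c(1L, keep)
  best <- NULL
  for (r in keep) {
    fit <- run_em(screened[[r]]$pwm)
    if (is.null(best) || fit$loglik > best$loglik + 1e-9) best <- fit
  }
  pwm <- best$pwm
  final <- estep(pwm, want_sites = TRUE)
  rownames(pwm) <- DNA
  ic <- sum(pwm * (log2(pwm) - log2(bg)))
  structure(list(
    prob = pwm, width = width,
    sites = final$sites,
    loglik = best$loglik,
    llr = best$loglik - bg_ll,
    objective_trace = best$trace,
    consensus = paste(DNA[apply(pwm, 2, which.max)], collapse = ""),
    ic = ic, background = setNames(bg, DNA),
    n_records = n, revcomp = revcomp, seed = seed
  ), class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> width %d, consensus %s, IC %.1f bits, loglik %.2f\n",
              x$width, x$consensus, x$ic, x$loglik))
  invisible(x)
}

#' @export
tidy.pwm <- function(x, ...) {
  tibble::tibble(
    column = rep(seq_len(x$width), each = 4),
    base = rep(DNA, x$width),
    prob = as.numeric(x$prob)
  )
}

#' @export
autoplot.pwm <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$column, y = .data$prob,
                                   fill = .data$base)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = "motif column", y = "probability") +
    ggplot2::theme_minimal()
}

#' Discover ranked motifs
#'
#' Repeatedly runs [oops_em()] across the width range, keeps the best
#' width per rank by a BIC-penalized log-likelihood-ratio score
#' (`2 * LLR - 3 * width * log(n_records)`), masks the confident sites
#' (posterior > 0.5) of each reported motif with background-sampled bases,
#' and repeats for the next rank. Motifs with fewer than `min_sites`
#' confident sites are not reported (the search stops there).
#'
#' @inheritParams oops_em
#' @param n_motifs number of ranked motifs sought.
#' @param width_min,width_max inclusive motif width range.
#' @param min_sites minimum number of confident sites for a motif to be
#'   reported.
#' @return List of `pwm` objects (possibly fewer than `n_motifs`), class
#'   `motif_set`.
#' @export
discover_motifs <- function(records, n_motifs = 2, width_min = 10,
                            width_max = 20, min_sites = 10, n_restarts = 5,
                            seed = 1, revcomp = TRUE) {
  seqs <- .as_seqs(records)
  widths <- seq(width_min, width_max)
  found <- list()
  seeds <- derive_seeds(seed, n_motifs * (length(widths) + 1))
  si <- 0L
  for (rank in seq_len(n_motifs)) {
    fits <- list()
    for (wi in seq_along(widths)) {
      si <- si + 1L
      if (widths[wi] > min(nchar(seqs))) next
      fit <- oops_em(seqs, widths[wi], n_restarts = n_restarts,
                     seed = seeds[si], revcomp = revcomp)
      fit$score <- 2 * fit$llr - 3 * fit$width * log(fit$n_records)
      fits[[length(fits) + 1]] <- fit
    }
    if (length(fits) == 0) break
    scores <- vapply(fits, `[[`, numeric(1), "score")
    best <- fits[[which.max(scores)]]
    confident <- best$sites[best$sites$posterior > 0.5, , drop = FALSE]
    if (nrow(confident) < min_sites) {
      inform(sprintf(
        "rank %d motif has %d confident sites (< %d); stopping",
        rank, nrow(confident), min_sites))
      break
    }
    best$n_confident_sites <- nrow(confident)
    best$rank <- rank
    found[[rank]] <- best
    # mask the confident sites before searching the next rank
    si <- si + 1L
    mask_bases <- random_dna(nrow(confident), best$width, seed = seeds[si],
                             freqs = best$background)
    for (ri in seq_len(nrow(confident))) {
      i <- confident$record[ri]
      p <- confident$position[ri]
      s <- seqs[[i]]
      substr(s, p, p + best$width - 1L) <- mask_bases[ri]
      seqs[[i]] <- s
    }
  }
  structure(found, class = "motif_set")
}

#' @export
print.motif_set <- function(x, ...) {
  cat(sprintf("<motif_set> %d motif(s)\n", length(x)))
  for (m in x)
    cat(sprintf("  rank %d: %s (width %d, %d sites, score %.1f)\n",
                m$rank, m$consensus, m$width, m$n_confident_sites, m$score))
  invisible(x)
}

#' @export
tidy.motif_set <- function(x, ...) {
  purrr::map_dfr(x, function(m) {
    tibble::tibble(rank = m$rank, width = m$width, consensus = m$consensus,
                   score = m$score, ic = m$ic,
                   n_confident_sites = m$n_confident_sites)
  })
}

#' Agreement between a PWM and a consensus string
#'
#' Maximum, over both strands and all alignments in which the shorter of
#' the two is fully contained in the longer, of the mean probability the
#' PWM assigns to the consensus base across the overlapping columns.
#' 1.0 for a one-hot encoding of the consensus; 0.25 for a uniform PWM.
#'
#' @param pwm a `pwm` from [oops_em()].
#' @param consensus consensus string to compare against.
#' @return Score in `[0, 1]`.
#' @export
consensus_match <- function(pwm, consensus) {
  stopifnot(inherits(pwm, "pwm"))
  score_one <- function(prob, cons) {
    w <- ncol(prob)
    cl <- length(cons)
    if (w >= cl) {
      best <- -Inf
      for (off in 0:(w - cl)) {
        v <- mean(prob[cbind(cons, off + seq_len(cl))])
        if (v > best) best <- v
      }
      best
    } else {
      best <- -Inf
      for (off in 0:(cl - w)) {
        v <- mean(prob[cbind(cons[off + seq_len(w)], seq_len(w))])
        if (v > best) best <- v
      }
      best
    }
  }
  cons <- .encode(toupper(consensus))
  comp <- c(4L, 3L, 2L, 1L)
  max(score_one(pwm$prob, cons),
      score_one(pwm$prob, comp[rev(cons)]))
}

#' Write motifs in MEME minimal text format
#'
#' @param motifs a `pwm` or `motif_set`.
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_meme_pwm <- function(motifs, path) {
  if (inherits(motifs, "pwm")) motifs <- structure(list(motifs),
                                                   class = "motif_set")
  bg <- motifs[[1]]$background
  lines <- c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -", "",
             "Background letter frequencies",
             paste(sprintf("%s %.5f", DNA, bg), collapse = " "), "")
  for (i in seq_along(motifs)) {
    m <- motifs[[i]]
    nsites <- m$n_confident_sites %||% m$n_records
    lines <- c(lines,
               sprintf("MOTIF %s m%d", m$consensus, i),
               sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
                       m$width, nsites),
               apply(m$prob, 2, function(col)
                 paste(sprintf("%.6f", col), collapse = " ")),
               "")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Build the simulated motif-finding benchmark corpus
#'
#' Mirrors the simulation benchmark: from each hotspot scan, select SNPs
#' (the significant ones with `p < alpha`, at most `top_k` most
#' significant per scan, or randomly chosen candidates for the negative
#' control), extend each to a random-DNA window of `2 * flank + 1` bases,
#' and plant the benchmark motifs in the windows whose SNP is that scan's
#' causal SNP (alternating the motif across scans). When the causal SNP of
#' a scan is not selected, nothing is planted for it — false negatives
#' propagate, as they do in the screening pipeline being benchmarked.
#'
#' @param scans list of [scan_hotspot()] results.
#' @param causal_sites integer vector: the causal SNP site index per scan.
#' @param motifs character vector of motifs planted in rotation.
#' @param alpha significance threshold for the guided selection.
#' @param top_k at most this many significant SNPs per scan (most
#'   significant first).
#' @param selection `"significant"` (guided) or `"random"` (negative
#'   control: the same number of SNPs per scan drawn at random from the
#'   candidates).
#' @param flank window half-width in bases.
#' @param seed integer seed (window sequences, planting, control draws).
#' @return List with `records` (tibble: `id`, `sequence`, `causal`,
#'   `motif`), `n_windows`, `n_causal`.
#' @export
benchmark_motif_corpus <- function(scans, causal_sites,
                                   motifs = c("ACTATCGATCTAG",
                                              "ATGATGTAATGGT"),
                                   alpha = 0.05, top_k = 1,
                                   selection = c("significant", "random"),
                                   flank = 50, seed = 1) {
  selection <- match.arg(selection)
  stopifnot(length(causal_sites) == length(scans))
  seeds <- derive_seeds(seed, length(scans) * 2)
  recs <- list()
  for (i in seq_along(scans)) {
    res <- tidy(scans[[i]])
    # most significant first; p-value ties broken by effect size
    sig <- dplyr::arrange(dplyr::filter(res, .data$p_value < alpha),
                          .data$p_value, dplyr::desc(abs(.data$delta_rho)),
                          .data$position_bp)
    n_take <- min(nrow(sig), top_k)
    take <- if (selection == "significant") {
      head(sig, n_take)
    } else {
      if (n_take == 0 || nrow(res) == 0) res[0, ] else
        with_seed(seeds[2 * i - 1],
                  res[sample.int(nrow(res), min(n_take, nrow(res))), ])
    }
    if (nrow(take) == 0) next
    win <- random_dna(nrow(take), 2 * flank + 1, seed = seeds[2 * i])
    motif_i <- motifs[(i - 1) %% length(motifs) + 1]
    recs[[length(recs) + 1]] <- tibble::tibble(
      id = paste0("scan", i, "_site", take$site),
      sequence = win,
      causal = take$site == causal_sites[i],
      motif = ifelse(take$site == causal_sites[i], motif_i, NA_character_)
    )
  }
  if (length(recs) == 0)
    abort("no windows selected; nothing to build a corpus from")
  records <- dplyr::bind_rows(recs)
  causal_ids <- records$id[records$causal]
  for (m in unique(stats::na.omit(records$motif))) {
    ids <- records$id[!is.na(records$motif) & records$motif == m]
    records <- plant_motifs(records, m, ids, offset_policy = "center")
  }
  list(records = records, n_windows = nrow(records),
       n_causal = length(causal_ids))
}
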