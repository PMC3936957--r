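#' Construct a phased haplotype panel
#'
#' A haplotype panel is the unit of all estimation in rhosplit: `n` phased
#' haplotypes (rows) typed at `L` biallelic sites (columns) with known
#' physical positions. Alleles are coded 0/1 with `NA` for missing calls.
#' Positions are stored in kb (the native unit of the LDhat locs dialect);
#' use [positions()] to read them in bp or kb.
#'
#' @param alleles integer (or coercible) matrix of 0/1/`NA`, haplotypes in
#'   rows, sites in columns.
#' @param positions physical site positions, strictly increasing.
#' @param labels optional character vector of unique haplotype identifiers;
#'   defaults to `hap_1 .. hap_n`.
#' @param unit unit of `positions`: `"bp"` (default) or `"kb"`.
#' @return An object of class `hap_panel`.
#' @examples
#' p <- haplotype_panel(matrix(c(0, 1, 1, 0, 0, 1), 2, 3),
#'                      positions = c(100, 2e3, 5e3))
#' maf(p)
#' @export
haplotype_panel <- function(alleles, positions, labels = NULL,
                            unit = c("bp", "kb")) {
  unit <- match.arg(unit)
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  n <- nrow(alleles)
  L <- ncol(alleles)
  if (n < 2L) abort("a haplotype panel needs at least 2 haplotypes")
  if (L < 1L) abort("a haplotype panel needs at least 1 site")
  bad <- !(alleles %in% c(0L, 1L, NA_integer_))
  if (any(bad)) abort("allele entries must be 0, 1 or NA")
  positions <- as.numeric(positions)
  if (length(positions) != L)
    abort(sprintf("got %d positions for %d sites", length(positions), L))
  if (any(!is.finite(positions)) || any(diff(positions) <= 0))
    abort("positions must be finite and strictly increasing")
  if (is.null(labels)) labels <- paste0("hap_", seq_len(n))
  labels <- as.character(labels)
  if (length(labels) != n || anyDuplicated(labels))
    abort("labels must be unique and one per haplotype")
  positions_kb <- if (unit == "bp") positions / 1000 else positions
  dimnames(alleles) <- NULL
  structure(list(alleles = alleles, positions_kb = positions_kb,
                 labels = labels),
            class = "hap_panel")
}

#' @export
print.hap_panel <- function(x, ...) {
  cat(sprintf("<hap_panel> %d haplotypes x %d sites, %.3f-%.3f kb\n",
              n_haps(x), n_sites(x),
              min(x$positions_kb), max(x$positions_kb)))
  nm <- sum(is.na(x$alleles))
  if (nm > 0) cat(sprintf("  %d missing calls\n", nm))
  invisible(x)
}

#' @export
dim.hap_panel <- function(x) dim(x$alleles)

#' Panel accessors
#'
#' @param panel a [haplotype_panel()].
#' @param unit `"bp"` or `"kb"`.
#' @return `positions()`: numeric vector of site positions; `n_haps()`,
#'   `n_sites()`: integer counts.
#' @export
positions <- function(panel, unit = c("bp", "kb")) {
  unit <- match.arg(unit)
  stopifnot(inherits(panel, "hap_panel"))
  if (unit == "bp") panel$positions_kb * 1000 else panel$positions_kb
}

#' @rdname positions
#' @export
n_haps <- function(panel) nrow(panel$alleles)

#' @rdname positions
#' @export
n_sites <- function(panel) ncol(panel$alleles)

# internal row/column subsetting that preserves the class
subset_panel <- function(panel, rows = NULL, sites = NULL) {
  a <- panel$alleles
  pos <- panel$positions_kb
  lab <- panel$labels
  if (!is.null(rows)) {
    a <- a[rows, , drop = FALSE]
    lab <- lab[rows]
  }
  if (!is.null(sites)) {
    a <- a[, sites, drop = FALSE]
    pos <- pos[sites]
  }
  structure(list(alleles = a, positions_kb = pos, labels = lab),
            class = "hap_panel")
}

#' Read a haplotype panel from LDhat sites/locs files
#'
#' The sites file starts with a header line `n L ploidy` followed by
#' FASTA-like records whose sequences are strings over `0`, `1` and `?`
#' (missing). The locs file starts with a header `L region_length model`
#' followed by the `L` site positions in kb.
#'
#' @param sites_path,locs_path paths to the two files.
#' @return A [haplotype_panel()].
#' @export
read_sites_locs <- function(sites_path, locs_path) {
  sl <- readLines(sites_path)
  sl <- sl[!grepl("^\\s*$", sl)]
  if (length(sl) < 2L) abort("sites file has no records")
  hdr <- scan(text = sl[1], what = numeric(), quiet = TRUE)
  if (length(hdr) < 3L)
    abort("sites header must be 'n L ploidy'")
  n <- as.integer(hdr[1]); L <- as.integer(hdr[2])
  body <- sl[-1]
  starts <- grep("^>", body)
  if (length(starts) != n)
    abort(sprintf("sites header announces %d haplotypes but %d records found",
                  n, length(starts)))
  ends <- c(starts[-1] - 1L, length(body))
  labels <- sub("^>\\s*", "", body[starts])
  labels <- sub("\\s+$", "", labels)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    seqlines <- body[(starts[i] + 1L):ends[i]]
    s <- gsub("\\s", "", paste(seqlines, collapse = ""))
    if (nchar(s) != L)
      abort(sprintf("record '%s' has %d sites, header announces %d",
                    labels[i], nchar(s), L))
    chars <- strsplit(s, "")[[1]]
    if (!all(chars %in% c("0", "1", "?")))
      abort(sprintf("record '%s' contains characters outside 0/1/?", labels[i]))
    rows[[i]] <- match(chars, c("0", "1")) - 1L # '?' maps to NA
  }
  ll <- readLines(locs_path)
  ll <- ll[!grepl("^\\s*$", ll)]
  lhdr <- scan(text = ll[1], what = character(), quiet = TRUE)
  nloc <- as.integer(lhdr[1])
  pos <- scan(text = paste(ll[-1], collapse = "\n"), what = numeric(),
              quiet = TRUE)
  if (nloc != L || length(pos) != L)
    abort(sprintf("locs file announces %d positions (%d read) but sites file has %d sites",
                  nloc, length(pos), L))
  if (any(diff(pos) <= 0)) abort("locs positions must be strictly increasing")
  haplotype_panel(do.call(rbind, rows), pos, labels = labels, unit = "kb")
}

#' Write a haplotype panel to LDhat sites/locs files
#'
#' Inverse of [read_sites_locs()]: files written here parse back to an
#' identical panel. Missing calls are emitted as `?`.
#'
#' @param panel a [haplotype_panel()].
#' @param sites_path,locs_path output paths.
#' @return Invisibly, the panel.
#' @export
write_sites_locs <- function(panel, sites_path, locs_path) {
  stopifnot(inherits(panel, "hap_panel"))
  n <- n_haps(panel); L <- n_sites(panel)
  a <- panel$alleles
  lines <- character(1L + 2L * n)
  lines[1] <- sprintf("%d %d 1", n, L)
  for (i in seq_len(n)) {
    s <- ifelse(is.na(a[i, ]), "?", as.character(a[i, ]))
    lines[2L * i] <- paste0(">", panel$labels[i])
    lines[2L * i + 1L] <- paste(s, collapse = "")
  }
  writeLines(lines, sites_path)
  pos <- panel$positions_kb
  region <- formatC(ceiling(max(pos)), format = "d")
  writeLines(c(sprintf("%d %s L", L, region),
               sprintf("%.15g", pos)),
             locs_path)
  invisible(panel)
}

#' Minor allele frequencies
#'
#' MAF at each requested site: `min(f, 1 - f)` over non-missing calls,
#' where `f` is the frequency of allele 1. Candidate SNPs for association
#' screening are conventionally required to have MAF at or above 0.30 so
#' that both allele subpopulations stay large enough to estimate from.
#'
#' @param panel a [haplotype_panel()].
#' @param sites site indices (default all sites).
#' @return Numeric vector of MAFs in `[0, 0.5]`.
#' @export
maf <- function(panel, sites = NULL) {
  stopifnot(inherits(panel, "hap_panel"))
  if (is.null(sites)) sites <- seq_len(n_sites(panel))
  if (any(sites < 1L | sites > n_sites(panel))) abort("site index out of range")
  a <- panel$alleles[, sites, drop = FALSE]
  nn <- colSums(!is.na(a))
  if (any(nn == 0))
    abort(sprintf("MAF undefined: site(s) %s have no non-missing calls",
                  paste(sites[nn == 0], collapse = ", ")))
  f <- colSums(a, na.rm = TRUE) / nn
  unname(pmin(f, 1 - f))
}

#' Candidate sites passing a MAF filter
#'
#' @inheritParams maf
#' @param maf_min minimum minor allele frequency (default 0.30).
#' @return Integer vector of site indices with `maf >= maf_min`.
#' @export
candidate_sites <- function(panel, maf_min = 0.30) {
  which(maf(panel) >= maf_min - 1e-12)
}

#' Cut a window of sites around a center SNP
#'
#' Returns the sub-panel of at most `2 * half_width + 1` sites centered on
#' `center_site`, truncated silently at the panel edges (a message reports
#' truncation). The motif-guided screen uses 101-SNP windows
#' (`half_width = 50`).
#'
#' @inheritParams maf
#' @param center_site index of the central site.
#' @param half_width number of sites kept on each side.
#' @return A [haplotype_panel()] over the retained sites.
#' @export
cut_window <- function(panel, center_site, half_width) {
  stopifnot(inherits(panel, "hap_panel"), is_count(center_site),
            is.numeric(half_width), half_width >= 0)
  L <- n_sites(panel)
  if (center_site > L) abort("center_site out of range")
  lo <- max(1L, as.integer(center_site - half_width))
  hi <- min(L, as.integer(center_site + half_width))
  if (lo > 1L || hi < L) {
    if (hi - lo + 1L < 2L * half_width + 1L)
      inform(sprintf("window truncated at panel edge: %d sites kept", hi - lo + 1L))
  }
  subset_panel(panel, sites = lo:hi)
}

#' @export
tidy.hap_panel <- function(x, ...) {
  tibble::tibble(
    site = rep(seq_len(n_sites(x)), each = n_haps(x)),
    position_bp = rep(positions(x, "bp"), each = n_haps(x)),
    haplotype = rep(x$labels, times = n_sites(x)),
    allele = as.integer(x$alleles)
  )
}
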