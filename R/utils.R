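# Shared internals: genetic-code tables and histogram mode finding.

.reedwgd_cache <- new.env(parent = emptyenv())

# Sense codons of the standard genetic code (no stop codons).
.sense_codons <- function() {
  if (is.null(.reedwgd_cache$sense)) {
    gc <- Biostrings::GENETIC_CODE
    .reedwgd_cache$sense <- names(gc)[gc != "*"]
  }
  .reedwgd_cache$sense
}

# Two-base codon prefixes whose third position is four-fold degenerate:
# any base in position 3 encodes the same amino acid.
.fourfold_prefixes <- function() {
  if (is.null(.reedwgd_cache$fourfold)) {
    gc <- Biostrings::GENETIC_CODE
    pre <- substr(names(gc), 1L, 2L)
    aa_by_pre <- split(unname(gc), pre)
    ok <- vapply(aa_by_pre, function(a) length(unique(a)) == 1L && !"*" %in% a,
                 logical(1))
    .reedwgd_cache$fourfold <- names(aa_by_pre)[ok]
  }
  .reedwgd_cache$fourfold
}

.blosum62 <- function() {
  if (is.null(.reedwgd_cache$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .reedwgd_cache$blosum62 <- e$BLOSUM62
  }
  .reedwgd_cache$blosum62
}

#' Histogram with bin centers on multiples of the bin width, plus its modes
#'
#' Bins are half-open intervals `[c - w/2, c + w/2)` centered on integer
#' multiples `c = k * w` of the bin width, so that theoretically meaningful
#' round values (allele dosages 0.25/0.5/0.75, copy-number ratios 1 and 2)
#' fall at bin centers rather than on bin edges.  A mode is a bin whose count
#' is no smaller than both neighbours (left edge of a plateau), carries at
#' least `min_frac` of the total mass, and is nonzero.
#'
#' @param values numeric vector.
#' @param bin_width width of the histogram bins, same units as `values`.
#' @param min_frac minimum fraction of the total count a bin must hold to be
#'   reported as a mode.
#' @return list with `histogram` (data.frame: `bin_center`, `bin_left`,
#'   `bin_right`, `count`) and `modes` (numeric vector of mode bin centers,
#'   increasing).
#' @export
#' @examples
#' h <- histogram_modes(c(rep(1, 50), rep(2, 30)), bin_width = 0.25)
#' h$modes  # 1 and 2
histogram_modes <- function(values, bin_width, min_frac = 0) {
  stopifnot(is.numeric(values), length(values) > 0L, bin_width > 0)
  idx <- floor(values / bin_width + 0.5 + 1e-9)
  rng <- range(idx)
  all_idx <- rng[1]:rng[2]
  counts <- tabulate(idx - rng[1] + 1L, nbins = length(all_idx))
  hist <- data.frame(
    bin_center = all_idx * bin_width,
    bin_left   = all_idx * bin_width - bin_width / 2,
    bin_right  = all_idx * bin_width + bin_width / 2,
    count      = counts
  )
  padded <- c(0L, counts, 0L)
  n <- length(counts)
  is_max <- counts >= padded[seq_len(n)] & counts >= padded[seq_len(n) + 2L] &
    counts > 0L & counts >= min_frac * length(values)
  # keep only the leftmost bin of a flat plateau of equal counts
  if (n > 1L) {
    drop <- c(FALSE, counts[-1L] == counts[-n] & is_max[-n])
    is_max <- is_max & !drop
  }
  list(histogram = hist, modes = hist$bin_center[is_max])
}

# Write a data.frame as a headered TSV (the package's tabular interchange
# format).
.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}
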