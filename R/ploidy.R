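# Functional-ploidy assessment from per-site nonreference allele
# frequencies of short-read counts.  A functionally diploid (disomic)
# genotype puts heterozygous-site allele balance at 1/2; tetrasomic dosage
# adds modes near 1/4 and 3/4.

#' Nonreference allele-frequency spectrum from a per-site count table
#'
#' Sites failing the depth or nonreference-count filters are excluded (their
#' counts are reported), nonreference fractions are histogrammed at
#' `bin_width` with bins centered on multiples of the width (so the
#' theoretical dosages 0.25, 0.5, 0.75 fall at bin centers), and modes are
#' local maxima holding at least `mode_min_frac` of the retained sites.
#'
#' @param counts data.frame with columns `position`, `depth`,
#'   `nonref_count`.
#' @param min_depth minimum site depth.
#' @param min_nonref minimum nonreference reads (removes homozygous sites
#'   whose only nonreference reads are sequencing errors).
#' @param bin_width histogram bin width (allele-fraction units).
#' @param mode_min_frac minimum fraction of retained sites a modal bin must
#'   hold.
#' @return object of class `allele_spectrum`: list with `sites` (retained
#'   sites with a `fraction` column), `histogram`, `modes`, and
#'   `filter_counts` (`input`, `low_depth`, `low_nonref`, `retained`).
#' @export
site_spectrum <- function(counts, min_depth = 10L, min_nonref = 3L,
                          bin_width = 0.05, mode_min_frac = 0.05) {
  stopifnot(all(c("position", "depth", "nonref_count") %in% names(counts)))
  low_depth <- counts$depth < min_depth
  low_nonref <- !low_depth & counts$nonref_count < min_nonref
  keep <- !low_depth & !low_nonref
  if (!any(keep))
    stop("no sites pass filters: ", sum(low_depth), " below depth ",
         min_depth, ", ", sum(low_nonref), " below nonref count ", min_nonref)
  s <- counts[keep, , drop = FALSE]
  s$fraction <- s$nonref_count / s$depth
  hm <- histogram_modes(s$fraction, bin_width, min_frac = mode_min_frac)
  out <- list(sites = s, histogram = hm$histogram, modes = hm$modes,
              filter_counts = c(input = nrow(counts),
                                low_depth = sum(low_depth),
                                low_nonref = sum(low_nonref),
                                retained = nrow(s)))
  class(out) <- "allele_spectrum"
  out
}

#' @export
print.allele_spectrum <- function(x, ...) {
  fc <- x$filter_counts
  cat(sprintf("allele_spectrum: %d/%d sites retained (%d low depth, %d low nonref)\n",
              fc[["retained"]], fc[["input"]], fc[["low_depth"]],
              fc[["low_nonref"]]))
  cat("  modes:", paste(signif(x$modes, 3), collapse = ", "), "\n")
  invisible(x)
}

#' Call functional ploidy from an allele-frequency spectrum
#'
#' *functionally_diploid*: a single mode, lying in \[0.40, 0.60\] (the
#' disomic allele-balance expectation of 1/2).  *tetraploid_signature*:
#' modes in both \[0.15, 0.35\] and \[0.65, 0.85\] (the tetrasomic 1/4 and
#' 3/4 dosages), with or without a central 0.5 mode.  Anything else --
#' including fewer than `min_sites` retained sites -- is *ambiguous*.
#'
#' @param spectrum an `allele_spectrum` from [site_spectrum()].
#' @param min_sites minimum retained sites for a confident call.
#' @return object of class `ploidy_call`: list with `verdict`,
#'   `primary_mode` (mode of the tallest modal bin), `evidence` (all
#'   modes), `reason`.
#' @export
classify_ploidy <- function(spectrum, min_sites = 500L) {
  stopifnot(inherits(spectrum, "allele_spectrum"))
  modes <- spectrum$modes
  counts <- spectrum$histogram$count[match(modes, spectrum$histogram$bin_center)]
  primary <- if (length(modes) > 0L) modes[which.max(counts)] else NA_real_
  n <- spectrum$filter_counts[["retained"]]
  if (n < min_sites) {
    out <- list(verdict = "ambiguous", primary_mode = primary,
                evidence = modes,
                reason = sprintf("only %d sites pass filters (< %d)", n,
                                 min_sites))
  } else {
    lower <- any(modes >= 0.15 & modes <= 0.35)
    upper <- any(modes >= 0.65 & modes <= 0.85)
    if (lower && upper) {
      out <- list(verdict = "tetraploid_signature", primary_mode = primary,
                  evidence = modes,
                  reason = "modes at both tetrasomic dosages 1/4 and 3/4")
    } else if (length(modes) == 1L && modes >= 0.40 && modes <= 0.60) {
      out <- list(verdict = "functionally_diploid", primary_mode = primary,
                  evidence = modes,
                  reason = "single mode at the disomic allele balance 1/2")
    } else {
      out <- list(verdict = "ambiguous", primary_mode = primary,
                  evidence = modes,
                  reason = paste("modes at",
                                 paste(signif(modes, 3), collapse = ", "),
                                 "match neither disomic nor tetrasomic dosage"))
    }
  }
  class(out) <- "ploidy_call"
  out
}

#' @export
print.ploidy_call <- function(x, ...) {
  cat("ploidy call:", x$verdict, "\n  ", x$reason, "\n")
  invisible(x)
}
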