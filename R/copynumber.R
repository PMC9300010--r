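# Orthologue copy numbers, the copy-number ratio R_CN (a species' count in a
# group divided by the mean count across the other species), and the
# conserved/duplicated classification of focal-species groups.

#' Orthologue-group copy-number matrix
#'
#' @param groups tidy orthologue-group table (`og_id`, `species`, `gene_id`),
#'   e.g. from [cluster_orthogroups()].
#' @param species character vector of species (matrix columns); species
#'   absent from a group count 0.
#' @return integer matrix, groups x species.
#' @export
copy_number_table <- function(groups, species) {
  stopifnot(length(species) >= 2L)
  if (nrow(groups) == 0L) {
    return(matrix(integer(0), nrow = 0L, ncol = length(species),
                  dimnames = list(NULL, species)))
  }
  tab <- table(factor(groups$og_id, levels = sort(unique(groups$og_id))),
               factor(groups$species, levels = species))
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = list(rownames(tab), species))
  m
}

#' Copy-number ratio R_CN for one orthologue group
#'
#' R_CN = (copy number in the focal species) / (mean copy number across the
#' other species).
#'
#' @param counts named integer vector of per-species copy counts.
#' @param focal focal species name.
#' @return the ratio; `NA` (with a message) when all comparator counts are 0.
#' @export
#' @examples
#' rcn(c(Paus = 2, sp1 = 1, sp2 = 1, sp3 = 1, sp4 = 1, sp5 = 1), "Paus")  # 2
rcn <- function(counts, focal) {
  stopifnot(focal %in% names(counts))
  comp <- counts[setdiff(names(counts), focal)]
  if (length(comp) == 0L) stop("no comparator species in counts")
  m <- mean(comp)
  if (m == 0) {
    message("R_CN undefined: all comparator counts are 0")
    return(NA_real_)
  }
  unname(counts[focal] / m)
}

#' Per-group R_CN table for a copy-number matrix
#'
#' @param matrix copy-number matrix from [copy_number_table()].
#' @param focal focal species (a column of `matrix`).
#' @return data.frame: `og_id`, `focal_count`, `comparator_mean`, `rcn`
#'   (`NA` where every comparator count is 0).
#' @export
rcn_table <- function(matrix, focal) {
  stopifnot(focal %in% colnames(matrix))
  comp <- matrix[, setdiff(colnames(matrix), focal), drop = FALSE]
  cm <- rowMeans(comp)
  data.frame(og_id = rownames(matrix),
             focal_count = as.integer(matrix[, focal]),
             comparator_mean = cm,
             rcn = ifelse(cm > 0, matrix[, focal] / cm, NA_real_),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Classify orthologue groups as conserved, duplicated, or other
#'
#' A group is *conserved* when the focal R_CN lies in `conserved_band` and
#' the focal count equals the rounded comparator mean (the copy number is
#' genuinely unchanged, not merely ratio-compatible); *duplicated* when the
#' focal R_CN lies in `duplicated_band` and the focal count is at least 2.
#' Everything else is *other*.  Groups with all comparator counts 0 (R_CN
#' undefined) are excluded; their number is recorded in the `n_excluded`
#' attribute.  With `strict_equal = TRUE` the conserved class additionally
#' requires every comparator count to equal the focal count.
#'
#' @param matrix copy-number matrix from [copy_number_table()].
#' @param focal focal species name.
#' @param conserved_band,duplicated_band inclusive R_CN intervals.
#' @param strict_equal require exact comparator equality for "conserved".
#' @return data.frame: `og_id`, `focal_count`, `rcn`, `label` (one of
#'   `"conserved"`, `"duplicated"`, `"other"`); attribute `n_excluded`.
#' @export
classify_groups <- function(matrix, focal, conserved_band = c(0.8, 1.25),
                            duplicated_band = c(1.6, 2.5),
                            strict_equal = FALSE) {
  rt <- rcn_table(matrix, focal)
  excluded <- is.na(rt$rcn)
  out <- rt[!excluded, , drop = FALSE]
  comp <- matrix[!excluded, setdiff(colnames(matrix), focal), drop = FALSE]
  round_half_up <- function(x) floor(x + 0.5)
  conserved_count_ok <- if (strict_equal) {
    rowSums(comp != out$focal_count) == 0L
  } else {
    out$focal_count == round_half_up(out$comparator_mean)
  }
  conserved <- out$rcn >= conserved_band[1] & out$rcn <= conserved_band[2] &
    conserved_count_ok
  duplicated_ <- out$rcn >= duplicated_band[1] & out$rcn <= duplicated_band[2] &
    out$focal_count >= 2L
  label <- rep("other", nrow(out))
  label[conserved] <- "conserved"
  label[duplicated_ & !conserved] <- "duplicated"
  res <- data.frame(og_id = out$og_id, focal_count = out$focal_count,
                    rcn = out$rcn, label = label, stringsAsFactors = FALSE)
  attr(res, "n_excluded") <- sum(excluded)
  res
}

#' Duplication fraction among universal single-copy groups
#'
#' The package's stand-in for a duplicated-BUSCO fraction: among orthologue
#' groups that are single-copy in every comparator species, the fraction in
#' which the focal species carries exactly 2 copies.
#'
#' @param matrix copy-number matrix from [copy_number_table()].
#' @param focal focal species name.
#' @return the fraction, with attribute `n_universal` (number of universal
#'   single-copy groups).
#' @export
single_copy_duplication_fraction <- function(matrix, focal) {
  stopifnot(nrow(matrix) > 0L, focal %in% colnames(matrix))
  comp <- matrix[, setdiff(colnames(matrix), focal), drop = FALSE]
  universal <- rowSums(comp != 1L) == 0L
  if (!any(universal))
    stop("no groups are single-copy in every comparator species")
  frac <- mean(matrix[universal, focal] == 2L)
  attr(frac, "n_universal") <- sum(universal)
  frac
}

#' R_CN histogram with modes
#'
#' Histograms R_CN values at `bin_width` (bins centered on multiples of the
#' width, so the expected peaks at 1 and 2 fall at bin centers) and reports
#' modal bin centers.
#'
#' @param values numeric R_CN values (NA dropped).
#' @param bin_width histogram bin width.
#' @param min_frac minimum fraction of groups a bin must hold to count as a
#'   mode.
#' @return list with `histogram` and `modes` (see [histogram_modes()]).
#' @export
rcn_histogram <- function(values, bin_width = 0.25, min_frac = 0.05) {
  histogram_modes(values[!is.na(values)], bin_width, min_frac)
}
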