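# On-disk interchange for simulated datasets: CDS FASTA (60-column wrap),
# 6-column BED (0-based half-open), and headered TSV truth/annotation tables.
# write_fixture() and read_fixture() round-trip losslessly.

#' Write a simulated dataset to plain-text files
#'
#' Emits, per species, a CDS FASTA (`<species>_cds.fasta`) and a BED6 gene
#' table (`<species>_genes.bed`, 0-based half-open, score column 0), plus
#' `gene_categories.tsv` (gene -> category, doubling as the flat GO-like
#' annotation map), and the ground-truth tables `truth_orthogroups.tsv`,
#' `truth_retained.tsv`, and `truth_blocks.tsv`.
#'
#' @param dataset a `wgd_simulation` from [simulate_dataset()].
#' @param directory output directory; created if absent.
#' @return invisibly, the vector of paths written.
#' @export
write_fixture <- function(dataset, directory) {
  stopifnot(inherits(dataset, "wgd_simulation"))
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(directory))
      stop("cannot create directory: ", directory)
  }
  paths <- character(0)
  for (sp in names(dataset$genes)) {
    g <- dataset$genes[[sp]]
    fa <- file.path(directory, paste0(sp, "_cds.fasta"))
    dna <- Biostrings::DNAStringSet(stats::setNames(g$cds, g$gene_id))
    Biostrings::writeXStringSet(dna, fa, width = 60L)
    bed <- file.path(directory, paste0(sp, "_genes.bed"))
    utils::write.table(
      data.frame(g$chromosome, g$start, g$end, g$gene_id, 0L, g$strand),
      bed, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    paths <- c(paths, fa, bed)
  }
  ann <- do.call(rbind, lapply(dataset$genes, function(g)
    data.frame(gene_id = g$gene_id, species = g$species, term_id = g$category,
               stringsAsFactors = FALSE)))
  rownames(ann) <- NULL
  p <- file.path(directory, "gene_categories.tsv")
  .write_tsv(ann, p)
  paths <- c(paths, p)

  p <- file.path(directory, "truth_orthogroups.tsv")
  .write_tsv(dataset$truth$orthogroups, p)
  paths <- c(paths, p)
  p <- file.path(directory, "truth_retained.tsv")
  .write_tsv(data.frame(ancestral_id = dataset$truth$retained_duplicates), p)
  paths <- c(paths, p)
  p <- file.path(directory, "truth_blocks.tsv")
  .write_tsv(dataset$truth$true_blocks, p)
  paths <- c(paths, p)
  invisible(paths)
}

#' Read a dataset written by [write_fixture()]
#'
#' @param directory directory containing the fixture files.
#' @return a list with `genes` (named list of per-species gene-model
#'   data.frames), `annotations` (gene -> term table), and `truth` (if the
#'   truth tables are present).
#' @export
read_fixture <- function(directory) {
  if (!dir.exists(directory)) stop("no such directory: ", directory)
  beds <- list.files(directory, pattern = "_genes\\.bed$", full.names = TRUE)
  if (length(beds) == 0L) stop("no *_genes.bed files in ", directory)
  ann_path <- file.path(directory, "gene_categories.tsv")
  ann <- if (file.exists(ann_path)) .read_tsv(ann_path) else NULL
  genes <- list()
  for (bed in sort(beds)) {
    sp <- sub("_genes\\.bed$", "", basename(bed))
    b <- utils::read.delim(bed, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("chromosome", "start", "end",
                                         "gene_id", "score", "strand"))
    fa <- file.path(directory, paste0(sp, "_cds.fasta"))
    if (!file.exists(fa)) stop("missing CDS FASTA for species ", sp, ": ", fa)
    dna <- Biostrings::readDNAStringSet(fa)
    cds <- stats::setNames(as.character(dna), names(dna))
    b <- b[order(b$chromosome, b$start), , drop = FALSE]
    oi <- stats::ave(b$start, b$chromosome, FUN = function(x) seq_along(x) - 1L)
    g <- data.frame(gene_id = b$gene_id, species = sp,
                    chromosome = b$chromosome, order_index = as.integer(oi),
                    start = b$start, end = b$end, strand = b$strand,
                    stringsAsFactors = FALSE)
    if (!is.null(ann)) {
      cat_map <- ann$term_id[match(g$gene_id, ann$gene_id)]
      g$category <- cat_map
    }
    g$cds <- unname(cds[g$gene_id])
    if (anyNA(g$cds)) stop("FASTA for species ", sp, " lacks some gene_ids")
    genes[[sp]] <- g
  }
  truth <- NULL
  tog <- file.path(directory, "truth_orthogroups.tsv")
  if (file.exists(tog)) {
    truth <- list(
      orthogroups = .read_tsv(tog),
      retained_duplicates =
        .read_tsv(file.path(directory, "truth_retained.tsv"))$ancestral_id,
      true_blocks = .read_tsv(file.path(directory, "truth_blocks.tsv"))
    )
  }
  list(genes = genes, annotations = ann, truth = truth)
}
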