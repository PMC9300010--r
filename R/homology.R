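# Pairwise protein similarity, reciprocal best hits, and orthologue-group
# clustering.  Homology is scored at the protein level (BLOSUM62, affine
# gaps) so that synonymous divergence -- which the Ks stage later measures --
# cannot weaken the homology calls.

.translate_checked <- function(genes) {
  dna <- Biostrings::DNAStringSet(stats::setNames(genes$cds, genes$gene_id))
  aa <- as.character(suppressWarnings(
    Biostrings::translate(dna, if.fuzzy.codon = "X")))
  internal_stop <- grepl("\\*", sub("\\*$", "", aa))
  if (any(internal_stop)) {
    warning("skipping ", sum(internal_stop),
            " gene(s) with internal stop codons: ",
            paste(utils::head(genes$gene_id[internal_stop], 5L), collapse = ", "),
            if (sum(internal_stop) > 5L) ", ..." else "")
  }
  aa <- sub("\\*$", "", aa)
  aa[!internal_stop]
}

# Identity and BLOSUM62 score matrices for two sets of equal-length protein
# sequences.  For indel-free homologues the optimal affine-gap global
# alignment is the gapless one (every gap costs more than any substitution
# gains), so the gapless score is computed directly with vectorised
# cross-products; this is exact for equal-length homologues and only
# underestimates scores of unrelated pairs, which fall below the identity
# threshold either way.
.score_equal_length <- function(aaA, aaB) {
  L <- nchar(aaA[1])
  A <- matrix(unlist(strsplit(aaA, ""), use.names = FALSE),
              nrow = length(aaA), byrow = TRUE)
  B <- matrix(unlist(strsplit(aaB, ""), use.names = FALSE),
              nrow = length(aaB), byrow = TRUE)
  b62 <- .blosum62()
  letters <- sort(unique(c(as.vector(A), as.vector(B))))
  id <- matrix(0, nrow(A), nrow(B))
  sc <- matrix(0, nrow(A), nrow(B))
  for (r in letters) {
    Ia <- (A == r) * 1
    id <- id + tcrossprod(Ia, (B == r) * 1)
    sc <- sc + tcrossprod(Ia, matrix(b62[r, B], nrow(B), L))
  }
  list(identity = id / L, score = sc)
}

.align_unequal <- function(aaA, aaB) {
  # affine-gap global alignment for length-mismatched pairs
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(aaA), Biostrings::AAString(aaB),
    substitutionMatrix = .blosum62(), gapOpening = 10, gapExtension = 1,
    type = "global")
  nm <- Biostrings::nmatch(pa)
  nmm <- Biostrings::nmismatch(pa)
  aligned <- nm + nmm
  list(identity = ifelse(aligned > 0, nm / aligned, 0),
       score = Biostrings::score(pa),
       qcov = aligned / nchar(aaA),
       scov = aligned / nchar(aaB))
}

#' Score all gene pairs between (or within) two gene sets
#'
#' Translates the coding sequences and computes global protein alignments
#' with BLOSUM62 scoring and affine gaps (open 10, extend 1).  Genes with an
#' internal stop codon are skipped with a warning.  Hits are reported in both
#' directions (the alignment is symmetric; query/subject coverages swap), and
#' self pairs are excluded in within-set comparisons.
#'
#' @param genesA gene-model data.frame (columns `gene_id`, `species`, `cds`).
#' @param genesB second gene set; omit (or pass `NULL`) for a within-set
#'   (self) comparison.
#' @param min_identity minimum fraction of identical aligned residues for a
#'   pair to be reported.
#' @param min_coverage minimum aligned fraction of both sequences.
#' @return data.frame of hits: `query`, `subject`, `species_q`, `species_s`,
#'   `identity`, `qcov`, `scov`, `score`.
#' @export
#' @examples
#' g <- data.frame(gene_id = c("a", "b"), species = "sp",
#'                 cds = c("ATGGGAGGT", "ATGGGAGGT"))
#' score_pairs(g)  # identical proteins: identity 1
score_pairs <- function(genesA, genesB = NULL, min_identity = 0.5,
                        min_coverage = 0.5) {
  stopifnot(nrow(genesA) > 0L)
  self <- is.null(genesB)
  if (self) genesB <- genesA
  stopifnot(nrow(genesB) > 0L)
  aaA <- .translate_checked(genesA)
  aaB <- if (self) aaA else .translate_checked(genesB)
  if (length(aaA) == 0L || length(aaB) == 0L) return(.empty_hits())
  spA <- stats::setNames(genesA$species, genesA$gene_id)
  spB <- stats::setNames(genesB$species, genesB$gene_id)

  hits <- list()
  lenA <- nchar(aaA)
  lenB <- nchar(aaB)
  for (la in sort(unique(lenA))) {
    ia <- which(lenA == la)
    # equal-length pairs: vectorised gapless scoring
    ib <- which(lenB == la)
    if (length(ib) > 0L) {
      m <- .score_equal_length(aaA[ia], aaB[ib])
      pass <- which(m$identity >= min_identity & 1 >= min_coverage,
                    arr.ind = TRUE)
      if (self) {
        keep <- names(aaA)[ia][pass[, 1L]] != names(aaB)[ib][pass[, 2L]]
        pass <- pass[keep, , drop = FALSE]
      }
      if (nrow(pass) > 0L) {
        hits[[length(hits) + 1L]] <- data.frame(
          query = names(aaA)[ia][pass[, 1L]],
          subject = names(aaB)[ib][pass[, 2L]],
          identity = m$identity[pass],
          qcov = 1, scov = 1,
          score = m$score[pass],
          stringsAsFactors = FALSE)
      }
    }
    # length-mismatched pairs: affine-gap global alignment
    ib2 <- which(lenB != la)
    for (j in ib2) {
      al <- .align_unequal(aaA[ia], aaB[[j]])
      ok <- which(al$identity >= min_identity & al$qcov >= min_coverage &
                    al$scov >= min_coverage)
      if (length(ok) > 0L) {
        hits[[length(hits) + 1L]] <- data.frame(
          query = names(aaA)[ia][ok],
          subject = names(aaB)[j],
          identity = al$identity[ok],
          qcov = al$qcov[ok], scov = al$scov[ok],
          score = al$score[ok],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits) == 0L) return(.empty_hits())
  h <- do.call(rbind, hits)
  # report both directions; coverages swap, identity and score are symmetric
  h <- rbind(h, data.frame(query = h$subject, subject = h$query,
                           identity = h$identity, qcov = h$scov,
                           scov = h$qcov, score = h$score,
                           stringsAsFactors = FALSE))
  h <- h[!duplicated(h[, c("query", "subject")]), , drop = FALSE]
  h$species_q <- unname(c(spA, spB)[h$query])
  h$species_s <- unname(c(spA, spB)[h$subject])
  h <- h[order(h$query, h$subject), , drop = FALSE]
  rownames(h) <- NULL
  h[, c("query", "subject", "species_q", "species_s", "identity",
        "qcov", "scov", "score")]
}

.empty_hits <- function() {
  data.frame(query = character(0), subject = character(0),
             species_q = character(0), species_s = character(0),
             identity = numeric(0), qcov = numeric(0), scov = numeric(0),
             score = numeric(0), stringsAsFactors = FALSE)
}

#' Reciprocal best hits
#'
#' A pair (a, b) is reported iff b is a's top-scoring subject and a is b's
#' top-scoring subject.  Score ties are broken towards the lexicographically
#' smallest subject id; the number of ties broken is recorded in the
#' `n_ties` attribute of the result.
#'
#' @param hits hit table from [score_pairs()] (both directions present).
#' @return data.frame with columns `gene_a`, `gene_b` (`gene_a < gene_b`),
#'   `score`; attribute `n_ties`.
#' @export
reciprocal_best_hits <- function(hits) {
  if (nrow(hits) == 0L) {
    out <- data.frame(gene_a = character(0), gene_b = character(0),
                      score = numeric(0), stringsAsFactors = FALSE)
    attr(out, "n_ties") <- 0L
    return(out)
  }
  h <- hits[order(hits$query, -hits$score, hits$subject), , drop = FALSE]
  first <- !duplicated(h$query)
  best <- stats::setNames(h$subject[first], h$query[first])
  best_score <- stats::setNames(h$score[first], h$query[first])
  # ties: more than one subject at the top score for a query
  top <- h[h$score == best_score[h$query], , drop = FALSE]
  n_ties <- sum(table(top$query) > 1L)
  q <- names(best)
  mutual <- !is.na(best[best[q]]) & best[best[q]] == q
  a <- q[mutual]
  b <- unname(best[a])
  keep <- a < b
  out <- data.frame(gene_a = a[keep], gene_b = b[keep],
                    score = unname(best_score[a[keep]]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_ties") <- n_ties
  out
}

#' Cluster genes into orthologue groups
#'
#' Builds a graph whose edges are (i) cross-species reciprocal-best-hit
#' pairs, computed per species pair, and (ii) within-species hits whose score
#' is at least the weakest cross-species RBH score of the connected component
#' either endpoint belongs to -- this is what lets both WGD copies of a focal
#' gene join the group anchored by their single-copy orthologues.  Orthologue
#' groups are the connected components with at least two members
#' (single-linkage clustering).
#'
#' @param hits combined hit table from [score_pairs()] runs covering the
#'   cross-species comparisons and any within-species (self) comparisons.
#' @return tidy data.frame: `og_id`, `species`, `gene_id`.  Group ids are
#'   assigned in order of each group's smallest gene id.
#' @export
cluster_orthogroups <- function(hits) {
  stopifnot(all(c("query", "subject", "species_q", "species_s", "score")
                %in% names(hits)))
  cross <- hits[hits$species_q != hits$species_s, , drop = FALSE]
  if (nrow(cross) == 0L) {
    return(data.frame(og_id = character(0), species = character(0),
                      gene_id = character(0), stringsAsFactors = FALSE))
  }
  sp_pair <- ifelse(cross$species_q < cross$species_s,
                    paste(cross$species_q, cross$species_s),
                    paste(cross$species_s, cross$species_q))
  rbh <- do.call(rbind, lapply(split(cross, sp_pair), reciprocal_best_hits))
  rownames(rbh) <- NULL
  if (nrow(rbh) == 0L) {
    return(data.frame(og_id = character(0), species = character(0),
                      gene_id = character(0), stringsAsFactors = FALSE))
  }
  g <- igraph::graph_from_data_frame(rbh[, c("gene_a", "gene_b")],
                                     directed = FALSE)
  comp <- igraph::components(g)$membership
  # weakest RBH score per component
  edge_comp <- comp[rbh$gene_a]
  comp_min <- tapply(rbh$score, edge_comp, min)

  within <- hits[hits$species_q == hits$species_s &
                   hits$query != hits$subject, , drop = FALSE]
  extra <- NULL
  if (nrow(within) > 0L) {
    ca <- comp[within$query]
    cb <- comp[within$subject]
    thr <- pmin(unname(comp_min[as.character(ca)]),
                unname(comp_min[as.character(cb)]), na.rm = TRUE)
    thr[is.na(ca) & is.na(cb)] <- NA
    ok <- !is.na(thr) & within$score >= thr
    extra <- within[ok, c("query", "subject"), drop = FALSE]
  }
  edges <- rbind(stats::setNames(rbh[, c("gene_a", "gene_b")], c("a", "b")),
                 if (!is.null(extra) && nrow(extra) > 0L)
                   stats::setNames(extra, c("a", "b")))
  g2 <- igraph::graph_from_data_frame(edges, directed = FALSE)
  memb <- igraph::components(g2)$membership
  df <- data.frame(gene_id = names(memb), comp = unname(memb),
                   stringsAsFactors = FALSE)
  sizes <- table(df$comp)
  df <- df[df$comp %in% names(sizes)[sizes >= 2L], , drop = FALSE]
  # deterministic group ids ordered by smallest member gene id
  min_gene <- tapply(df$gene_id, df$comp, min)
  comp_rank <- rank(min_gene)
  df$og_id <- sprintf("OG%05d", comp_rank[as.character(df$comp)])
  sp_map <- stats::setNames(
    c(hits$species_q, hits$species_s), c(hits$query, hits$subject))
  df$species <- unname(sp_map[df$gene_id])
  df <- df[order(df$og_id, df$species, df$gene_id), , drop = FALSE]
  rownames(df) <- NULL
  df[, c("og_id", "species", "gene_id")]
}
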