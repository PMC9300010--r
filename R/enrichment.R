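# Flat GO-like annotation transfer, hypergeometric over-representation
# tests with Benjamini-Hochberg correction, and overlap-based clustering of
# enriched terms.  Annotations are flat term -> gene sets (no DAG ancestor
# propagation); the simulator's gene categories play the role of terms.

#' Transfer annotations across a homology search
#'
#' A query gene receives every term of every annotated subject it hits with
#' at least `min_coverage` aligned fraction of *both* sequences (the
#' bidirectional 30% coverage rule); terms from multiple hits are unioned.
#'
#' @param query_hits hit table from [score_pairs()] (`query`, `subject`,
#'   `qcov`, `scov`).
#' @param reference_annotations data.frame `gene_id`, `term_id` annotating
#'   the subject side.
#' @param min_coverage minimum aligned fraction of each sequence.
#' @return data.frame `gene_id`, `term_id` for the query side (unique rows).
#' @export
transfer_annotations <- function(query_hits, reference_annotations,
                                 min_coverage = 0.30) {
  h <- query_hits[query_hits$qcov >= min_coverage &
                    query_hits$scov >= min_coverage, , drop = FALSE]
  m <- merge(h[, c("query", "subject")], reference_annotations,
             by.x = "subject", by.y = "gene_id")
  out <- unique(data.frame(gene_id = m$query, term_id = m$term_id,
                           stringsAsFactors = FALSE))
  out <- out[order(out$gene_id, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Hypergeometric over-representation test with BH correction
#'
#' For each term annotating at least one gene of the set, tests
#' over-representation of the term in `gene_set` against `background` by the
#' upper-tail hypergeometric probability P(X >= k), where k genes of the
#' n-gene set and K genes of the N-gene background carry the term.
#' Benjamini-Hochberg adjustment is applied across all tested terms of this
#' set/background pairing.
#'
#' @param gene_set character vector, a subset of `background`.
#' @param background character vector, the gene universe (annotated or not).
#' @param annotations data.frame `gene_id`, `term_id`.
#' @return data.frame sorted by `p_adj` then `term_id`: `term_id`, `k`, `n`,
#'   `K`, `N`, `p`, `p_adj`.
#' @export
#' @examples
#' ann <- data.frame(gene_id = paste0("g", 1:5), term_id = "T")
#' enrich_terms(paste0("g", 1:4), paste0("g", 1:10), ann)  # p = 5/210
enrich_terms <- function(gene_set, background, annotations) {
  if (length(gene_set) == 0L) stop("gene_set is empty")
  if (length(background) == 0L) stop("background is empty")
  gene_set <- unique(gene_set)
  background <- unique(background)
  if (!all(gene_set %in% background))
    stop("gene_set must be a subset of background")
  ann <- unique(annotations[annotations$gene_id %in% background, , drop = FALSE])
  if (nrow(ann) == 0L) {
    return(data.frame(term_id = character(0), k = integer(0), n = integer(0),
                      K = integer(0), N = integer(0), p = numeric(0),
                      p_adj = numeric(0), stringsAsFactors = FALSE))
  }
  n <- length(gene_set)
  N <- length(background)
  K_tab <- table(ann$term_id)
  in_set <- ann[ann$gene_id %in% gene_set, , drop = FALSE]
  k_tab <- table(in_set$term_id)
  terms <- names(k_tab)[k_tab >= 1L]      # only terms present in the set
  k <- as.integer(k_tab[terms])
  K <- as.integer(K_tab[terms])
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(term_id = terms, k = k, n = n, K = K, N = N, p = p,
                    p_adj = stats::p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_adj, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cluster enriched terms by gene-set overlap
#'
#' Terms are sorted by annotated-gene-set size (largest first); each term
#' joins the first existing cluster whose representative (the cluster's
#' largest term) shares at least `overlap` of the smaller of the two gene
#' sets, otherwise it seeds a new cluster.  The `top_k` clusters by size of
#' the member-gene union are returned.
#'
#' @param rows enrichment rows ([enrich_terms()] output), typically already
#'   filtered to significant terms.
#' @param annotations data.frame `gene_id`, `term_id` defining term gene
#'   sets.
#' @param overlap minimum shared fraction of the smaller gene set.
#' @param top_k number of clusters to return.
#' @return data.frame: `cluster_id`, `representative`, `n_terms`, `n_genes`,
#'   `members` (comma-separated term ids).
#' @export
cluster_terms <- function(rows, annotations, overlap = 0.80, top_k = 5L) {
  if (nrow(rows) == 0L) {
    return(data.frame(cluster_id = character(0), representative = character(0),
                      n_terms = integer(0), n_genes = integer(0),
                      members = character(0), stringsAsFactors = FALSE))
  }
  sets <- split(annotations$gene_id, annotations$term_id)
  sets <- lapply(sets, unique)
  terms <- rows$term_id[rows$term_id %in% names(sets)]
  sizes <- vapply(sets[terms], length, integer(1))
  terms <- terms[order(-sizes, terms)]
  reps <- character(0)
  members <- list()
  for (t in terms) {
    placed <- FALSE
    for (ci in seq_along(reps)) {
      a <- sets[[reps[ci]]]
      b <- sets[[t]]
      shared <- length(intersect(a, b)) / min(length(a), length(b))
      if (shared >= overlap) {
        members[[ci]] <- c(members[[ci]], t)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, t)
      members[[length(reps)]] <- t
    }
  }
  union_sizes <- vapply(members, function(m)
    length(unique(unlist(sets[m]))), integer(1))
  ord <- order(-union_sizes, reps)
  keep <- utils::head(ord, top_k)
  data.frame(cluster_id = paste0("C", seq_along(keep)),
             representative = reps[keep],
             n_terms = lengths(members)[keep],
             n_genes = union_sizes[keep],
             members = vapply(members[keep], paste, character(1),
                              collapse = ","),
             stringsAsFactors = FALSE, row.names = NULL)
}
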