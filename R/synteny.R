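# Colinear synteny-block detection by anchor chaining in gene-order
# coordinates, and syntenic-depth summaries.  Chains are maximum-weight
# monotone subsequences of anchors (strictly increasing on the A side,
# strictly monotone on the B side), with a gap penalty per skipped gene and a
# hard cap on the gap size; non-overlapping blocks are extracted greedily by
# descending chain score.

#' Build an anchor table from homology hits and gene positions
#'
#' Joins a hit table onto gene-order coordinates.  Anchors are directed
#' A -> B: only hits whose query belongs to `genesA` and subject to `genesB`
#' are used, so pass the two gene tables in the orientation you want the
#' blocks reported in.  The anchor weight is the hit identity.
#'
#' @param hits hit table from [score_pairs()].
#' @param genesA,genesB gene-model data.frames with `gene_id`, `species`,
#'   `chromosome`, `order_index`.
#' @return anchor data.frame: `gene_a`, `gene_b`, `species_a`, `species_b`,
#'   `chr_a`, `idx_a`, `chr_b`, `idx_b`, `score`.
#' @export
anchors_from_hits <- function(hits, genesA, genesB) {
  h <- hits[hits$query %in% genesA$gene_id &
              hits$subject %in% genesB$gene_id, , drop = FALSE]
  ia <- match(h$query, genesA$gene_id)
  ib <- match(h$subject, genesB$gene_id)
  a <- data.frame(gene_a = h$query, gene_b = h$subject,
                  species_a = genesA$species[ia], species_b = genesB$species[ib],
                  chr_a = genesA$chromosome[ia], idx_a = genesA$order_index[ia],
                  chr_b = genesB$chromosome[ib], idx_b = genesB$order_index[ib],
                  score = h$identity, stringsAsFactors = FALSE)
  a <- a[order(a$chr_a, a$idx_a, a$chr_b, a$idx_b), , drop = FALSE]
  rownames(a) <- NULL
  a
}

# Best chain over one chromosome pair for one B-side direction.
# a: anchors sorted by idx_a (strictly handled in DP); dir: +1 (same) or -1
# (inverted).  f(j) = w_j + max(0, max over compatible i of f(i) - gap(i,j)),
# gap(i, j) = gap_penalty * (skipped genes on A + skipped genes on B);
# links with more than max_gap skipped genes on either side are forbidden.
# Returns list(score, chain indices into a) or NULL.
.chain_dir <- function(a, dir, max_gap, gap_penalty) {
  n <- nrow(a)
  f <- numeric(n)
  prev <- integer(n)
  b <- a$idx_b * dir
  for (j in seq_len(n)) {
    f[j] <- a$score[j]
    prev[j] <- 0L
    if (j > 1L) {
      i <- seq_len(j - 1L)
      ga <- a$idx_a[j] - a$idx_a[i] - 1L
      gb <- b[j] - b[i] - 1L
      ok <- ga >= 0L & a$idx_a[j] > a$idx_a[i] & gb >= 0L &
        ga <= max_gap & gb <= max_gap
      if (any(ok)) {
        cand <- f[i][ok] - gap_penalty * (ga[ok] + gb[ok])
        best <- which.max(cand)
        if (cand[best] > 0) {
          f[j] <- f[j] + cand[best]
          prev[j] <- i[ok][best]
        }
      }
    }
  }
  end <- which.max(f)
  chain <- integer(0)
  j <- end
  while (j != 0L) {
    chain <- c(j, chain)
    j <- prev[j]
  }
  list(score = f[end], chain = chain)
}

#' Detect colinear synteny blocks by anchor chaining
#'
#' Within each chromosome pair, repeatedly extracts the highest-scoring
#' monotone anchor chain (both B-side orientations searched), assigns its
#' anchors to a block, and continues on the remaining anchors; chains with
#' fewer than `min_anchors` anchors are discarded.  Each anchor belongs to at
#' most one block.
#'
#' @param anchors anchor table from [anchors_from_hits()].
#' @param min_anchors minimum colinear anchor pairs per reported block.
#' @param max_gap maximum number of skipped genes between consecutive
#'   anchors, per genome.
#' @param gap_penalty chain-score penalty per skipped gene (anchor scores are
#'   identities, i.e. about 1 per anchor).
#' @return object of class `synteny_blocks`: list with `blocks` (one row per
#'   block: `block_id`, `species_a`, `species_b`, `chr_a`, `start_a`,
#'   `end_a`, `chr_b`, `start_b`, `end_b`, `n_anchors`, `orientation`,
#'   `score`) and `anchors` (the input anchors of reported blocks with a
#'   `block_id` column).
#' @export
detect_blocks <- function(anchors, min_anchors = 5L, max_gap = 10L,
                          gap_penalty = 0.1) {
  if (is.null(anchors)) {
    anchors <- data.frame(gene_a = character(0), gene_b = character(0),
                          species_a = character(0), species_b = character(0),
                          chr_a = character(0), idx_a = integer(0),
                          chr_b = character(0), idx_b = integer(0),
                          score = numeric(0), stringsAsFactors = FALSE)
  }
  empty <- list(
    blocks = data.frame(block_id = character(0), species_a = character(0),
                        species_b = character(0), chr_a = character(0),
                        start_a = integer(0), end_a = integer(0),
                        chr_b = character(0), start_b = integer(0),
                        end_b = integer(0), n_anchors = integer(0),
                        orientation = character(0), score = numeric(0),
                        stringsAsFactors = FALSE),
    anchors = cbind(anchors[0, , drop = FALSE],
                    data.frame(block_id = character(0))))
  class(empty) <- "synteny_blocks"
  if (is.null(anchors) || nrow(anchors) == 0L) return(empty)
  blocks <- list()
  banchors <- list()
  nb <- 0L
  for (key in unique(paste(anchors$chr_a, anchors$chr_b, sep = "\r"))) {
    sel <- paste(anchors$chr_a, anchors$chr_b, sep = "\r") == key
    a <- anchors[sel, , drop = FALSE]
    a <- a[order(a$idx_a, a$idx_b), , drop = FALSE]
    active <- rep(TRUE, nrow(a))
    repeat {
      if (!any(active)) break
      aa <- a[active, , drop = FALSE]
      fwd <- .chain_dir(aa, +1L, max_gap, gap_penalty)
      rev <- .chain_dir(aa, -1L, max_gap, gap_penalty)
      best <- if (fwd$score >= rev$score) fwd else rev
      orientation <- if (fwd$score >= rev$score) "same" else "inverted"
      if (best$score <= 0 || length(best$chain) == 0L) break
      idx_active <- which(active)[best$chain]
      active[idx_active] <- FALSE
      if (length(best$chain) < min_anchors) {
        # too short to report; drop its anchors and keep looking
        if (!any(active)) break
        next
      }
      nb <- nb + 1L
      ca <- a[idx_active, , drop = FALSE]
      blocks[[nb]] <- data.frame(
        block_id = NA_character_,
        species_a = ca$species_a[1], species_b = ca$species_b[1],
        chr_a = ca$chr_a[1], start_a = min(ca$idx_a), end_a = max(ca$idx_a),
        chr_b = ca$chr_b[1], start_b = min(ca$idx_b), end_b = max(ca$idx_b),
        n_anchors = nrow(ca), orientation = orientation, score = best$score,
        stringsAsFactors = FALSE)
      ca$block_id <- NA_character_
      banchors[[nb]] <- ca
    }
  }
  if (nb == 0L) return(empty)
  bl <- do.call(rbind, blocks)
  # deterministic ids: by position, then score
  ord <- order(bl$chr_a, bl$start_a, bl$chr_b, bl$start_b, -bl$score)
  bl <- bl[ord, , drop = FALSE]
  bl$block_id <- sprintf("SB%04d", seq_len(nrow(bl)))
  banchors <- banchors[ord]
  for (i in seq_along(banchors)) banchors[[i]]$block_id <- bl$block_id[i]
  an <- do.call(rbind, banchors)
  rownames(bl) <- NULL
  rownames(an) <- NULL
  out <- list(blocks = bl, anchors = an)
  class(out) <- "synteny_blocks"
  out
}

#' @export
print.synteny_blocks <- function(x, ...) {
  cat("synteny_blocks:", nrow(x$blocks), "blocks,",
      nrow(x$anchors), "anchors\n")
  if (nrow(x$blocks) > 0L) print(utils::head(x$blocks, 10L))
  invisible(x)
}

#' Self-synteny: paralogous blocks within one genome
#'
#' Prepares within-genome anchors from a self hit table and chains them.
#' Self matches (a gene hitting itself) are removed; tandem arrays
#' (paralogues within `tandem_window` genes on one chromosome) are collapsed
#' to their lowest-index representative before chaining, so an array
#' contributes one anchor, not one per member; each unordered paralogue pair
#' is used once, oriented so the A side is the lexicographically smaller
#' (chromosome, index) position.
#'
#' @param genome gene-model data.frame of one species.
#' @param hits self hit table from `score_pairs(genome)`.
#' @param min_anchors,max_gap,gap_penalty see [detect_blocks()].
#' @param tandem_window maximum gene distance for two same-chromosome
#'   paralogues to count as a tandem array.
#' @return a `synteny_blocks` object (see [detect_blocks()]).
#' @export
self_synteny <- function(genome, hits, min_anchors = 5L, max_gap = 10L,
                         gap_penalty = 0.1, tandem_window = 5L) {
  h <- hits[hits$query != hits$subject &
              hits$species_q == hits$species_s, , drop = FALSE]
  if (nrow(h) == 0L) return(detect_blocks(NULL))
  pos <- genome[match(c(h$query, h$subject), genome$gene_id), ]
  hq <- pos[seq_len(nrow(h)), ]
  hs <- pos[nrow(h) + seq_len(nrow(h)), ]
  # tandem collapse: union same-chromosome pairs within the window
  tandem <- hq$chromosome == hs$chromosome &
    abs(hq$order_index - hs$order_index) <= tandem_window
  rep_of <- stats::setNames(genome$gene_id, genome$gene_id)
  if (any(tandem)) {
    tg <- igraph::graph_from_data_frame(
      data.frame(h$query[tandem], h$subject[tandem]), directed = FALSE)
    memb <- igraph::components(tg)$membership
    for (cl in split(names(memb), memb)) {
      ord <- order(genome$order_index[match(cl, genome$gene_id)])
      rep_of[cl] <- cl[ord[1L]]
    }
  }
  h$query <- unname(rep_of[h$query])
  h$subject <- unname(rep_of[h$subject])
  h <- h[h$query != h$subject, , drop = FALSE]
  if (nrow(h) == 0L) return(detect_blocks(NULL))
  # canonical orientation: A side is the smaller (chromosome, order) position
  ia <- match(h$query, genome$gene_id)
  ib <- match(h$subject, genome$gene_id)
  a_first <- genome$chromosome[ia] < genome$chromosome[ib] |
    (genome$chromosome[ia] == genome$chromosome[ib] &
       genome$order_index[ia] < genome$order_index[ib])
  ga <- ifelse(a_first, h$query, h$subject)
  gb <- ifelse(a_first, h$subject, h$query)
  ja <- match(ga, genome$gene_id)
  jb <- match(gb, genome$gene_id)
  anch <- data.frame(gene_a = ga, gene_b = gb,
                     species_a = genome$species[ja],
                     species_b = genome$species[jb],
                     chr_a = genome$chromosome[ja], idx_a = genome$order_index[ja],
                     chr_b = genome$chromosome[jb], idx_b = genome$order_index[jb],
                     score = h$identity, stringsAsFactors = FALSE)
  anch <- anch[!duplicated(anch[, c("gene_a", "gene_b")]), , drop = FALSE]
  anch <- anch[order(anch$chr_a, anch$idx_a, anch$chr_b, anch$idx_b), ,
               drop = FALSE]
  rownames(anch) <- NULL
  detect_blocks(anch, min_anchors = min_anchors, max_gap = max_gap,
                gap_penalty = gap_penalty)
}

#' Syntenic depth of a reference genome
#'
#' For each reference gene, counts the distinct blocks of the other genome
#' whose reference-side span covers its position, and summarises the
#' fractions of reference genes covered 0, 1, 2, or more than 2 times.  A
#' 2:1 depth pattern (most genes covered twice) is the classic footprint of
#' a WGD in the other genome.
#'
#' @param blocks a `synteny_blocks` object whose blocks all pair the
#'   reference species with one other genome (reference on either side).
#' @param reference reference species name.
#' @param reference_genome gene-model data.frame of the reference species.
#' @return list with `per_gene` (data.frame `gene_id`, `coverage`) and
#'   `fractions` (named numeric: `"0"`, `"1"`, `"2"`, `">2"`, summing to 1).
#' @export
syntenic_depth <- function(blocks, reference, reference_genome) {
  bl <- blocks$blocks
  if (nrow(bl) > 0L) {
    pairs <- unique(paste(bl$species_a, bl$species_b))
    if (length(pairs) > 1L)
      stop("blocks mix species pairs: ", paste(pairs, collapse = "; "))
    if (!all(bl$species_a == reference | bl$species_b == reference))
      stop("blocks do not involve reference species ", reference)
  }
  cov <- integer(nrow(reference_genome))
  for (i in seq_len(nrow(bl))) {
    if (bl$species_a[i] == reference) {
      chr <- bl$chr_a[i]; lo <- bl$start_a[i]; hi <- bl$end_a[i]
    } else {
      chr <- bl$chr_b[i]; lo <- bl$start_b[i]; hi <- bl$end_b[i]
    }
    hit <- reference_genome$chromosome == chr &
      reference_genome$order_index >= lo & reference_genome$order_index <= hi
    cov[hit] <- cov[hit] + 1L
  }
  fr <- c("0" = mean(cov == 0L), "1" = mean(cov == 1L),
          "2" = mean(cov == 2L), ">2" = mean(cov > 2L))
  list(per_gene = data.frame(gene_id = reference_genome$gene_id,
                             coverage = cov, stringsAsFactors = FALSE),
       fractions = fr)
}
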