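colinear_anchors <- function(n, idx_b = seq_len(n), score = 1) {
  data.frame(gene_a = paste0("a", seq_len(n)), gene_b = paste0("b", seq_len(n)),
             species_a = "A", species_b = "B",
             chr_a = "c1", idx_a = seq_len(n),
             chr_b = "c1", idx_b = idx_b,
             score = score, stringsAsFactors = FALSE)
}

test_that("blocks need at least min_anchors colinear pairs", {
  expect_equal(nrow(detect_blocks(colinear_anchors(4))$blocks), 0L)
  res <- detect_blocks(colinear_anchors(5))
  expect_equal(nrow(res$blocks), 1L)
  expect_equal(res$blocks$orientation, "same")
  expect_equal(res$blocks$n_anchors, 5L)
  expect_equal(sort(res$anchors$gene_a), paste0("a", 1:5))
})

test_that("inverted chains are found and labelled", {
  res <- detect_blocks(colinear_anchors(6, idx_b = 6:1))
  expect_equal(nrow(res$blocks), 1L)
  expect_equal(res$blocks$orientation, "inverted")
})

test_that("gaps beyond max_gap break chains", {
  a <- colinear_anchors(10)
  a$idx_a <- c(1:5, 30:34)  # 24 skipped genes between anchor 5 and 6
  res <- detect_blocks(a, min_anchors = 5, max_gap = 10)
  expect_equal(nrow(res$blocks), 2L)
})

test_that("chain DP equals exhaustive monotone-chain search", {
  set.seed(42)
  for (i in 1:40) {
    n <- sample(4:10, 1)
    a <- random_anchor_set(n)
    expect_equal(dp_best_chain(a, max_gap = 10, gap_penalty = 0.1),
                 oracle_best_chain(a, max_gap = 10, gap_penalty = 0.1),
                 tolerance = 1e-12)
  }
  # also under a tight gap cap and a heavier penalty
  for (i in 1:20) {
    a <- random_anchor_set(sample(4:9, 1), span = 15L)
    expect_equal(dp_best_chain(a, max_gap = 3, gap_penalty = 0.4),
                 oracle_best_chain(a, max_gap = 3, gap_penalty = 0.4),
                 tolerance = 1e-12)
  }
})

test_that("block anchors are strictly monotone on both sides", {
  set.seed(7)
  for (i in 1:20) {
    a <- random_anchor_set(30, span = 40L)
    res <- detect_blocks(a, min_anchors = 3)
    for (b in unique(res$anchors$block_id)) {
      an <- res$anchors[res$anchors$block_id == b, ]
      an <- an[order(an$idx_a), ]
      expect_true(all(diff(an$idx_a) > 0))
      db <- diff(an$idx_b)
      expect_true(all(db > 0) || all(db < 0))
    }
    # each anchor in at most one block
    expect_false(anyDuplicated(res$anchors[, c("gene_a", "gene_b")]) > 0)
  }
})

test_that("tandem arrays collapse to a single representative anchor", {
  # three adjacent copies on c1 plus their distant partner region on c2:
  # five anchors are needed, so give the distant region five genes and make
  # one of them a tandem triplet
  cds <- replicate(6, random_cds(40))
  ids1 <- paste0("t", 1:3)
  far <- paste0("f", 1:5)
  g <- rbind(
    make_genes(c(ids1, paste0("x", 1:5)),
               c(cds[1], cds[1], cds[1], cds[2:6]), chromosome = "chr1"),
    make_genes(far, cds[c(1, 2, 3, 4, 5)], chromosome = "chr2"))
  hits <- score_pairs(g)
  res <- self_synteny(g, hits, min_anchors = 5, tandem_window = 5)
  # the t1/t2/t3 array contributes one anchor (representative t1)
  an <- res$anchors
  expect_true("t1" %in% c(an$gene_a, an$gene_b))
  expect_false(any(c("t2", "t3") %in% c(an$gene_a, an$gene_b)))
})

test_that("syntenic depth counts covering blocks per reference gene", {
  ref <- make_genes(paste0("r", 1:20), strrep("GGA", 20), species = "R")
  blocks <- detect_blocks(data.frame(
    gene_a = paste0("r", 1:10), gene_b = paste0("q", 1:10),
    species_a = "R", species_b = "Q",
    chr_a = "chr1", idx_a = 0:9, chr_b = "c9", idx_b = 0:9,
    score = 1, stringsAsFactors = FALSE))
  d <- syntenic_depth(blocks, "R", ref)
  expect_equal(unname(d$fractions), c(0.5, 0.5, 0, 0))
  expect_equal(sum(d$fractions), 1, tolerance = 1e-12)
  # no blocks at all
  d0 <- syntenic_depth(detect_blocks(NULL), "R", ref)
  expect_equal(unname(d0$fractions[["0"]]), 1)
  # mixed species pairs are rejected
  b2 <- blocks
  b2$blocks <- rbind(b2$blocks, transform(b2$blocks, species_b = "Z"))
  expect_error(syntenic_depth(b2, "R", ref), "mix")
})

test_that("full-retention WGD yields full-length self-synteny and ~2x depth", {
  cfg <- tiny_config(n_ancestral_genes = 80, codon_length = 50,
                     speciation_depths = c(Sita = 0.3),
                     retention_prob = c(gene = 1), seed = 14)
  sim <- simulate_dataset(cfg)
  g <- sim$genes$Paus
  res <- self_synteny(g, score_pairs(g))
  # every chromosome pairs with its WGD partner over its full length
  expect_setequal(paste(res$blocks$chr_a, res$blocks$chr_b),
                  c("chr1 chr1B", "chr2 chr2B"))
  expect_equal(nrow(res$anchors), 80L)
  # a single-copy comparator sees (almost) every gene twice
  h <- score_pairs(g, sim$genes$Sita)
  bl <- detect_blocks(anchors_from_hits(h, sim$genes$Sita, g))
  d <- syntenic_depth(bl, "Sita", sim$genes$Sita)
  expect_gte(d$fractions[["2"]], 0.9)
})

test_that("self-synteny anchor fraction tracks the truth-block density", {
  cfg <- tiny_config(n_ancestral_genes = 200, codon_length = 50,
                     speciation_depths = c(Sita = 0.3),
                     retention_prob = c(gene = 0.35), seed = 22)
  sim <- simulate_dataset(cfg)
  g <- sim$genes$Paus
  res <- self_synteny(g, score_pairs(g))
  detected <- nrow(res$anchors)
  # oracle: anchors inside truth runs long enough to pass the block filter
  tb <- sim$truth$true_blocks
  tb <- tb[tb$species_a == "Paus" & tb$species_b == "Paus", ]
  runs <- table(tb$run_id)
  expected <- sum(runs[runs >= 5])
  expect_lt(abs(detected - expected), 3 * sqrt(expected) + 5)
})
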