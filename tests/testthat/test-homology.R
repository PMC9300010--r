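test_that("identical proteins score identity 1 with full coverage", {
  cds <- strrep("GGAATGCTT", 10L)
  g <- make_genes(c("a", "b"), c(cds, cds))
  h <- score_pairs(g)
  expect_equal(nrow(h), 2L)  # both directions
  expect_equal(h$identity, c(1, 1))
  expect_equal(h$qcov, c(1, 1))
  expect_equal(h$scov, c(1, 1))
})

test_that("unrelated random sequences fall below the identity threshold", {
  set.seed(17)
  for (i in 1:5) {
    g <- make_genes(c("x", "y"), c(random_cds(100), random_cds(100)))
    h <- score_pairs(g, min_identity = 0.5)
    expect_equal(nrow(h), 0L)
  }
})

test_that("synonymous substitutions are invisible at the protein level", {
  set.seed(4)
  cds <- random_cds(80)
  # substitute ~10% of third positions within four-fold families
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  fams <- c("CT", "GT", "TC", "CC", "AC", "GC", "CG", "GG")
  idx <- which(substr(codons, 1, 2) %in% fams)
  idx <- sample(idx, ceiling(length(idx) * 0.3))
  for (i in idx) {
    alt <- setdiff(c("A", "C", "G", "T"), substr(codons[i], 3, 3))
    substr(codons[i], 3, 3) <- sample(alt, 1)
  }
  mut <- paste(codons, collapse = "")
  expect_false(identical(mut, cds))
  h <- score_pairs(make_genes(c("wt", "mut"), c(cds, mut)))
  expect_equal(unique(h$identity), 1)
})

test_that("genes with internal stop codons are skipped with a warning", {
  good <- strrep("GGAATGCTT", 10L)
  bad <- paste0(substr(good, 1, 30), "TAA", substr(good, 34, 90))
  g <- make_genes(c("ok1", "ok2", "bad"), c(good, good, bad))
  expect_warning(h <- score_pairs(g), "internal stop")
  expect_false("bad" %in% c(h$query, h$subject))
  expect_equal(sort(unique(c(h$query, h$subject))), c("ok1", "ok2"))
})

test_that("length-mismatched pairs are aligned with affine gaps", {
  core <- strrep("GGAATGCTTCAT", 10L)           # 40 codons
  longer <- paste0(core, strrep("GCT", 10L))    # 50 codons
  gA <- make_genes("short", core, species = "A")
  gB <- make_genes("long", longer, species = "B")
  h <- score_pairs(gA, gB, min_identity = 0.5, min_coverage = 0.5)
  expect_gte(nrow(h), 1L)
  row <- h[h$query == "short", ]
  expect_equal(row$identity, 1)
  expect_equal(row$qcov, 1)
  expect_equal(row$scov, 0.8)
})

test_that("reciprocal best hits require mutual top ranking", {
  hit <- function(q, s, sc) data.frame(query = q, subject = s,
                                       species_q = "A", species_s = "B",
                                       identity = 1, qcov = 1, scov = 1,
                                       score = sc)
  # single pair
  h <- rbind(hit("a", "b", 10), hit("b", "a", 10))
  expect_equal(reciprocal_best_hits(h)[, c("gene_a", "gene_b")],
               data.frame(gene_a = "a", gene_b = "b"))
  # a's best is b, but b's best is c: no pair for a
  h <- rbind(hit("a", "b", 10), hit("b", "a", 10), hit("b", "c", 20),
             hit("c", "b", 20))
  r <- reciprocal_best_hits(h)
  expect_false("a" %in% c(r$gene_a, r$gene_b))
  expect_equal(nrow(r), 1L)
  # empty in, empty out
  expect_equal(nrow(reciprocal_best_hits(h[0, ])), 0L)
})

test_that("RBH ties break lexicographically and are counted", {
  hit <- function(q, s, sc) data.frame(query = q, subject = s,
                                       species_q = "A", species_s = "B",
                                       identity = 1, qcov = 1, scov = 1,
                                       score = sc)
  h <- rbind(hit("z", "b1", 10), hit("z", "b2", 10),
             hit("b1", "z", 10), hit("b2", "z", 10))
  r <- reciprocal_best_hits(h)
  expect_equal(r$gene_a, "b1")
  expect_gte(attr(r, "n_ties"), 1L)
})

test_that("RBH recovers the true orthology on a clean two-species dataset", {
  cfg <- tiny_config(n_ancestral_genes = 80, codon_length = 50,
                     speciation_depths = c(Sita = 0.3),
                     retention_prob = c(gene = 0), seed = 12)
  sim <- simulate_dataset(cfg)
  h <- score_pairs(sim$genes$Paus, sim$genes$Sita)
  r <- reciprocal_best_hits(h)
  expect_equal(nrow(r), 80L)
  anc_a <- sub("a$", "", sub("Paus_", "", r$gene_a))
  anc_b <- sub("Sita_", "", r$gene_b)
  expect_equal(anc_a, anc_b)
})

test_that("RBH output is invariant under input row permutation", {
  sim <- simulate_dataset(tiny_config(n_ancestral_genes = 40, seed = 6))
  h <- score_pairs(sim$genes$Paus, sim$genes$Sita)
  r1 <- reciprocal_best_hits(h)
  set.seed(1)
  r2 <- reciprocal_best_hits(h[sample.int(nrow(h)), ])
  expect_equal(r1, r2, ignore_attr = TRUE)
})

test_that("orthogroups partition the genes and match the simulated truth", {
  cfg <- tiny_config(n_ancestral_genes = 60, codon_length = 50,
                     speciation_depths = c(Pame = 0.02, Sita = 0.30),
                     retention_prob = c(gene = 0.5), seed = 9)
  sim <- simulate_dataset(cfg)
  res <- classify_simulated(sim)
  groups <- res$groups
  # partition: no gene in two groups
  expect_false(anyDuplicated(groups$gene_id) > 0)
  # equals the truth partition: genes grouped iff same ancestral gene
  truth <- sim$truth$orthogroups
  truth_of <- setNames(truth$ancestral_id, truth$gene_id)
  anc_per_group <- tapply(truth_of[groups$gene_id], groups$og_id,
                          function(x) length(unique(x)))
  expect_true(all(anc_per_group == 1L))
  expect_equal(length(unique(groups$og_id)), cfg$n_ancestral_genes)
  # both WGD copies join the group anchored by their orthologues
  n_focal <- tapply(groups$species == "Paus", groups$og_id, sum)
  retained <- sim$truth$retained_duplicates
  anc_of_group <- tapply(truth_of[groups$gene_id], groups$og_id,
                         function(x) x[1])
  expect_equal(as.vector(n_focal[anc_of_group %in% retained]),
               rep(2L, length(retained)))
})
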