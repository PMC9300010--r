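test_that("configuration invariants are enforced with the field named", {
  expect_error(tiny_config(n_ancestral_genes = 0), "n_ancestral_genes")
  expect_error(tiny_config(retention_prob = c(gene = 1.2)), "retention_prob")
  expect_error(tiny_config(category_fractions = c(gene = 0.7)),
               "category_fractions")
  expect_error(tiny_config(speciation_depths = c(Sita = 0.3),
                           wgd_ks = 0.3), "wgd_ks")
  expect_error(tiny_config(speciation_depths = c(0.3, 0.4)),
               "speciation_depths")
  expect_error(tiny_config(background_loss = 2), "background_loss")
})

test_that("identical configurations give identical datasets", {
  s1 <- simulate_dataset(tiny_config(seed = 99))
  s2 <- simulate_dataset(tiny_config(seed = 99))
  expect_identical(s1, s2)
  s3 <- simulate_dataset(tiny_config(seed = 100))
  expect_false(identical(s1$genes, s3$genes))
})

test_that("full retention doubles every gene; zero retention leaves none", {
  full <- simulate_dataset(tiny_config(retention_prob = c(gene = 1)))
  focal <- full$genes$Paus
  expect_equal(nrow(focal), 2L * full$config$n_ancestral_genes)
  expect_length(full$truth$retained_duplicates, full$config$n_ancestral_genes)

  none <- simulate_dataset(tiny_config(retention_prob = c(gene = 0)))
  expect_equal(nrow(none$genes$Paus), none$config$n_ancestral_genes)
  expect_length(none$truth$retained_duplicates, 0L)
})

test_that("realized duplicate retention tracks the per-category probability", {
  cfg <- simulation_config(
    n_ancestral_genes = 600, codon_length = 10, rearrangement_rate = 0,
    speciation_depths = c(Sita = 0.3),
    retention_prob = c(regulatory = 0.8, other = 0.3),
    category_fractions = c(regulatory = 0.3, other = 0.7), seed = 5)
  sim <- simulate_dataset(cfg)
  focal_a <- sim$genes$Paus[grepl("a$", sim$genes$Paus$gene_id), ]
  anc <- sub("a$", "", sub("Paus_", "", focal_a$gene_id))
  retained <- anc %in% sim$truth$retained_duplicates
  for (cat in c("regulatory", "other")) {
    sel <- focal_a$category == cat
    p <- cfg$retention_prob[[cat]]
    se <- sqrt(p * (1 - p) / sum(sel))
    expect_lt(abs(mean(retained[sel]) - p), 3 * se + 1e-12)
  }
})

test_that("pairwise 4D divergence recovers the configured Ks depth", {
  # oracle: count mismatches at 4D sites directly from the emitted CDS,
  # Jukes-Cantor correct, compare with the configured depth
  cfg <- simulation_config(n_ancestral_genes = 400, codon_length = 60,
                           speciation_depths = c(Pame = 0.02, Sita = 0.30),
                           retention_prob = c(gene = 0.35),
                           category_fractions = c(gene = 1),
                           rearrangement_rate = 0, seed = 21)
  sim <- simulate_dataset(cfg)
  fa <- sim$genes$Paus[grepl("a$", sim$genes$Paus$gene_id), ]
  anc <- sub("a$", "", sub("Paus_", "", fa$gene_id))
  sita <- sim$genes$Sita
  partner <- sita$cds[match(paste0("Sita_", anc), sita$gene_id)]
  counts <- mapply(function(a, b) oracle_4d_mismatch(a, b), fa$cds, partner)
  n4d <- sum(counts["n_4d", ])
  p <- sum(counts["n_diff", ]) / n4d
  k_hat <- jc_correct(p)
  se_k <- sqrt(p * (1 - p) / n4d) / (1 - 4 * p / 3)
  expect_lt(abs(k_hat - 0.30), 3 * se_k)
})

test_that("paralogue pairs diverge by wgd_ks and orthologues by their depth sum", {
  cfg <- simulation_config(n_ancestral_genes = 300, codon_length = 60,
                           speciation_depths = c(Pame = 0.02, Sita = 0.30),
                           wgd_ks = 0.15,
                           retention_prob = c(gene = 1),
                           category_fractions = c(gene = 1),
                           rearrangement_rate = 0, seed = 8)
  sim <- simulate_dataset(cfg)
  g <- sim$genes$Paus
  a <- g[grepl("a$", g$gene_id), ]
  b <- g[grepl("b$", g$gene_id), ]
  b <- b[match(sub("a$", "b", a$gene_id), b$gene_id), ]
  counts <- mapply(function(x, y) oracle_4d_mismatch(x, y), a$cds, b$cds)
  p <- sum(counts["n_diff", ]) / sum(counts["n_4d", ])
  se_k <- sqrt(p * (1 - p) / sum(counts["n_4d", ])) / (1 - 4 * p / 3)
  expect_lt(abs(jc_correct(p) - 0.15), 3 * se_k)
})

test_that("read-count simulation follows binomial sampling around the dosage", {
  rc <- simulate_read_counts(5000, 0.5, het_rate = 1, mean_depth = 40,
                             error_rate = 0, seed = 3)
  frac <- rc$nonref_count / rc$depth
  se <- sqrt(0.25 / (40 * 5000))  # binomial SE of the pooled mean
  expect_lt(abs(mean(frac) - 0.5), 3 * se * 2)
  # no heterozygosity: only error-driven nonreference reads
  rc0 <- simulate_read_counts(2000, 0.5, het_rate = 0, mean_depth = 40,
                              error_rate = 0.01, seed = 4)
  expect_lte(max(rc0$nonref_count / pmax(rc0$depth, 1)), 0.25)
  expect_lt(mean(rc0$nonref_count) / 40, 0.02)
  # determinism and input validation
  expect_identical(simulate_read_counts(100, 0.5, 1, 40, 0.002, seed = 9),
                   simulate_read_counts(100, 0.5, 1, 40, 0.002, seed = 9))
  expect_error(simulate_read_counts(100, numeric(0), 1, 40), "ploidy_profile")
  expect_error(simulate_read_counts(100, 0.5, 1, 0), "mean_depth")
})

test_that("fixtures round-trip losslessly and use half-open BED coordinates", {
  sim <- simulate_dataset(tiny_config(n_ancestral_genes = 10,
                                      codon_length = 12, seed = 31))
  d <- withr::local_tempdir()
  write_fixture(sim, d)
  expect_setequal(
    list.files(d),
    c(paste0(rep(names(sim$genes), each = 2), c("_cds.fasta", "_genes.bed")),
      "gene_categories.tsv", "truth_orthogroups.tsv", "truth_retained.tsv",
      "truth_blocks.tsv"))
  bed <- read.delim(file.path(d, "Paus_genes.bed"), header = FALSE)
  expect_true(all(bed$V3 - bed$V2 == 3L * sim$config$codon_length))

  fx <- read_fixture(d)
  cols <- c("gene_id", "species", "chromosome", "order_index", "start",
            "end", "strand", "category", "cds")
  for (sp in names(sim$genes)) {
    g1 <- sim$genes[[sp]][, cols]
    g2 <- fx$genes[[sp]][, cols]
    g1 <- g1[order(g1$gene_id), ]; rownames(g1) <- NULL
    g2 <- g2[order(g2$gene_id), ]; rownames(g2) <- NULL
    expect_equal(g1, g2)
  }
  expect_equal(fx$truth$retained_duplicates, sim$truth$retained_duplicates)
})

test_that("copy-number matrix generator matches its stated structure", {
  m <- simulate_copy_number_matrix(2000, retention = 0.4, noise_rate = 0,
                                   seed = 2)
  expect_true(all(m[, 1:5] == 1L))
  frac2 <- mean(m[, "Paus"] == 2L)
  expect_lt(abs(frac2 - 0.4), 3 * sqrt(0.4 * 0.6 / 2000))
  expect_true(all(m[, "Paus"] %in% c(1L, 2L)))
})
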