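toy_groups <- function() {
  data.frame(
    og_id = c("OG1", "OG1", "OG1", "OG2", "OG2", "OG3"),
    species = c("Paus", "Paus", "sp1", "Paus", "sp1", "sp1"),
    gene_id = c("pa1", "pa2", "s1", "pa3", "s2", "s3"),
    stringsAsFactors = FALSE)
}

test_that("copy-number table counts members per species", {
  m <- copy_number_table(toy_groups(), c("Paus", "sp1", "sp2"))
  expect_equal(dim(m), c(3L, 3L))
  expect_equal(unname(m["OG1", ]), c(2L, 1L, 0L))
  expect_equal(unname(m["OG3", ]), c(0L, 1L, 0L))
  empty <- copy_number_table(toy_groups()[0, ], c("a", "b"))
  expect_equal(nrow(empty), 0L)
})

test_that("R_CN is the focal count over the comparator mean", {
  expect_equal(rcn(c(Paus = 2, a = 1, b = 1, c = 1, d = 1, e = 1), "Paus"), 2)
  expect_equal(rcn(c(Paus = 1, a = 1, b = 1, c = 1, d = 1, e = 1), "Paus"), 1)
  expect_equal(rcn(c(Paus = 3, a = 1, b = 2, c = 1, d = 2, e = 0), "Paus"),
               3 / 1.2)  # 2.5, by hand
  expect_message(v <- rcn(c(Paus = 3, a = 0, b = 0), "Paus"), "undefined")
  expect_true(is.na(v))
})

test_that("groups classify into conserved, duplicated, and other", {
  m <- rbind(OGa = c(2L, 1L, 1L, 1L, 1L, 1L),   # R_CN 2: duplicated
             OGb = c(1L, 1L, 1L, 1L, 1L, 1L),   # R_CN 1: conserved
             OGc = c(5L, 1L, 1L, 1L, 1L, 1L),   # R_CN 5: other
             OGd = c(1L, 1L, 2L, 1L, 2L, 1L),   # focal 1 vs mean 1.4: other
             OGe = c(0L, 0L, 0L, 0L, 0L, 0L))   # undefined: excluded
  colnames(m) <- c("Paus", paste0("sp", 1:5))
  cl <- classify_groups(m, "Paus")
  expect_equal(cl$label[match(c("OGa", "OGb", "OGc", "OGd"), cl$og_id)],
               c("duplicated", "conserved", "other", "other"))
  expect_equal(attr(cl, "n_excluded"), 1L)
  expect_false("OGe" %in% cl$og_id)
  # strict comparator equality mode
  cl2 <- classify_groups(m, "Paus", strict_equal = TRUE)
  expect_equal(cl2$label[cl2$og_id == "OGb"], "conserved")
})

test_that("classification is invariant to row and column order", {
  m <- simulate_copy_number_matrix(200, retention = 0.4, seed = 8)
  cl1 <- classify_groups(m, "Paus")
  m2 <- m[sample.int(nrow(m)), rev(colnames(m))]
  cl2 <- classify_groups(m2, "Paus")
  cl2 <- cl2[match(cl1$og_id, cl2$og_id), ]
  expect_equal(cl1$label, cl2$label)
  expect_equal(cl1$rcn, cl2$rcn)
})

test_that("single-copy duplication fraction matches its definition", {
  m <- rbind(c(2L, 1L, 1L), c(1L, 1L, 1L), c(2L, 1L, 2L))
  colnames(m) <- c("Paus", "sp1", "sp2")
  rownames(m) <- paste0("OG", 1:3)
  f <- single_copy_duplication_fraction(m, "Paus")
  expect_equal(as.numeric(f), 0.5)  # OG3 is not universal single-copy
  expect_equal(attr(f, "n_universal"), 2L)
  m0 <- m; m0[, "sp1"] <- 2L
  expect_error(single_copy_duplication_fraction(m0, "Paus"), "single-copy")
})

test_that("R_CN histogram is bimodal at 1 and 2 under WGD retention", {
  m <- simulate_copy_number_matrix(3000, retention = 0.35, noise_rate = 0.02,
                                   seed = 4)
  h <- rcn_histogram(rcn_table(m, "Paus")$rcn)
  expect_equal(h$modes, c(1, 2))
  # comparator species keep a single mode at 1
  for (sp in paste0("sp", 1:3)) {
    expect_equal(rcn_histogram(rcn_table(m, sp)$rcn)$modes, 1)
  }
  # upper-mode mass tracks the retention rate
  mass2 <- vapply(c(0.2, 0.35, 0.5), function(r) {
    mm <- simulate_copy_number_matrix(2000, retention = r, noise_rate = 0.02,
                                      seed = 6)
    hh <- rcn_histogram(rcn_table(mm, "Paus")$rcn)
    hh$histogram$count[hh$histogram$bin_center == 2] / 2000
  }, numeric(1))
  expect_true(all(diff(mass2) > 0))
})

test_that("copy-number recovery through the homology path matches truth", {
  cfg <- tiny_config(n_ancestral_genes = 120, codon_length = 50,
                     speciation_depths = c(Pame = 0.02, Sita = 0.30,
                                           Osat = 0.45),
                     retention_prob = c(gene = 0.35), seed = 18)
  sim <- simulate_dataset(cfg)
  res <- classify_simulated(sim)
  truth_dup <- length(sim$truth$retained_duplicates)
  # the copy-number matrix equals truth-derived counts exactly
  truth <- sim$truth$orthogroups
  expect_equal(sum(res$matrix[, "Paus"] == 2L), truth_dup)
  expect_equal(nrow(res$matrix), cfg$n_ancestral_genes)
  # duplicated fraction and single-copy duplication fraction track retention
  r <- 0.35
  se <- sqrt(r * (1 - r) / nrow(res$matrix))
  expect_lt(abs(mean(res$classification$label == "duplicated") -
                  truth_dup / cfg$n_ancestral_genes), 1e-9)
  expect_lt(abs(single_copy_duplication_fraction(res$matrix, "Paus") - r),
            3 * se)
})
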