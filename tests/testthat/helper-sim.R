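# Small simulation configurations and hand-built gene tables shared by the
# tests.

tiny_config <- function(..., seed = 1L) {
  defaults <- list(n_ancestral_genes = 60L, n_chromosomes = 2L,
                   codon_length = 40L,
                   speciation_depths = c(Pame = 0.02, Sita = 0.30),
                   retention_prob = c(gene = 0.5),
                   category_fractions = c(gene = 1),
                   rearrangement_rate = 0, seed = seed)
  args <- utils::modifyList(defaults, list(...))
  do.call(simulation_config, args)
}

# A gene-model table built from explicit CDS strings, positioned along one
# chromosome in the order given.
make_genes <- function(ids, cds, species = "sp", chromosome = "chr1") {
  oi <- seq_along(ids) - 1L
  data.frame(gene_id = ids, species = species, chromosome = chromosome,
             order_index = oi, start = oi * 2000L,
             end = oi * 2000L + nchar(cds), strand = "+",
             category = "gene", cds = cds, stringsAsFactors = FALSE)
}

# A random CDS of `n` codons drawn from sense codons (no stops).
random_cds <- function(n) {
  gc <- Biostrings::GENETIC_CODE
  paste(sample(names(gc)[gc != "*"], n, replace = TRUE), collapse = "")
}

# One full WGD-placement replicate: simulate, run homology/synteny/Ks on
# the focal species against all comparators, and return the placement.
placement_replicate <- function(seed, n_genes = 300L) {
  cfg <- simulation_config(
    n_ancestral_genes = n_genes, codon_length = 100,
    speciation_depths = c(Pame = 0.02, Sita = 0.30, Acom = 0.60),
    wgd_ks = 0.15,
    retention_prob = c(gene = 0.35), category_fractions = c(gene = 1),
    rearrangement_rate = 1, seed = seed)
  sim <- simulate_dataset(cfg)
  g <- sim$genes
  cds <- unlist(lapply(g, function(x) setNames(x$cds, x$gene_id)))
  names(cds) <- sub("^[^.]*\\.", "", names(cds))
  self_hits <- score_pairs(g$Paus)
  sb <- self_synteny(g$Paus, self_hits)
  kpar <- suppressMessages(ks_pairs(sb$anchors[, c("gene_a", "gene_b")], cds))
  dpar <- ks_distribution_peak(kpar$ks, "paralogue")
  ortho <- list()
  for (sp in c("Sita", "Acom")) {
    h <- score_pairs(g$Paus, g[[sp]])
    bl <- detect_blocks(anchors_from_hits(h, g[[sp]], g$Paus))
    kt <- suppressMessages(ks_pairs(bl$anchors[, c("gene_a", "gene_b")], cds))
    ortho[[sp]] <- ks_distribution_peak(kt$ks, sp)
  }
  wr <- reciprocal_best_hits(score_pairs(g$Paus, g$Pame))
  kw <- suppressMessages(ks_pairs(wr[, c("gene_a", "gene_b")], cds))
  dwithin <- ks_distribution_peak(kw$ks, "within")
  place_wgd(dpar, ortho, dwithin)
}

# Run the homology -> orthogroups -> copy-number path for one simulated
# dataset; returns the classification plus the copy-number matrix.
classify_simulated <- function(sim) {
  g <- sim$genes
  focal <- sim$config$focal_species
  others <- setdiff(names(g), focal)
  hits <- rbind(score_pairs(g[[focal]]),
                do.call(rbind, lapply(others, function(sp)
                  score_pairs(g[[focal]], g[[sp]]))))
  groups <- cluster_orthogroups(hits)
  cn <- copy_number_table(groups, c(focal, others))
  list(groups = groups, matrix = cn,
       classification = classify_groups(cn, focal))
}
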