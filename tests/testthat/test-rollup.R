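## genome summaries built directly from generator truth (the rollup is
## independent of the aligner here)
truthGenes <- function(sim) {
  data.frame(genome_id = sim$truth$genome_id,
             taxon_id = sim$records$taxon_id[
               match(sim$truth$record_id, sim$records$record_id)],
             class = sim$truth$class,
             templates_cca = sim$truth$templates_cca)
}

test_that("degenerate templating probabilities give frequencies 0 and 1", {
  cfg <- syntheticConfig(pCCA = c(Ini = 1), pCCAElongDefault = 0)
  sim <- simulateGenomes(cfg, seed = 31)
  gs <- summarizeGenomes(truthGenes(sim), sim$genomeSizes)
  ini <- gs[gs$class == "Ini", ]
  elo <- gs[gs$class != "Ini", ]
  expect_true(all(ini$n_templating == ini$n_genes))
  expect_true(all(elo$n_templating == 0))
  expect_false(any(gs$missing_initiator))
})

test_that("a genome with no initiator gene is flagged", {
  cfg <- syntheticConfig(geneCounts = c(Met = 5L, kIle = 3L))
  sim <- simulateGenomes(cfg, seed = 32)
  gs <- summarizeGenomes(truthGenes(sim), sim$genomeSizes)
  expect_true(all(gs$missing_initiator))
})

test_that("per-genome frequencies stay within the binomial 3-sigma bound", {
  cfg <- syntheticConfig(genomes = data.frame(genome_id = "G1",
                                              taxon_id = 1000L,
                                              genome_size = 3e6),
                         lineage = NULL,
                         geneCounts = c(Ini = 60L))
  sim <- simulateGenomes(cfg, seed = 33)
  gs <- summarizeGenomes(truthGenes(sim), sim$genomeSizes)
  p <- 0.741
  expect_lt(abs(gs$n_templating / gs$n_genes - p), 3 * sqrt(p * (1 - p) / 60))
})

test_that("clade rollup pools gene-weighted frequencies by ancestor rank", {
  sim <- simulateGenomes(syntheticConfig(), seed = 34)
  genes <- truthGenes(sim)
  gs <- summarizeGenomes(genes, sim$genomeSizes)
  ru <- rollupClades(gs, sim$lineage, "genus")
  ## bookkeeping oracle per clade x class
  anc <- ancestorAtRank(sim$lineage, genes$taxon_id, "genus")
  genes$clade <- sim$lineage$name[match(anc, sim$lineage$taxon_id)]
  for (k in seq_len(nrow(ru))) {
    sub <- genes[genes$clade == ru$clade[k] & genes$class == ru$class[k], ]
    expect_equal(ru$n_genes[k], nrow(sub))
    expect_equal(ru$freq[k], mean(sub$templates_cca))
  }
  ## pooled counts are additive up the tree
  ruP <- rollupClades(gs, sim$lineage, "phylum")
  for (cl in unique(ru$class)) {
    expect_equal(sum(ru$n_templating[ru$class == cl]),
                 sum(ruP$n_templating[ruP$class == cl]))
  }
  ## order invariance
  set.seed(2)
  ru2 <- rollupClades(gs[sample(nrow(gs)), ], sim$lineage, "genus")
  expect_equal(ru[order(ru$clade, ru$class), ],
               ru2[order(ru2$clade, ru2$class), ], ignore_attr = TRUE)
})

test_that("two genomes in one genus pool to the average; singletons are identity", {
  lineage <- data.frame(taxon_id = c(1L, 100L, 1001L, 1002L),
                        rank = c("no rank", "genus", "species", "species"),
                        name = c("root", "GenusX", "sp1", "sp2"),
                        parent_taxon_id = c(1L, 1L, 100L, 100L))
  genes <- data.frame(genome_id = c("A", "B"),
                      taxon_id = c(1001L, 1002L),
                      class = "Ini",
                      templates_cca = c(TRUE, FALSE))
  sizes <- data.frame(genome_id = c("A", "B"), size_bp = c(2e6, 4e6))
  gs <- summarizeGenomes(genes, sizes)
  ru <- rollupClades(gs, lineage, "genus")
  expect_equal(nrow(ru), 1L)
  expect_equal(ru$freq, 0.5)
  expect_equal(ru$mean_genome_size, 3e6)

  ruOne <- rollupClades(gs[gs$genome_id == "A", ], lineage, "genus")
  expect_equal(ruOne$freq, 1)
  expect_equal(ruOne$n_genomes, 1L)
  expect_equal(ruOne$mean_genome_size, 2e6)
})

test_that("unresolvable taxa are excluded with a warning", {
  lineage <- data.frame(taxon_id = c(1L, 100L, 1001L),
                        rank = c("no rank", "genus", "species"),
                        name = c("root", "GenusX", "sp1"),
                        parent_taxon_id = c(1L, 1L, 100L))
  genes <- data.frame(genome_id = c("A", "B"),
                      taxon_id = c(1001L, 9999L),
                      class = "Ini", templates_cca = TRUE)
  sizes <- data.frame(genome_id = c("A", "B"), size_bp = c(2e6, 4e6))
  gs <- summarizeGenomes(genes, sizes)
  expect_warning(ru <- rollupClades(gs, lineage, "genus"), "unresolvable")
  expect_equal(ru$n_genomes, 1L)
})

test_that("pattern calls follow the four phyletic rules with precedence", {
  expect_equal(callPattern(0.95, 0.93), "all_template")
  expect_equal(callPattern(0.05, 0.03), "none_template")
  expect_equal(callPattern(0.92, 0.03), "initiator_predominant")
  expect_equal(callPattern(0.917, 0.034), "initiator_predominant")
  expect_equal(callPattern(0.0, 0.60), "elongator_predominant")
  ## all_template takes precedence over initiator_predominant on overlap
  expect_equal(callPattern(1.0, 0.5), "all_template")
  ## nearest rule on a non-matching intermediate point
  expect_equal(callPattern(0.49, 0.02), "initiator_predominant")
})

test_that("clade pattern table flags clades lacking initiator genes", {
  rollup <- data.frame(
    clade = rep(c("C1", "C2"), each = 2),
    class = rep(c("Ini", "Tyr"), 2),
    n_genes = c(10, 100, 0, 100),
    n_templating = c(9, 3, 0, 60))
  pat <- cladePatterns(rollup)
  expect_equal(pat$pattern[pat$clade == "C1"], "initiator_predominant")
  expect_equal(pat$pattern[pat$clade == "C2"], "elongator_predominant")
  expect_false(pat$no_initiator_flag[pat$clade == "C1"])
  expect_true(pat$no_initiator_flag[pat$clade == "C2"])
})
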