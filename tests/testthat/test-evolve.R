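quiet_params <- function(seed, ...) {
  evolver_params(n_genes = 20, mean_protein_len = 100, sub_proportion = 0,
                 loss_prob = 0, gain_count = 0, n_inversions = 0,
                 n_translocations = 0, seed = seed, ...)
}

test_that("the same seed reproduces the simulation exactly", {
  p <- evolver_params(n_genes = 25, sub_proportion = 0.08, loss_prob = 0.05,
                      gain_count = 3, n_inversions = 2, n_translocations = 1,
                      island_spec = list(length = 5, gc_shift_sd = 2),
                      seed = 99)
  s1 <- evolve_pair(p)
  s2 <- evolve_pair(p)
  expect_identical(s1$genome_a$proteins, s2$genome_a$proteins)
  expect_identical(s1$genome_b$genes, s2$genome_b$genes)
  expect_identical(s1$genome_a$contig_seqs, s2$genome_a$contig_seqs)
  expect_identical(s1$truth$ortholog_pairs, s2$truth$ortholog_pairs)
})

test_that("zero divergence leaves the two lineages identical", {
  sim <- evolve_pair(quiet_params(3))
  expect_equal(unname(sim$genome_a$proteins), unname(sim$genome_b$proteins))
  expect_equal(nrow(sim$truth$ortholog_pairs), 20L)
  expect_true(all(sim$truth$ortholog_pairs$identity == 1))
  expect_equal(sim$truth$n_true_segments, 1L)
})

test_that("realized pairwise identity converges to the analytic expectation", {
  s <- 0.09
  sim <- evolve_pair(evolver_params(n_genes = 200, mean_protein_len = 500,
                                    sub_proportion = s, loss_prob = 0,
                                    gain_count = 0, n_inversions = 0,
                                    n_translocations = 0, seed = 11))
  lens <- nchar(sim$genome_a$proteins[sim$truth$ortholog_pairs$gene_a])
  expect_gte(sum(lens), 1e5)
  realized <- 100 * sum(sim$truth$ortholog_pairs$identity * lens) / sum(lens)
  expect_lt(abs(realized - 100 * (1 - s)^2), 0.5)
})

test_that("per-gene events are logged consistently with the gene tables", {
  p <- evolver_params(n_genes = 40, mean_protein_len = 80,
                      sub_proportion = 0.05, loss_prob = 0.1, gain_count = 4,
                      n_inversions = 2, n_translocations = 1, seed = 13)
  sim <- evolve_pair(p)
  ga <- sim$genome_a$genes$gene_id
  gb <- sim$genome_b$genes$gene_id
  # lost ancestral genes are absent; gained genes present exactly once
  expect_false(any(paste0("a_", sim$truth$lost_a) %in% ga))
  expect_false(any(paste0("b_", sim$truth$lost_b) %in% gb))
  expect_true(all(sim$truth$gained_a %in% ga))
  expect_true(all(sim$truth$ortholog_pairs$gene_a %in% ga))
  expect_true(all(sim$truth$ortholog_pairs$gene_b %in% gb))
  # gene counts balance: ancestor - losses + gains
  expect_equal(length(ga), 40L - length(sim$truth$lost_a) + 4L)
})

test_that("true segment count equals block detection under noise-free settings", {
  for (seed in c(5, 6, 7)) {
    sim <- evolve_pair(evolver_params(n_genes = 40, mean_protein_len = 60,
                                      sub_proportion = 0.02, loss_prob = 0,
                                      gain_count = 0, n_inversions = 3,
                                      n_translocations = 0, seed = seed))
    bl <- find_synteny_blocks(truth_ortholog_map(sim), sim$genome_a,
                              sim$genome_b, gap_tolerance = 0,
                              min_block_size = 1)
    expect_equal(nrow(bl$blocks), sim$truth$n_true_segments)
    expect_equal(sum(bl$blocks$length), nrow(sim$truth$ortholog_pairs))
  }
})

test_that("emitted sequences and tables round-trip through the readers", {
  sim <- evolve_pair(evolver_params(n_genes = 15, mean_protein_len = 70,
                                    sub_proportion = 0.05, loss_prob = 0.05,
                                    gain_count = 1, n_inversions = 1,
                                    n_translocations = 0, n_contigs = 2,
                                    seed = 17))
  dirp <- withr::local_tempdir()
  fa <- file.path(dirp, "A.faa"); fn <- file.path(dirp, "A.fna")
  ft <- file.path(dirp, "A.tsv")
  write_fasta(sim$genome_a$proteins, fa)
  write_fasta(sim$genome_a$gene_dna, fn)
  write_gene_table(sim$genome_a, ft)
  expect_equal(read_fasta(fa, "protein"), sim$genome_a$proteins)
  expect_equal(read_fasta(fn, "dna"), sim$genome_a$gene_dna)
  g2 <- read_gene_table(ft, "tsv")
  expect_equal(g2$genes[, c("gene_id", "contig_id", "start", "end",
                            "strand", "ordinal")],
               sim$genome_a$genes[, c("gene_id", "contig_id", "start", "end",
                                      "strand", "ordinal")])
})

test_that("gene DNA is embedded in contigs at the stated coordinates", {
  sim <- evolve_pair(quiet_params(19))
  g <- sim$genome_a
  for (i in sample(nrow(g$genes), 5)) {
    row <- g$genes[i, ]
    sub <- substr(g$contig_seqs[[row$contig_id]], row$start, row$end)
    expected <- g$gene_dna[[row$gene_id]]
    if (row$strand == "-")
      expected <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(expected)))
    expect_equal(sub, expected)
  }
})

test_that("an island longer than the genome is rejected", {
  expect_error(evolve_pair(evolver_params(
    n_genes = 5, island_spec = list(length = 50), seed = 1)),
    "island longer")
})

test_that("marker test sets cover the degenerate fractions", {
  sim <- evolve_pair(quiet_params(23))
  m0 <- make_marker_test_set(sim$genome_a, 0, seed = 1, n_markers = 10)
  expect_equal(m0$expected_completeness_pct, 100)
  expect_equal(n_genes(m0$genome_deleted), 20L)
  m1 <- make_marker_test_set(sim$genome_a, 1, seed = 1, n_markers = 10)
  expect_equal(m1$expected_completeness_pct, 0)
  expect_equal(n_genes(m1$genome_deleted), 10L)
  expect_equal(length(m1$deleted_ids), 10L)
})
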