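# ortholog map between two toy gene orders; pairing given as b-index per
# a-position (NA = no ortholog)
toy_orthomap <- function(b_of_a, ids_a, ids_b) {
  keep <- !is.na(b_of_a)
  ortholog_map("A", "B",
               data.frame(gene_a = ids_a[keep], gene_b = ids_b[b_of_a[keep]],
                          pct_identity = 90, bit_score = 100,
                          stringsAsFactors = FALSE),
               length(ids_a), length(ids_b))
}

test_that("identity gene orders form one same-orientation block", {
  ids_a <- paste0("a", 1:5); ids_b <- paste0("b", 1:5)
  ga <- toy_genome("A", ids_a); gb <- toy_genome("B", ids_b)
  om <- toy_orthomap(1:5, ids_a, ids_b)
  bl <- find_synteny_blocks(om, ga, gb, gap_tolerance = 0)
  expect_equal(nrow(bl$blocks), 1L)
  expect_equal(bl$blocks$length, 5L)
  expect_equal(bl$blocks$orientation, "same")
  m <- synteny_metrics(bl, om)
  expect_equal(m$synteny_fraction, 1)
  expect_equal(m$mean_block_length, 5)
})

test_that("a shuffled ortholog breaks the run as enumerated by hand", {
  # pairs (a1,b1)(a2,b2)(a3,b5)(a4,b3)(a5,b4), gap 0, min size 2:
  # blocks {a1,a2} and {a4,a5}; (a3,b5) stays unplaced
  ids_a <- paste0("a", 1:5); ids_b <- paste0("b", 1:5)
  ga <- toy_genome("A", ids_a); gb <- toy_genome("B", ids_b)
  om <- toy_orthomap(c(1, 2, 5, 3, 4), ids_a, ids_b)
  bl <- find_synteny_blocks(om, ga, gb, gap_tolerance = 0, min_block_size = 2)
  expect_equal(nrow(bl$blocks), 2L)
  expect_equal(bl$blocks$length, c(2L, 2L))
  placed <- bl$pairs[!is.na(bl$pairs$block_id), ]
  expect_setequal(placed$gene_a, c("a1", "a2", "a4", "a5"))
  expect_true(is.na(bl$pairs$block_id[bl$pairs$gene_a == "a3"]))
  m <- synteny_metrics(bl, om)
  expect_equal(m$synteny_fraction, 0.8)
  expect_equal(m$mean_block_length, 2)
})

test_that("a reversed gene order is one inverted block", {
  ids_a <- paste0("a", 1:3); ids_b <- paste0("b", 1:3)
  ga <- toy_genome("A", ids_a)
  gb <- toy_genome("B", rev(ids_b))  # B order b3, b2, b1
  om <- toy_orthomap(1:3, ids_a, ids_b)
  bl <- find_synteny_blocks(om, ga, gb, gap_tolerance = 0)
  expect_equal(nrow(bl$blocks), 1L)
  expect_equal(bl$blocks$orientation, "inverted")
  expect_equal(bl$blocks$length, 3L)
  # with inversions disallowed, no block reaches min size 2
  bl2 <- find_synteny_blocks(om, ga, gb, gap_tolerance = 0,
                             allow_inversion = FALSE)
  expect_equal(nrow(bl2$blocks), 0L)
  expect_equal(synteny_metrics(bl2, om)$synteny_fraction, 0)
  expect_true(is.na(synteny_metrics(bl2, om)$mean_block_length))
})

test_that("no orthologs yields no blocks and zero fraction", {
  om <- ortholog_map("A", "B",
                     data.frame(gene_a = character(), gene_b = character(),
                                pct_identity = numeric(),
                                bit_score = numeric()), 5, 5)
  bl <- find_synteny_blocks(om, toy_genome("A", paste0("a", 1:5)),
                            toy_genome("B", paste0("b", 1:5)))
  expect_equal(nrow(bl$blocks), 0L)
  expect_equal(synteny_metrics(bl, om)$synteny_fraction, 0)
})

test_that("unknown ortholog gene ids are reported by name", {
  ids_a <- paste0("a", 1:3); ids_b <- paste0("b", 1:3)
  om <- ortholog_map("A", "B",
                     data.frame(gene_a = c("a1", "zz"), gene_b = c("b1", "b2"),
                                pct_identity = 90, bit_score = 10), 3, 3)
  expect_error(find_synteny_blocks(om, toy_genome("A", ids_a),
                                   toy_genome("B", ids_b)), "zz")
})

test_that("blocks never span contigs", {
  ids_a <- paste0("a", 1:6); ids_b <- paste0("b", 1:6)
  ga <- genome_record("A", data.frame(
    gene_id = ids_a, contig_id = rep(c("c1", "c2"), each = 3),
    start = rep(1:3, 2) * 100L, end = rep(1:3, 2) * 100L + 50L,
    strand = "+", stringsAsFactors = FALSE))
  gb <- toy_genome("B", ids_b)
  om <- toy_orthomap(1:6, ids_a, ids_b)
  bl <- find_synteny_blocks(om, ga, gb, gap_tolerance = 0)
  expect_equal(nrow(bl$blocks), 2L)
  expect_equal(sort(bl$blocks$contig_a), c("c1", "c2"))
})

test_that("detected blocks match the exhaustive gap-0 enumerator", {
  withr::local_seed(42)
  for (n in 2:6) {
    perms <- combinat_perms(n)
    for (k in seq_len(nrow(perms))) {
      ids_a <- paste0("a", 1:n); ids_b <- paste0("b", 1:n)
      ga <- toy_genome("A", ids_a); gb <- toy_genome("B", ids_b)
      om <- toy_orthomap(perms[k, ], ids_a, ids_b)
      bl <- find_synteny_blocks(om, ga, gb, gap_tolerance = 0,
                                min_block_size = 2)
      chains <- oracle_chains_gap0(seq_len(n) - 1L, perms[k, ] - 1L,
                                   min_block_size = 2)
      expect_equal(nrow(bl$blocks), length(chains))
      got <- sort(bl$pairs$gene_a[!is.na(bl$pairs$block_id)])
      exp <- if (length(chains)) sort(paste0("a", unlist(chains)))
      else character(0)
      expect_equal(got, exp)
    }
  }
})

test_that("greedy blocks are maximal and disjoint at positive gap tolerance", {
  withr::local_seed(43)
  for (rep in 1:40) {
    n <- sample(5:9, 1)
    m <- sample(3:n, 1)  # some genes without orthologs
    sel <- sort(sample(n, m))
    perm <- sample(n)
    ids_a <- paste0("a", 1:n); ids_b <- paste0("b", 1:n)
    ga <- toy_genome("A", ids_a); gb <- toy_genome("B", ids_b)
    b_of_a <- rep(NA_integer_, n)
    b_of_a[sel] <- perm[sel]
    om <- toy_orthomap(b_of_a, ids_a, ids_b)
    bl <- find_synteny_blocks(om, ga, gb, gap_tolerance = 1,
                              min_block_size = 2)
    expect_lte(sum(bl$blocks$length), nrow(om$pairs))
    tab <- table(bl$pairs$block_id)
    expect_equal(sum(tab), sum(bl$blocks$length))
    # maximality: no unplaced pair can extend a block at either end
    unplaced <- bl$pairs[is.na(bl$pairs$block_id), , drop = FALSE]
    for (b in bl$blocks$block_id) {
      members <- bl$pairs[!is.na(bl$pairs$block_id) &
                            bl$pairs$block_id == b, , drop = FALSE]
      dirn <- if (bl$blocks$orientation[bl$blocks$block_id == b] == "same")
        1L else -1L
      first <- members[which.min(members$a_ord), ]
      last <- members[which.max(members$a_ord), ]
      for (k in seq_len(nrow(unplaced))) {
        u <- unplaced[k, ]
        extends_tail <- u$contig_a == last$contig_a &&
          u$a_ord > last$a_ord & u$a_ord <= last$a_ord + 2L &&
          (u$b_ord - last$b_ord) * dirn >= 1 &&
          (u$b_ord - last$b_ord) * dirn <= 2
        extends_head <- u$contig_a == first$contig_a &&
          u$a_ord < first$a_ord & u$a_ord >= first$a_ord - 2L &&
          (first$b_ord - u$b_ord) * dirn >= 1 &&
          (first$b_ord - u$b_ord) * dirn <= 2
        expect_false(extends_tail || extends_head)
      }
    }
  }
})

test_that("swapping the genomes preserves blocks up to orientation", {
  withr::local_seed(44)
  for (rep in 1:20) {
    n <- sample(4:8, 1)
    perm <- sample(n)
    ids_a <- paste0("a", 1:n); ids_b <- paste0("b", 1:n)
    ga <- toy_genome("A", ids_a); gb <- toy_genome("B", ids_b)
    om <- toy_orthomap(perm, ids_a, ids_b)
    bl1 <- find_synteny_blocks(om, ga, gb, gap_tolerance = 0)
    bl2 <- find_synteny_blocks(swap_orthomap(om), gb, ga, gap_tolerance = 0)
    expect_equal(nrow(bl1$blocks), nrow(bl2$blocks))
    expect_equal(sort(bl1$blocks$length), sort(bl2$blocks$length))
    set1 <- lapply(split(bl1$pairs$gene_a[!is.na(bl1$pairs$block_id)],
                         bl1$pairs$block_id[!is.na(bl1$pairs$block_id)]), sort)
    set2s <- split(bl2$pairs$gene_b[!is.na(bl2$pairs$block_id)],
                   bl2$pairs$block_id[!is.na(bl2$pairs$block_id)])
    set2 <- lapply(set2s, sort)
    expect_setequal(unname(lapply(set1, paste, collapse = ",")),
                    unname(lapply(set2, paste, collapse = ",")))
  }
})
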