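ev_row <- function(source, evalue, coverage, pct_identity = NA_real_,
                   general = FALSE) {
  data.frame(source = source, evalue = evalue, coverage = coverage,
             pct_identity = pct_identity, general = general,
             stringsAsFactors = FALSE)
}

tier_of <- function(ev) classify_tier(ev, "g")$tier

test_that("tier thresholds match the curation scheme", {
  # strong specific-function domain hit
  expect_equal(tier_of(ev_row("domain_db", 1e-12, 0.80)), "specific")
  # weaker domain evidence: putative
  expect_equal(tier_of(ev_row("domain_db", 1e-6, 0.60)), "putative")
  # nr-only evidence above 30% identity over 70% of the protein: probable
  expect_equal(tier_of(ev_row("nr", 1e-20, 0.75, pct_identity = 35)),
               "probable")
  # nothing qualifying
  expect_equal(tier_of(ev_row("nr", 1e-20, 0.75, pct_identity = 25)),
               "hypothetical")
  expect_equal(tier_of(ev_row("domain_db", 1e-3, 0.90)), "hypothetical")
  expect_equal(tier_of(ev_row("domain_db", 1e-12, 0.40)), "hypothetical")
  expect_equal(classify_tier(ev_row("x", 1, 1)[0, ])$tier, "hypothetical")
})

test_that("boundary cases sit on the documented sides", {
  # e-value exactly 1e-10 with coverage just above 0.70: specific
  expect_equal(tier_of(ev_row("domain_db", 1e-10, 0.71)), "specific")
  # coverage exactly 0.70 fails specific (strictly more than 70%) but
  # passes putative (50-70% inclusive)
  expect_equal(tier_of(ev_row("domain_db", 1e-12, 0.70)), "putative")
  expect_equal(tier_of(ev_row("domain_db", 1e-4, 0.50)), "putative")
  # nr identity exactly 30 is not above 30
  expect_equal(tier_of(ev_row("nr", 1e-20, 0.80, pct_identity = 30)),
               "hypothetical")
})

test_that("general-function domains cap out at putative", {
  expect_equal(tier_of(ev_row("domain_db", 1e-30, 0.95, general = TRUE)),
               "putative")
})

test_that("precedence is specific > putative > probable", {
  ev <- rbind(ev_row("domain_db", 1e-12, 0.80),
              ev_row("domain_db", 1e-5, 0.60),
              ev_row("nr", 1e-30, 0.90, pct_identity = 60))
  expect_equal(tier_of(ev), "specific")
  ev2 <- rbind(ev_row("domain_db", 1e-5, 0.60),
               ev_row("nr", 1e-30, 0.90, pct_identity = 60))
  expect_equal(tier_of(ev2), "putative")
})

test_that("strengthening evidence never lowers the tier", {
  withr::local_seed(55)
  rank <- c(hypothetical = 0, probable = 1, putative = 2, specific = 3)
  for (rep in 1:200) {
    n <- sample(1:3, 1)
    ev <- do.call(rbind, lapply(seq_len(n), function(i) {
      if (stats::runif(1) < 0.6)
        ev_row("domain_db", 10^stats::runif(1, -15, 0),
               stats::runif(1), general = stats::runif(1) < 0.2)
      else
        ev_row("nr", 10^stats::runif(1, -15, 0), stats::runif(1),
               pct_identity = stats::runif(1, 0, 100))
    }))
    t0 <- rank[tier_of(ev)]
    k <- sample(nrow(ev), 1)
    ev$evalue[k] <- ev$evalue[k] / 10^stats::runif(1, 0, 5)
    ev$coverage[k] <- min(1, ev$coverage[k] + stats::runif(1, 0, 0.3))
    if (!is.na(ev$pct_identity[k]))
      ev$pct_identity[k] <- min(100, ev$pct_identity[k] +
                                  stats::runif(1, 0, 30))
    expect_gte(rank[tier_of(ev)], t0)
  }
})

test_that("exact motif matches are found at the right position", {
  hits <- scan_motif("AAFNFNGTSAA", "FNFNGTS", 0)
  expect_equal(hits$position, 2L)
  expect_equal(hits$mismatches, 0L)
  # one tolerated mismatch
  hits <- scan_motif("AAFNFNGTSAA", "FNFNATS", 1)
  expect_equal(hits$position, 2L)
  expect_equal(hits$mismatches, 1L)
  # three differences with no tolerance: nothing
  expect_equal(nrow(scan_motif("AAFNFNGTSAA", "FAFAGAS", 0)), 0L)
  # pattern longer than protein: empty result, not an error
  expect_equal(nrow(scan_motif("MKV", "FNFNGTS", 0)), 0L)
})

test_that("motif scanning agrees with the all-window Hamming oracle", {
  withr::local_seed(56)
  for (rep in 1:30) {
    s <- random_protein_seq(sample(20:200, 1))
    pat <- random_protein_seq(sample(4:8, 1))
    mm <- sample(0:2, 1)
    expect_equal(scan_motif(s, pat, mm), oracle_motif_scan(s, pat, mm))
  }
})

test_that("the built-in motif table finds planted diagnostic motifs", {
  withr::local_seed(57)
  prot <- c(bcp = paste0(random_protein_seq(40), "FNFNGTS",
                         random_protein_seq(40)),
            codh = paste0(random_protein_seq(30), "AYRGAGR",
                          random_protein_seq(30)))
  res <- scan_motif_table(prot)
  expect_true(any(res$gene_id == "bcp" &
                    res$motif_id == "sulfocyanin_FNFNGTS" &
                    res$position == 40))
  expect_true(any(res$gene_id == "codh" &
                    res$motif_id == "codh_form2_active_site"))
})

test_that("the type I copper site requires the ordered H..C..H..M placement", {
  mk <- function(pos, res, len = 60) {
    v <- rep("A", len)
    v[pos] <- res
    paste(v, collapse = "")
  }
  yes <- mk(c(10, 40, 45, 50), c("H", "C", "H", "M"))
  got <- check_type1_copper_site(yes)
  expect_true(got$found)
  expect_equal(unname(got$positions), c(10, 40, 45, 50))
  expect_false(check_type1_copper_site(strrep("A", 80))$found)
  # methionine missing entirely
  expect_false(check_type1_copper_site(mk(c(10, 40, 45),
                                          c("H", "C", "H")))$found)
  # right residues, wrong order (M before the second H)
  expect_false(check_type1_copper_site(mk(c(10, 40, 44, 58),
                                          c("H", "C", "M", "H"),
                                          len = 60))$found)
})

test_that("copper-site detection agrees with the exhaustive placement oracle", {
  withr::local_seed(58)
  spacing <- list(h1_c = c(20L, 60L), c_h2 = c(1L, 10L), h2_m = c(1L, 15L))
  aa_rich <- c("A", "G", "S", "H", "H", "C", "M")  # enriched in site residues
  for (rep in 1:60) {
    s <- paste(sample(aa_rich, sample(30:90, 1), replace = TRUE),
               collapse = "")
    expect_equal(check_type1_copper_site(s, spacing)$found,
                 oracle_copper_site(s, spacing))
  }
})
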