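# Independent brute-force oracles used to validate the package's
# implementations on small instances. These deliberately share no code with
# the package beyond the BLOSUM62 matrix constant.

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  m <- e$BLOSUM62
  m["X", ] <- pmin(m["X", ], -1)
  m[, "X"] <- pmin(m[, "X"], -1)
  m
})

# Gotoh affine-gap DP; gap of length L costs gap_open + L * gap_extend.
# type "local" = Smith-Waterman; "global" = Needleman-Wunsch with end gaps
# charged; "overlap" = ends-free global.
oracle_align_score <- function(a, b, mat, gap_open, gap_extend,
                               type = c("local", "global", "overlap")) {
  type <- match.arg(type)
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)  # gap in b (consuming a)
  Iy <- matrix(NEG, n + 1, m + 1)  # gap in a (consuming b)
  M[1, 1] <- 0
  if (type == "overlap") {
    M[, 1] <- 0
    M[1, ] <- 0
  } else if (type == "global") {
    Ix[seq_len(n) + 1L, 1] <- -gap_open - seq_len(n) * gap_extend
    Iy[1, seq_len(m) + 1L] <- -gap_open - seq_len(m) * gap_extend
  }
  floor0 <- if (type == "local") 0 else NEG
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- mat[av[i], bv[j]]
      best_prev <- max(floor0, M[i, j], Ix[i, j], Iy[i, j])
      M[i + 1, j + 1] <- max(floor0, best_prev + s)
      Ix[i + 1, j + 1] <- max(M[i, j + 1] - gap_open - gap_extend,
                              Ix[i, j + 1] - gap_extend)
      Iy[i + 1, j + 1] <- max(M[i + 1, j] - gap_open - gap_extend,
                              Iy[i + 1, j] - gap_extend)
    }
  }
  if (type == "local") {
    max(M)
  } else if (type == "global") {
    max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
  } else {
    max(M[n + 1, ], Ix[n + 1, ], Iy[n + 1, ],
        M[, m + 1], Ix[, m + 1], Iy[, m + 1])
  }
}

dna_score_matrix <- function(match = 1, mismatch = -1) {
  b <- c("A", "C", "G", "T")
  m <- matrix(mismatch, 4, 4, dimnames = list(b, b))
  diag(m) <- match
  m
}

# reciprocal best hits by explicit double loop, fully independent of the
# vectorized implementation
oracle_rbh <- function(hits_ab, hits_ba, evalue_max = 1e-5, cov_min = 0.7,
                       pident_min = 0) {
  qualify <- function(h) {
    h[h$evalue <= evalue_max & pmax(h$q_cov, h$s_cov) >= cov_min &
        h$pct_identity >= pident_min, , drop = FALSE]
  }
  best_of <- function(h, q) {
    hh <- h[h$query_id == q, , drop = FALSE]
    if (!nrow(hh)) return(NA_character_)
    best <- hh[1, ]
    for (k in seq_len(nrow(hh))) {
      x <- hh[k, ]
      if (x$bit_score > best$bit_score ||
          (x$bit_score == best$bit_score &&
             x$pct_identity > best$pct_identity) ||
          (x$bit_score == best$bit_score &&
             x$pct_identity == best$pct_identity &&
             x$subject_id < best$subject_id)) best <- x
    }
    best$subject_id
  }
  qab <- qualify(as.data.frame(hits_ab))
  qba <- qualify(as.data.frame(hits_ba))
  out <- list()
  for (x in unique(qab$query_id)) {
    y <- best_of(qab, x)
    if (!is.na(y) && identical(best_of(qba, y), x))
      out[[length(out) + 1L]] <- c(x, y)
  }
  if (!length(out)) return(data.frame(gene_a = character(),
                                      gene_b = character()))
  m <- do.call(rbind, out)
  d <- data.frame(gene_a = m[, 1], gene_b = m[, 2], stringsAsFactors = FALSE)
  d[order(d$gene_a), , drop = FALSE]
}

# maximal collinear chains at gap tolerance 0: since b-ordinals are unique
# across pairs, every pair has at most one predecessor and one successor,
# so chains are connected components of the adjacency links
oracle_chains_gap0 <- function(a_ord, b_ord, min_block_size = 2,
                               allow_inversion = TRUE) {
  n <- length(a_ord)
  succ <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    j <- which(a_ord == a_ord[i] + 1L)
    if (length(j) == 1L) {
      step <- b_ord[j] - b_ord[i]
      if (step == 1L || (allow_inversion && step == -1L)) succ[i] <- j
    }
  }
  has_pred <- rep(FALSE, n)
  has_pred[succ[!is.na(succ)]] <- TRUE
  chains <- list()
  for (s in which(!has_pred)) {
    ch <- s
    while (!is.na(succ[ch[length(ch)]])) ch <- c(ch, succ[ch[length(ch)]])
    # direction consistency: a chain may mix +1/-1 steps only if each pair's
    # link is unique; split at direction changes
    if (length(ch) >= 3L) {
      steps <- sign(diff(b_ord[ch]))
      brk <- which(diff(steps) != 0)
      if (length(brk)) {
        pieces <- split(ch, cumsum(c(0, seq_along(ch)[-1] %in% (brk + 1L))))
        for (p in pieces) chains[[length(chains) + 1L]] <- p
        next
      }
    }
    chains[[length(chains) + 1L]] <- ch
  }
  chains[vapply(chains, length, 0L) >= min_block_size]
}

# all-window Hamming motif scan by explicit substring comparison
oracle_motif_scan <- function(seq, pattern, max_mismatch) {
  k <- nchar(pattern)
  n <- nchar(seq)
  out <- list()
  if (k > n) return(data.frame(position = integer(), mismatches = integer()))
  for (i in seq_len(n - k + 1)) {
    w <- substr(seq, i, i + k - 1)
    mm <- sum(strsplit(w, "")[[1]] != strsplit(pattern, "")[[1]])
    if (mm <= max_mismatch)
      out[[length(out) + 1L]] <- data.frame(position = i - 1L,
                                            mismatches = mm)
  }
  if (!length(out)) return(data.frame(position = integer(),
                                      mismatches = integer()))
  do.call(rbind, out)
}

# exhaustive placement search for the type I copper site
oracle_copper_site <- function(seq, spacing) {
  v <- strsplit(toupper(seq), "")[[1]]
  h <- which(v == "H"); cc <- which(v == "C"); m <- which(v == "M")
  for (h1 in h) for (c1 in cc) for (h2 in h) for (m1 in m) {
    if (c1 - h1 >= spacing$h1_c[1] && c1 - h1 <= spacing$h1_c[2] &&
        h2 - c1 >= spacing$c_h2[1] && h2 - c1 <= spacing$c_h2[2] &&
        m1 - h2 >= spacing$h2_m[1] && m1 - h2 <= spacing$h2_m[2])
      return(TRUE)
  }
  FALSE
}

# maximal runs of TRUE in a logical vector, by explicit scan
oracle_runs <- function(x, min_run) {
  out <- list()
  i <- 1L
  while (i <= length(x)) {
    if (x[i]) {
      j <- i
      while (j < length(x) && x[j + 1L]) j <- j + 1L
      if (j - i + 1L >= min_run)
        out[[length(out) + 1L]] <- c(start = i, end = j)
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

random_protein_seq <- function(len) {
  paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                 "M", "F", "P", "S", "T", "W", "Y", "V"), len, replace = TRUE),
        collapse = "")
}

random_dna_seq <- function(len, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# a small genome_record laid out on one contig from an id -> order vector
toy_genome <- function(genome_id, gene_ids, contig = "c1", proteins = NULL) {
  n <- length(gene_ids)
  genome_record(genome_id,
                data.frame(gene_id = gene_ids, contig_id = contig,
                           start = seq_len(n) * 1000L,
                           end = seq_len(n) * 1000L + 500L,
                           strand = "+", stringsAsFactors = FALSE),
                proteins = proteins)
}

# hit-table row builder for concise test fixtures
hit_row <- function(q, s, bits, pident = 50, ev = 1e-20, qc = 1, sc = 1) {
  data.frame(query_id = q, subject_id = s, pct_identity = pident,
             aln_length = 100L, evalue = ev, bit_score = bits,
             q_cov = qc, s_cov = sc, stringsAsFactors = FALSE)
}

empty_hits <- function() {
  data.frame(query_id = character(), subject_id = character(),
             pct_identity = numeric(), aln_length = integer(),
             evalue = numeric(), bit_score = numeric(),
             q_cov = numeric(), s_cov = numeric(), stringsAsFactors = FALSE)
}

# random directed hit tables with deliberate score ties and some hits that
# fail the e-value / coverage filters
random_hit_tables <- function(na = 6, nb = 6, p_hit = 0.4) {
  ps <- paste0("p", seq_len(na))
  qs <- paste0("q", seq_len(nb))
  mk <- function(from, to) {
    rows <- list()
    for (x in from) for (y in to) {
      if (stats::runif(1) < p_hit) {
        rows[[length(rows) + 1L]] <- hit_row(
          x, y, bits = sample(c(50, 60, 60, 70, 80), 1),
          pident = sample(c(40, 55, 55, 70), 1),
          ev = sample(c(1e-30, 1e-20, 1e-3), 1, prob = c(0.45, 0.45, 0.1)),
          qc = sample(c(1, 0.9, 0.5), 1, prob = c(0.6, 0.3, 0.1)),
          sc = sample(c(1, 0.8), 1))
      }
    }
    if (!length(rows)) return(empty_hits())
    do.call(rbind, rows)
  }
  list(ab = mk(ps, qs), ba = mk(qs, ps))
}

# all permutations of 1..n as rows (n! x n matrix), deterministic order
combinat_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- combinat_perms(n - 1L)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub), n - 1L)))
  }
  unname(out)
}
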