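#' Parameters for the genome-pair evolver
#'
#' Defaults describe a pair of closely related single-contig archaeal
#' genomes: 200 genes of mean length 300 residues, 5% per-site amino acid
#' substitution per lineage, 2% per-gene loss, 5 gained genes, 2 inversions
#' and 1 translocation per lineage, background GC 0.5, no island.
#'
#' @param n_genes Ancestral gene count.
#' @param mean_protein_len Mean protein length (geometric, minimum 50).
#' @param sub_proportion Per-site amino acid substitution fraction applied
#'   independently to each lineage (0-1).
#' @param loss_prob Per-gene loss probability per lineage.
#' @param gain_count Lineage-specific genes gained per lineage.
#' @param n_inversions,n_translocations Rearrangements applied per lineage.
#' @param island_spec Optional list \code{(length, gc_shift_sd, lineage)}:
#'   insert a contiguous block of novel genes with GC shifted by
#'   \code{gc_shift_sd} background standard deviations into lineage
#'   \code{"a"} or \code{"b"}.
#' @param n_contigs Number of contigs per genome (genes split evenly).
#' @param gc_content Background GC fraction of generated DNA.
#' @param seed Integer seed governing all randomness.
#' @return List of class \code{evolver_params}.
#' @export
evolver_params <- function(n_genes = 200L, mean_protein_len = 300L,
                           sub_proportion = 0.05, loss_prob = 0.02,
                           gain_count = 5L, n_inversions = 2L,
                           n_translocations = 1L, island_spec = NULL,
                           n_contigs = 1L, gc_content = 0.5, seed = 1L) {
  stopifnot(n_genes >= 1L, mean_protein_len >= 50L,
            sub_proportion >= 0, sub_proportion <= 1,
            loss_prob >= 0, loss_prob <= 1, gain_count >= 0L,
            n_inversions >= 0L, n_translocations >= 0L,
            gc_content > 0, gc_content < 1, n_contigs >= 1L)
  if (!is.null(island_spec)) {
    stopifnot(is.list(island_spec), island_spec$length >= 1L)
    if (is.null(island_spec$lineage)) island_spec$lineage <- "a"
    if (is.null(island_spec$gc_shift_sd)) island_spec$gc_shift_sd <- 3
  }
  structure(list(n_genes = as.integer(n_genes),
                 mean_protein_len = as.integer(mean_protein_len),
                 sub_proportion = sub_proportion, loss_prob = loss_prob,
                 gain_count = as.integer(gain_count),
                 n_inversions = as.integer(n_inversions),
                 n_translocations = as.integer(n_translocations),
                 island_spec = island_spec, n_contigs = as.integer(n_contigs),
                 gc_content = gc_content, seed = as.integer(seed)),
            class = "evolver_params")
}

#' Evolve a genome pair from a common ancestor with full ground truth
#'
#' Generates an ancestor of random proteins, then lets two lineages diverge
#' independently: per-site substitutions (uniform over sites, replacement
#' uniform over the other 19 residues), whole-gene losses and gains,
#' inversions (reverse a random gene interval) and translocations (move an
#' interval), and optionally inserts a compositionally shifted island of
#' novel genes. DNA is produced by reverse-translating each protein with
#' codon choice weighted to hit the background GC (islands use a shifted
#' target). Every event is logged, so the true orthology, the true
#' collinear segments of the final gene orders, the true island interval
#' and the realized per-pair identities are all available.
#'
#' @param params An \code{evolver_params} list.
#' @return List of class \code{sim_pair} with elements \code{genome_a},
#'   \code{genome_b} (complete \code{genome_record}s with proteins, per-gene
#'   DNA and contig sequences) and \code{truth}: a list with
#'   \code{ortholog_pairs} (data.frame ancestor_id, gene_a, gene_b,
#'   identity), \code{n_true_segments}, \code{segment_id} per pair,
#'   \code{islands} (data.frame of inserted intervals), \code{lost_a},
#'   \code{lost_b}, \code{gained_a}, \code{gained_b}, and \code{params}.
#' @export
evolve_pair <- function(params = evolver_params()) {
  stopifnot(inherits(params, "evolver_params"))
  set.seed(params$seed)
  n <- params$n_genes
  lens <- random_gene_lengths(n, params$mean_protein_len)
  anc <- lapply(lens, random_protein)
  anc_ids <- sprintf("g%04d", seq_len(n))

  lineage <- function(tag) {
    prot <- lapply(anc, mutate_protein, s = params$sub_proportion)
    lost <- stats::runif(n) < params$loss_prob
    order_ids <- anc_ids[!lost]
    proteins <- stats::setNames(prot[!lost], paste0(tag, "_", order_ids))
    names(order_ids) <- NULL
    ids <- paste0(tag, "_", order_ids)
    gained <- character(0)
    if (params$gain_count > 0L) {
      glens <- random_gene_lengths(params$gain_count, params$mean_protein_len)
      for (k in seq_len(params$gain_count)) {
        gid <- sprintf("%s_n%03d", tag, k)
        pos <- sample.int(length(ids) + 1L, 1L)
        ids <- append(ids, gid, after = pos - 1L)
        proteins[[gid]] <- random_protein(glens[k])
        gained <- c(gained, gid)
      }
    }
    for (k in seq_len(params$n_inversions)) ids <- invert_interval(ids)
    for (k in seq_len(params$n_translocations)) ids <- translocate_interval(ids)
    list(ids = ids, proteins = proteins, lost = anc_ids[lost],
         gained = gained)
  }
  la <- lineage("a")
  lb <- lineage("b")

  # background DNA for every gene of both lineages
  dna_a <- reverse_translate_set(la$proteins, params$gc_content)
  dna_b <- reverse_translate_set(lb$proteins, params$gc_content)
  per_gene_gc <- vapply(c(dna_a, dna_b), gc_fraction, 0)
  gc_mu <- mean(per_gene_gc)
  gc_sd <- stats::sd(per_gene_gc)

  islands <- data.frame(lineage = character(), contig_id = character(),
                        start_ordinal = integer(), end_ordinal = integer(),
                        gene_ids = character(), target_gc = numeric(),
                        stringsAsFactors = FALSE)
  isl <- params$island_spec
  island_ids <- character(0)
  if (!is.null(isl)) {
    side <- if (isl$lineage == "a") la else lb
    tag <- isl$lineage
    if (isl$length > length(side$ids))
      stop("island longer than the recipient genome")
    target_gc <- min(max(gc_mu + isl$gc_shift_sd * gc_sd, 0.05), 0.95)
    ilens <- random_gene_lengths(isl$length, params$mean_protein_len)
    iprot <- stats::setNames(lapply(ilens, random_protein),
                             sprintf("%s_i%03d", tag, seq_len(isl$length)))
    idna <- reverse_translate_set(iprot, target_gc)
    pos <- sample.int(length(side$ids) + 1L, 1L)
    side$ids <- append(side$ids, names(iprot), after = pos - 1L)
    side$proteins <- c(side$proteins, iprot)
    island_ids <- names(iprot)
    if (tag == "a") { la <- side; dna_a <- c(dna_a, idna) }
    else { lb <- side; dna_b <- c(dna_b, idna) }
  }

  ga <- assemble_genome("A", la$ids, la$proteins, dna_a, params)
  gb <- assemble_genome("B", lb$ids, lb$proteins, dna_b, params)

  if (length(island_ids)) {
    gt <- if (isl$lineage == "a") ga else gb
    idx <- match(island_ids, gt$genes$gene_id)
    islands <- data.frame(lineage = isl$lineage,
                          contig_id = gt$genes$contig_id[idx[1L]],
                          start_ordinal = min(gt$genes$ordinal[idx]),
                          end_ordinal = max(gt$genes$ordinal[idx]),
                          gene_ids = paste(island_ids, collapse = ","),
                          target_gc = min(max(gc_mu + isl$gc_shift_sd * gc_sd,
                                              0.05), 0.95),
                          stringsAsFactors = FALSE)
  }

  shared <- setdiff(anc_ids, union(la$lost, lb$lost))
  identity <- vapply(shared, function(g) {
    i <- match(g, anc_ids)
    pa <- strsplit(la$proteins[[paste0("a_", g)]], "")[[1L]]
    pb <- strsplit(lb$proteins[[paste0("b_", g)]], "")[[1L]]
    mean(pa == pb)
  }, 0)
  pairs <- data.frame(ancestor_id = shared,
                      gene_a = paste0("a_", shared),
                      gene_b = paste0("b_", shared),
                      identity = unname(identity),
                      stringsAsFactors = FALSE)
  seg <- true_segments(pairs, ga, gb)
  truth <- list(ortholog_pairs = cbind(pairs, segment_id = seg$segment_id),
                n_true_segments = seg$n_segments,
                islands = islands,
                lost_a = la$lost, lost_b = lb$lost,
                gained_a = la$gained, gained_b = lb$gained,
                gc_background_mean = gc_mu, gc_background_sd = gc_sd,
                params = params)
  structure(list(genome_a = ga, genome_b = gb, truth = truth),
            class = "sim_pair")
}

#' @export
print.sim_pair <- function(x, ...) {
  cat("sim_pair: ", n_genes(x$genome_a), " + ", n_genes(x$genome_b),
      " genes, ", nrow(x$truth$ortholog_pairs), " true ortholog pairs, ",
      x$truth$n_true_segments, " true collinear segment(s)\n", sep = "")
  invisible(x)
}

#' Ortholog map implied by simulation ground truth
#'
#' Builds an \code{ortholog_map} directly from the evolver's recorded
#' ancestor-mediated gene pairing (identities are the realized site
#' identities, as percentages). Useful for testing synteny and island
#' detection in isolation from the aligner.
#'
#' @param sim A \code{sim_pair}.
#' @return An \code{ortholog_map}.
#' @export
truth_ortholog_map <- function(sim) {
  p <- sim$truth$ortholog_pairs
  ortholog_map(sim$genome_a$genome_id, sim$genome_b$genome_id,
               data.frame(gene_a = p$gene_a, gene_b = p$gene_b,
                          pct_identity = 100 * p$identity,
                          bit_score = NA_real_, stringsAsFactors = FALSE),
               n_genes(sim$genome_a), n_genes(sim$genome_b))
}

#' Build a marker set with a known deleted fraction
#'
#' Samples marker genes from a genome, deletes an exact fraction of them
#' from a copy of the genome, and records the expected completeness, so
#' completeness estimation can be checked against truth.
#'
#' @param genome A \code{genome_record} with proteins.
#' @param fraction_deleted Fraction of markers removed from the genome copy.
#' @param seed Integer seed.
#' @param n_markers Number of marker genes sampled (default 50, capped at
#'   the gene count).
#' @return List with \code{markers} (named character vector),
#'   \code{genome_deleted} (a \code{genome_record}),
#'   \code{expected_completeness_pct}, \code{deleted_ids}.
#' @export
make_marker_test_set <- function(genome, fraction_deleted, seed = 1L,
                                 n_markers = 50L) {
  stopifnot(fraction_deleted >= 0, fraction_deleted <= 1,
            !is.null(genome$proteins))
  set.seed(seed)
  n_markers <- min(n_markers, n_genes(genome))
  marker_ids <- sort(sample(genome$genes$gene_id, n_markers))
  n_del <- round(fraction_deleted * n_markers)
  deleted <- if (n_del > 0L) sort(sample(marker_ids, n_del)) else character(0)
  keep <- !genome$genes$gene_id %in% deleted
  g2 <- genome_record(paste0(genome$genome_id, "_del"),
                      genome$genes[keep, , drop = FALSE],
                      proteins = genome$proteins[setdiff(names(genome$proteins),
                                                         deleted)],
                      gene_dna = genome$gene_dna[setdiff(names(genome$gene_dna),
                                                         deleted)])
  list(markers = stats::setNames(unlist(genome$proteins[marker_ids]),
                                 paste0("marker_", marker_ids)),
       genome_deleted = g2,
       expected_completeness_pct = 100 * (n_markers - n_del) / n_markers,
       deleted_ids = deleted)
}

## ---- internal helpers ----

random_gene_lengths <- function(n, mean_len) {
  50L + stats::rgeom(n, 1 / (mean_len - 50 + 1))
}

random_protein <- function(len) {
  paste(sample(AA20, len, replace = TRUE), collapse = "")
}

mutate_protein <- function(seq, s) {
  if (s <= 0) return(seq)
  v <- strsplit(seq, "")[[1L]]
  hit <- which(stats::runif(length(v)) < s)
  for (i in hit) v[i] <- sample(setdiff(AA20, v[i]), 1L)
  paste(v, collapse = "")
}

invert_interval <- function(ids, max_len = 8L) {
  n <- length(ids)
  if (n < 2L) return(ids)
  len <- sample(2L:min(max_len, n), 1L)
  start <- sample.int(n - len + 1L, 1L)
  idx <- start:(start + len - 1L)
  ids[idx] <- rev(ids[idx])
  ids
}

translocate_interval <- function(ids, max_len = 8L) {
  n <- length(ids)
  if (n < 2L) return(ids)
  len <- sample(1L:min(max_len, n - 1L), 1L)
  start <- sample.int(n - len + 1L, 1L)
  seg <- ids[start:(start + len - 1L)]
  rest <- ids[-(start:(start + len - 1L))]
  pos <- sample.int(length(rest) + 1L, 1L)
  append(rest, seg, after = pos - 1L)
}

# codon table: codons per amino acid (DNA alphabet)
CODONS <- list(
  A = c("GCT", "GCC", "GCA", "GCG"), R = c("CGT", "CGC", "CGA", "CGG", "AGA", "AGG"),
  N = c("AAT", "AAC"), D = c("GAT", "GAC"), C = c("TGT", "TGC"),
  Q = c("CAA", "CAG"), E = c("GAA", "GAG"), G = c("GGT", "GGC", "GGA", "GGG"),
  H = c("CAT", "CAC"), I = c("ATT", "ATC", "ATA"),
  L = c("TTA", "TTG", "CTT", "CTC", "CTA", "CTG"), K = c("AAA", "AAG"),
  M = "ATG", F = c("TTT", "TTC"), P = c("CCT", "CCC", "CCA", "CCG"),
  S = c("TCT", "TCC", "TCA", "TCG", "AGT", "AGC"),
  T = c("ACT", "ACC", "ACA", "ACG"), W = "TGG", Y = c("TAT", "TAC"),
  V = c("GTT", "GTC", "GTA", "GTG"), X = "NNN")

codon_gc_counts <- lapply(CODONS, function(cs)
  vapply(strsplit(cs, ""), function(v) sum(v %in% c("G", "C")), 0L))

# pick the codon-weighting parameter p so the expected GC of a random
# protein reverse-translated with weights p^gc (1-p)^(3-gc) matches target
calibrate_gc_param <- function(target) {
  exp_gc <- function(p) {
    per_aa <- vapply(names(CODONS), function(aa) {
      gc <- codon_gc_counts[[aa]]
      w <- p^gc * (1 - p)^(3 - gc)
      sum(w * gc) / sum(w) / 3
    }, 0)
    mean(per_aa[AA20])  # uniform residue usage
  }
  lo <- exp_gc(0.001); hi <- exp_gc(0.999)
  if (target <= lo) return(0.001)
  if (target >= hi) return(0.999)
  stats::uniroot(function(p) exp_gc(p) - target, c(0.001, 0.999))$root
}

reverse_translate <- function(protein, p) {
  v <- strsplit(protein, "")[[1L]]
  codons <- vapply(v, function(aa) {
    cs <- CODONS[[aa]]
    if (length(cs) == 1L) return(cs)
    gc <- codon_gc_counts[[aa]]
    w <- p^gc * (1 - p)^(3 - gc)
    sample(cs, 1L, prob = w)
  }, "", USE.NAMES = FALSE)
  paste(c(codons, "TAA"), collapse = "")
}

reverse_translate_set <- function(proteins, target_gc) {
  p <- calibrate_gc_param(target_gc)
  stats::setNames(lapply(proteins, reverse_translate, p = p),
                  names(proteins))
}

gc_fraction <- function(s) {
  v <- strsplit(s, "")[[1L]]
  sum(v %in% c("G", "C")) / length(v)
}

# lay genes along contigs with fixed 30 bp spacers; '-' strand genes are
# embedded reverse-complemented in the contig sequence
assemble_genome <- function(genome_id, ids, proteins, dna, params) {
  n <- length(ids)
  contig_of <- sort(rep_len(seq_len(params$n_contigs), n))
  spacer_len <- 30L
  rows <- vector("list", n)
  contig_seqs <- stats::setNames(
    vector("list", params$n_contigs),
    sprintf("%s_c%02d", genome_id, seq_len(params$n_contigs)))
  for (ct in seq_len(params$n_contigs)) {
    sel <- which(contig_of == ct)
    pos <- 1L
    pieces <- character(0)
    for (i in sel) {
      gdna <- dna[[ids[i]]]
      spacer <- paste(sample(c("A", "C", "G", "T"), spacer_len, replace = TRUE,
                             prob = c((1 - params$gc_content) / 2,
                                      params$gc_content / 2,
                                      params$gc_content / 2,
                                      (1 - params$gc_content) / 2)),
                      collapse = "")
      strand <- sample(c("+", "-"), 1L)
      start <- pos + spacer_len
      end <- start + nchar(gdna) - 1L
      rows[[i]] <- data.frame(gene_id = ids[i],
                              contig_id = names(contig_seqs)[ct],
                              start = start, end = end, strand = strand,
                              stringsAsFactors = FALSE)
      embedded <- if (strand == "+") gdna else revcomp(gdna)
      pieces <- c(pieces, spacer, embedded)
      pos <- end + 1L
    }
    contig_seqs[[ct]] <- paste(pieces, collapse = "")
  }
  genome_record(genome_id, do.call(rbind, rows),
                proteins = stats::setNames(unlist(proteins[ids]), ids),
                gene_dna = stats::setNames(unlist(dna[ids]), ids),
                contig_seqs = stats::setNames(unlist(contig_seqs),
                                              names(contig_seqs)))
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# decompose the true ortholog pairing into maximal strictly consecutive
# collinear segments (gap 0, inversions allowed) of the final gene orders
true_segments <- function(pairs, ga, gb) {
  if (!nrow(pairs))
    return(list(segment_id = integer(0), n_segments = 0L))
  pa <- gene_positions(ga, pairs$gene_a)
  pb <- gene_positions(gb, pairs$gene_b)
  d <- data.frame(contig_a = pa$contig_id, a_ord = pa$ordinal,
                  contig_b = pb$contig_id, b_ord = pb$ordinal)
  o <- order(d$contig_a, d$a_ord)
  seg <- integer(nrow(d))
  cur <- 1L
  dir <- 0L
  seg[o[1L]] <- cur
  if (nrow(d) > 1L) {
    for (k in 2:nrow(d)) {
      i <- o[k]; j <- o[k - 1L]
      step_b <- d$b_ord[i] - d$b_ord[j]
      contig_ok <- d$contig_a[i] == d$contig_a[j] &&
        d$contig_b[i] == d$contig_b[j]
      adjacent <- contig_ok && d$a_ord[i] - d$a_ord[j] == 1L &&
        abs(step_b) == 1L && (dir == 0L || step_b == dir)
      if (adjacent) {
        dir <- step_b
      } else {
        cur <- cur + 1L
        dir <- 0L
      }
      seg[i] <- cur
    }
  }
  list(segment_id = seg, n_segments = cur)
}
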