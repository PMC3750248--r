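# Karlin-Altschul parameters for gapped BLOSUM62 (gap open 11, extend 1),
# the values used by BLASTP for this scoring scheme.
KA_LAMBDA <- 0.267
KA_K <- 0.041

bit_score_from_raw <- function(raw) (KA_LAMBDA * raw - log(KA_K)) / log(2)

evalue_from_bits <- function(bits, m, n) m * n * 2^(-bits)

#' All-vs-all local protein alignment
#'
#' Aligns every protein of set A against every protein of set B with
#' Smith-Waterman (BLOSUM62, gap open 11, extend 1) and reports one directed
#' hit per ordered pair whose e-value passes the threshold. Bit scores follow
#' the Karlin-Altschul transformation of the raw score with the standard
#' gapped BLOSUM62 parameters; the e-value search space is query length times
#' total subject-set length. Intended for desk-scale inputs (up to a few
#' thousand proteins in total); larger comparisons should be imported as
#' precomputed hit tables via [read_hit_table()].
#'
#' A fast score-only pass computes the full score matrix; full tracebacks
#' (for percent identity and coverage) are computed only for pairs that pass
#' the e-value filter.
#'
#' @param proteins_a,proteins_b Named character vectors of protein sequences.
#' @param evalue_max Report hits with e-value at or below this (default 1e-3).
#' @param gap_open,gap_extend Affine gap penalties (positive costs).
#' @return A \code{hit_table} data.frame of directed a-vs-b hits.
#' @export
align_all_vs_all <- function(proteins_a, proteins_b, evalue_max = 1e-3,
                             gap_open = 11, gap_extend = 1) {
  if (!length(proteins_a) || !length(proteins_b))
    stop("both protein sets must be non-empty")
  empty_a <- !nchar(proteins_a)
  empty_b <- !nchar(proteins_b)
  if (any(empty_a)) {
    warning("skipping zero-length proteins: ",
            paste(names(proteins_a)[empty_a], collapse = ", "))
    proteins_a <- proteins_a[!empty_a]
  }
  if (any(empty_b)) {
    warning("skipping zero-length proteins: ",
            paste(names(proteins_b)[empty_b], collapse = ", "))
    proteins_b <- proteins_b[!empty_b]
  }
  if (!length(proteins_a) || !length(proteins_b)) return(empty_hit_table())
  mat <- blosum62_matrix()
  aset <- Biostrings::AAStringSet(proteins_a)
  db_len <- sum(nchar(proteins_b))
  scores <- matrix(NA_real_, length(proteins_a), length(proteins_b),
                   dimnames = list(names(proteins_a), names(proteins_b)))
  for (j in seq_along(proteins_b)) {
    scores[, j] <- Biostrings::pairwiseAlignment(
      aset, Biostrings::AAString(proteins_b[[j]]), type = "local",
      substitutionMatrix = mat, gapOpening = gap_open,
      gapExtension = gap_extend, scoreOnly = TRUE)
  }
  bits <- bit_score_from_raw(scores)
  ev <- evalue_from_bits(bits, nchar(proteins_a), db_len)
  keep <- which(ev <= evalue_max, arr.ind = TRUE)
  if (!nrow(keep)) return(empty_hit_table())
  keep <- keep[order(keep[, 1L], keep[, 2L]), , drop = FALSE]
  rows <- vector("list", nrow(keep))
  for (k in seq_len(nrow(keep))) {
    i <- keep[k, 1L]; j <- keep[k, 2L]
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(proteins_a[[i]]),
      Biostrings::AAString(proteins_b[[j]]), type = "local",
      substitutionMatrix = mat, gapOpening = gap_open,
      gapExtension = gap_extend)
    stats_ <- alignment_stats(aln)
    rows[[k]] <- data.frame(
      query_id = names(proteins_a)[i], subject_id = names(proteins_b)[j],
      pct_identity = stats_$pct_identity, aln_length = stats_$columns,
      evalue = ev[i, j], bit_score = bits[i, j],
      q_cov = stats_$q_span / nchar(proteins_a[[i]]),
      s_cov = stats_$s_span / nchar(proteins_b[[j]]),
      stringsAsFactors = FALSE)
  }
  validate_hit_table(do.call(rbind, rows))
}

# identity = matches / alignment columns (gap columns included in the
# denominator); X never counts as a match
alignment_stats <- function(aln) {
  p <- as.character(Biostrings::alignedPattern(aln))
  s <- as.character(Biostrings::alignedSubject(aln))
  pc <- strsplit(p, "")[[1L]]
  sc <- strsplit(s, "")[[1L]]
  matches <- sum(pc == sc & pc != "-" & pc != "X")
  list(pct_identity = 100 * matches / length(pc),
       columns = length(pc),
       q_span = sum(pc != "-"),
       s_span = sum(sc != "-"))
}

blosum62_matrix <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  m <- e$BLOSUM62
  # score X-against-anything as a mismatch, never a positive match
  m["X", ] <- pmin(m["X", ], -1)
  m[, "X"] <- pmin(m[, "X"], -1)
  m
}

#' Call reciprocal-best-hit orthologs from directed hit tables
#'
#' A pair (x, y) is an ortholog call iff y is x's best qualifying hit among
#' the a-to-b hits and x is y's best qualifying hit among the b-to-a hits.
#' "Best" is the maximum bit score, ties broken by maximum percent identity,
#' then by lexicographically smallest subject id, so the call is fully
#' deterministic. A hit qualifies if its e-value, identity, and coverage of
#' the shorter sequence (the larger of query and subject coverage) pass the
#' thresholds.
#'
#' @param hits_ab,hits_ba \code{hit_table}s of directed hits a-to-b and
#'   b-to-a.
#' @param genome_a_id,genome_b_id Genome identifiers for bookkeeping.
#' @param n_genes_a,n_genes_b Gene counts of the two genomes (needed by the
#'   ortholog-fraction normalization).
#' @param evalue_max,cov_min,pident_min Qualification thresholds; defaults
#'   1e-5, 0.7 (of the shorter sequence), 0.
#' @return An object of class \code{ortholog_map}: list with
#'   \code{genome_a_id}, \code{genome_b_id}, \code{pairs} (data.frame
#'   \code{gene_a}, \code{gene_b}, \code{pct_identity}, \code{bit_score}),
#'   \code{n_genes_a}, \code{n_genes_b}.
#' @export
call_rbh <- function(hits_ab, hits_ba, genome_a_id = "A", genome_b_id = "B",
                     n_genes_a = NULL, n_genes_b = NULL,
                     evalue_max = 1e-5, cov_min = 0.7, pident_min = 0) {
  best_ab <- best_hits(hits_ab, evalue_max, cov_min, pident_min)
  best_ba <- best_hits(hits_ba, evalue_max, cov_min, pident_min)
  if (is.null(n_genes_a))
    n_genes_a <- length(unique(c(hits_ab$query_id, hits_ba$subject_id)))
  if (is.null(n_genes_b))
    n_genes_b <- length(unique(c(hits_ab$subject_id, hits_ba$query_id)))
  if (!nrow(best_ab) || !nrow(best_ba)) {
    pairs <- data.frame(gene_a = character(), gene_b = character(),
                        pct_identity = numeric(), bit_score = numeric(),
                        stringsAsFactors = FALSE)
  } else {
    back <- stats::setNames(best_ba$subject_id, best_ba$query_id)
    recip <- !is.na(back[best_ab$subject_id]) &
      back[best_ab$subject_id] == best_ab$query_id
    sel <- best_ab[recip, , drop = FALSE]
    pairs <- data.frame(gene_a = sel$query_id, gene_b = sel$subject_id,
                        pct_identity = sel$pct_identity,
                        bit_score = sel$bit_score, stringsAsFactors = FALSE)
    pairs <- pairs[order(pairs$gene_a), , drop = FALSE]
    rownames(pairs) <- NULL
  }
  ortholog_map(genome_a_id, genome_b_id, pairs, n_genes_a, n_genes_b)
}

# best qualifying hit per query: max bit score, tie -> max identity,
# tie -> lexicographic smallest subject
best_hits <- function(hits, evalue_max, cov_min, pident_min) {
  h <- as.data.frame(hits)
  if (!nrow(h)) return(h)
  shorter_cov <- pmax(h$q_cov, h$s_cov)
  h <- h[h$evalue <= evalue_max & shorter_cov >= cov_min &
           h$pct_identity >= pident_min, , drop = FALSE]
  if (!nrow(h)) return(h)
  o <- order(h$query_id, -h$bit_score, -h$pct_identity, h$subject_id)
  h <- h[o, , drop = FALSE]
  h[!duplicated(h$query_id), , drop = FALSE]
}

#' Construct an ortholog map
#'
#' @param genome_a_id,genome_b_id Genome ids.
#' @param pairs data.frame with \code{gene_a}, \code{gene_b},
#'   \code{pct_identity}, \code{bit_score}.
#' @param n_genes_a,n_genes_b Gene counts.
#' @return Object of class \code{ortholog_map}.
#' @export
ortholog_map <- function(genome_a_id, genome_b_id, pairs, n_genes_a,
                         n_genes_b) {
  stopifnot(is.data.frame(pairs),
            all(c("gene_a", "gene_b", "pct_identity") %in% names(pairs)))
  if (anyDuplicated(pairs$gene_a) || anyDuplicated(pairs$gene_b))
    stop("a gene may appear in at most one ortholog pair")
  if (nrow(pairs) > min(n_genes_a, n_genes_b))
    stop("more ortholog pairs than genes in the smaller genome")
  structure(list(genome_a_id = genome_a_id, genome_b_id = genome_b_id,
                 pairs = pairs, n_genes_a = as.integer(n_genes_a),
                 n_genes_b = as.integer(n_genes_b)),
            class = "ortholog_map")
}

#' @export
print.ortholog_map <- function(x, ...) {
  cat("ortholog_map ", x$genome_a_id, " vs ", x$genome_b_id, ": ",
      nrow(x$pairs), " pairs (", x$n_genes_a, " and ", x$n_genes_b,
      " genes)\n", sep = "")
  invisible(x)
}

#' Reverse the orientation of an ortholog map
#' @param orthomap An \code{ortholog_map}.
#' @return The same map with genomes a and b swapped.
#' @export
swap_orthomap <- function(orthomap) {
  p <- orthomap$pairs
  ortholog_map(orthomap$genome_b_id, orthomap$genome_a_id,
               data.frame(gene_a = p$gene_b, gene_b = p$gene_a,
                          pct_identity = p$pct_identity,
                          bit_score = p$bit_score, stringsAsFactors = FALSE),
               orthomap$n_genes_b, orthomap$n_genes_a)
}

#' Write / read an ortholog map's pair table as TSV
#' @param orthomap An \code{ortholog_map}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_orthologs <- function(orthomap, path) {
  utils::write.table(orthomap$pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_orthologs
#' @param genome_a_id,genome_b_id,n_genes_a,n_genes_b Map metadata (not
#'   stored in the TSV).
#' @export
read_orthologs <- function(path, genome_a_id = "A", genome_b_id = "B",
                           n_genes_a, n_genes_b) {
  pairs <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  if (!"bit_score" %in% names(pairs)) pairs$bit_score <- NA_real_
  ortholog_map(genome_a_id, genome_b_id, pairs, n_genes_a, n_genes_b)
}
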