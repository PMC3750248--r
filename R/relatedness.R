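#' Average amino acid identity (AAI) over an ortholog map
#'
#' The unweighted arithmetic mean of percent identity over the reciprocal
#' best-hit pairs; set \code{weight_by_length = TRUE} for the
#' alignment-length-weighted variant.
#'
#' @param orthomap An \code{ortholog_map}.
#' @param weight_by_length Weight each pair by its alignment length (requires
#'   an \code{aln_length} column in the pair table).
#' @return AAI as a percentage in [0, 100].
#' @export
compute_aai <- function(orthomap, weight_by_length = FALSE) {
  p <- orthomap$pairs
  if (!nrow(p))
    stop("no ortholog pairs between ", orthomap$genome_a_id, " and ",
         orthomap$genome_b_id, "; AAI is undefined")
  if (weight_by_length) {
    if (is.null(p$aln_length))
      stop("length weighting requires an aln_length column")
    sum(p$pct_identity * p$aln_length) / sum(p$aln_length)
  } else {
    mean(p$pct_identity)
  }
}

#' Ortholog fraction: pairs normalized by the mean gene count
#'
#' The number of ortholog pairs divided by the average of the two genomes'
#' gene counts, a size-normalized measure of shared gene content.
#'
#' @param orthomap An \code{ortholog_map} with positive gene counts.
#' @return Fraction in [0, 1].
#' @export
compute_ortholog_fraction <- function(orthomap) {
  if (orthomap$n_genes_a <= 0L || orthomap$n_genes_b <= 0L)
    stop("both genomes must have at least one gene")
  nrow(orthomap$pairs) / ((orthomap$n_genes_a + orthomap$n_genes_b) / 2)
}

#' Pairwise nucleotide identity by global alignment
#'
#' Global alignment with free terminal gaps (ends-free Needleman-Wunsch;
#' match +1, mismatch -1, gap open 5, gap extend 2). Identity is matches
#' over alignment columns, excluding the terminal-overhang columns
#' (leading/trailing gap runs), since gene-boundary calls differ between
#' genomes and internal divergence is the signal.
#'
#' @param seq_a,seq_b Non-empty DNA strings.
#' @param match,mismatch,gap_open,gap_extend Scoring parameters.
#' @return Percent identity in [0, 100].
#' @export
nucleotide_identity <- function(seq_a, seq_b, match = 1, mismatch = -1,
                                gap_open = 5, gap_extend = 2) {
  if (!nchar(seq_a) || !nchar(seq_b)) stop("empty sequence")
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(seq_a), Biostrings::DNAString(seq_b),
    type = "overlap", substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_extend)
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
  inner <- which(p != "-" & s != "-")
  if (!length(inner)) return(0)
  span <- seq(min(inner), max(inner))
  100 * sum(p[span] == s[span]) / length(span)
}

#' Summarize whole-genome relatedness for one genome pair
#'
#' Bundles AAI, ortholog fraction and the two synteny statistics into one
#' row-like record.
#'
#' @param orthomap An \code{ortholog_map}.
#' @param blocks Optional \code{synteny_blocks} from [find_synteny_blocks()];
#'   if omitted the synteny fields are NA.
#' @return Object of class \code{relatedness_summary} (a one-row list).
#' @export
relatedness_summary <- function(orthomap, blocks = NULL) {
  n_orth <- nrow(orthomap$pairs)
  out <- list(genome_a_id = orthomap$genome_a_id,
              genome_b_id = orthomap$genome_b_id,
              aai = if (n_orth) compute_aai(orthomap) else NA_real_,
              n_orthologs = n_orth,
              ortholog_fraction = compute_ortholog_fraction(orthomap),
              n_syntenous = NA_integer_, synteny_fraction = NA_real_,
              mean_block_length = NA_real_)
  if (!is.null(blocks)) {
    m <- synteny_metrics(blocks, orthomap)
    out$n_syntenous <- m$n_syntenous
    out$synteny_fraction <- m$synteny_fraction
    out$mean_block_length <- m$mean_block_length
  }
  structure(out, class = "relatedness_summary")
}

#' @export
print.relatedness_summary <- function(x, ...) {
  cat(sprintf("%s vs %s: AAI %.1f%%, %d orthologs (fraction %.3f)",
              x$genome_a_id, x$genome_b_id, x$aai, x$n_orthologs,
              x$ortholog_fraction))
  if (!is.na(x$synteny_fraction))
    cat(sprintf(", synteny %.3f, mean block %.1f genes",
                x$synteny_fraction, x$mean_block_length))
  cat("\n")
  invisible(x)
}
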