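#' Construct a genome record
#'
#' A \code{genome_record} is the unit of all pairwise comparison: an ordered
#' set of contigs, each carrying an ordered gene table, plus optional protein
#' and per-gene nucleotide sequences keyed by gene id.
#'
#' Gene coordinates are 1-based inclusive (GFF convention); ordinals are
#' 0-based positions in the gene order of each contig, assigned after sorting
#' genes by start coordinate (ties broken by gene id).
#'
#' @param genome_id Non-empty genome identifier.
#' @param genes data.frame with columns \code{gene_id}, \code{contig_id},
#'   \code{start}, \code{end}, \code{strand} (\code{"+"}/\code{"-"}) and
#'   optionally \code{annotation}. Ordinals are (re)assigned here.
#' @param proteins Optional named character vector of amino acid sequences
#'   (20 canonical residues plus \code{X}), names matching gene ids.
#' @param gene_dna Optional named character vector of per-gene coding DNA.
#' @param contig_seqs Optional named character vector of contig nucleotide
#'   sequences.
#' @return An object of class \code{genome_record}.
#' @export
genome_record <- function(genome_id, genes, proteins = NULL, gene_dna = NULL,
                          contig_seqs = NULL) {
  if (!is.character(genome_id) || length(genome_id) != 1L || !nzchar(genome_id))
    stop("genome_id must be a non-empty string")
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  required <- c("gene_id", "contig_id", "start", "end", "strand")
  missing_cols <- setdiff(required, names(genes))
  if (length(missing_cols))
    stop("gene table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene_id in genome '", genome_id, "': ",
         genes$gene_id[duplicated(genes$gene_id)][1L])
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  bad <- which(genes$start > genes$end)
  if (length(bad))
    stop("gene '", genes$gene_id[bad[1L]], "' has start > end")
  if (!all(genes$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'; offending gene: ",
         genes$gene_id[which(!genes$strand %in% c("+", "-"))[1L]])
  if (is.null(genes$annotation)) genes$annotation <- NA_character_
  ord <- order(genes$contig_id, genes$start, genes$gene_id)
  genes <- genes[ord, , drop = FALSE]
  genes$ordinal <- stats::ave(integer(nrow(genes)), genes$contig_id,
                              FUN = function(z) seq_along(z) - 1L)
  rownames(genes) <- NULL
  if (!is.null(proteins)) {
    proteins <- validate_protein_set(proteins)
    unknown <- setdiff(names(proteins), genes$gene_id)
    # proteins without a gene row are tolerated only if the gene table is empty
    if (length(unknown) && nrow(genes) > 0L)
      stop("protein ids not in gene table: ",
           paste(utils::head(unknown, 3L), collapse = ", "))
  }
  structure(
    list(genome_id = genome_id, genes = genes, proteins = proteins,
         gene_dna = gene_dna, contig_seqs = contig_seqs),
    class = "genome_record"
  )
}

validate_protein_set <- function(proteins) {
  if (is.null(names(proteins)) || any(!nzchar(names(proteins))))
    stop("protein sequences must be named by gene id")
  if (anyDuplicated(names(proteins)))
    stop("duplicate protein id: ", names(proteins)[duplicated(names(proteins))][1L])
  proteins <- toupper(proteins)
  proteins <- sub("\\*+$", "", proteins)
  bad <- regexpr(sprintf("[^%sX]", paste(AA20, collapse = "")), proteins)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop("illegal residue in '", names(proteins)[i], "' at position ", bad[i])
  }
  proteins
}

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' @export
print.genome_record <- function(x, ...) {
  cat("genome_record '", x$genome_id, "': ", nrow(x$genes), " genes on ",
      length(unique(x$genes$contig_id)), " contig(s)",
      if (!is.null(x$proteins)) sprintf("; %d protein seqs", length(x$proteins)),
      "\n", sep = "")
  invisible(x)
}

#' Number of genes in a genome record
#' @param genome A \code{genome_record}.
#' @return Integer gene count.
#' @export
n_genes <- function(genome) {
  stopifnot(inherits(genome, "genome_record"))
  nrow(genome$genes)
}

# (contig_id, ordinal) lookup keyed by gene id; errors on unknown ids
gene_positions <- function(genome, gene_ids) {
  idx <- match(gene_ids, genome$genes$gene_id)
  if (anyNA(idx))
    stop("gene id not found in genome '", genome$genome_id, "': ",
         gene_ids[which(is.na(idx))[1L]])
  data.frame(gene_id = gene_ids,
             contig_id = genome$genes$contig_id[idx],
             ordinal = genome$genes$ordinal[idx],
             stringsAsFactors = FALSE)
}
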