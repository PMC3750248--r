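#' Detect lineage-specific gene clusters (candidate genomic islands)
#'
#' A gene of the query genome is "foreign-like" when it has an ortholog in at
#' most \code{max_panel_hits} genomes of a reference panel (default 0: no
#' ortholog anywhere in the panel). Islands are maximal runs of at least
#' \code{min_run} consecutive foreign-like genes on one contig — the pattern
#' expected of a horizontally acquired block, such as a cluster of
#' hypothetical proteins absent from all related genomes.
#'
#' @param query_genome \code{genome_record} of the genome screened.
#' @param orthomaps_to_panel List of \code{ortholog_map}s, one per panel
#'   genome, each with the query as genome a (maps with the query as genome
#'   b are swapped automatically by matching \code{genome_a_id}).
#' @param min_run Minimum genes per island (default 5).
#' @param max_panel_hits Maximum panel genomes an island gene may have an
#'   ortholog in (default 0).
#' @return data.frame of class \code{island_calls}: one row per island with
#'   \code{genome_id}, \code{contig_id}, \code{start_ordinal},
#'   \code{end_ordinal} (inclusive), \code{n_genes}, \code{gene_ids}
#'   (comma-separated), reported in contig order.
#' @export
find_islands <- function(query_genome, orthomaps_to_panel, min_run = 5L,
                         max_panel_hits = 0L) {
  if (!length(orthomaps_to_panel)) stop("panel must contain >= 1 genome")
  g <- query_genome$genes
  qid <- query_genome$genome_id
  hits_per_gene <- integer(nrow(g))
  names(hits_per_gene) <- g$gene_id
  for (om in orthomaps_to_panel) {
    if (om$genome_a_id != qid && om$genome_b_id == qid) om <- swap_orthomap(om)
    if (om$genome_a_id != qid)
      stop("ortholog map ", om$genome_a_id, " vs ", om$genome_b_id,
           " does not involve query genome ", qid)
    with_orth <- intersect(om$pairs$gene_a, g$gene_id)
    hits_per_gene[with_orth] <- hits_per_gene[with_orth] + 1L
  }
  foreign <- hits_per_gene <= max_panel_hits
  out <- list()
  for (ct in unique(g$contig_id)) {
    sel <- g$contig_id == ct
    ord <- order(g$ordinal[sel])
    fvec <- foreign[g$gene_id[sel][ord]]
    runs <- rle(unname(fvec))
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (r in which(runs$values & runs$lengths >= min_run)) {
      idx <- seq(starts[r], ends[r])
      ids <- g$gene_id[sel][ord][idx]
      out[[length(out) + 1L]] <- data.frame(
        genome_id = qid, contig_id = ct,
        start_ordinal = g$ordinal[sel][ord][idx[1L]],
        end_ordinal = g$ordinal[sel][ord][idx[length(idx)]],
        n_genes = length(idx),
        gene_ids = paste(ids, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out)
  else data.frame(genome_id = character(), contig_id = character(),
                  start_ordinal = integer(), end_ordinal = integer(),
                  n_genes = integer(), gene_ids = character(),
                  stringsAsFactors = FALSE)
  class(res) <- c("island_calls", "data.frame")
  res
}

#' GC-composition deviation of a candidate island
#'
#' Compares the GC content of the concatenated island genes against the
#' per-gene GC distribution of the whole genome: \code{gc_z} is the island
#' GC minus the genome per-gene mean, in units of the per-gene standard
#' deviation. The strand GC skew (G-C)/(G+C) of the island is also reported;
#' a transferred block from a donor of similar composition shows neither a
#' GC-content anomaly nor a skew anomaly, consistent with an ancient
#' transfer or a like-composition donor.
#'
#' @param island_genes_dna Character vector of island gene DNA sequences.
#' @param genome_gene_dna Character vector of DNA sequences for all genes of
#'   the genome (the background distribution).
#' @return List with \code{gc_island}, \code{gc_genome_mean},
#'   \code{gc_genome_sd}, \code{gc_z}, \code{gc_skew_island}.
#' @export
composition_deviation <- function(island_genes_dna, genome_gene_dna) {
  if (!length(island_genes_dna) || any(!nchar(island_genes_dna)))
    stop("island gene sequences must be non-empty")
  if (!length(genome_gene_dna) || any(!nchar(genome_gene_dna)))
    stop("genome gene sequences must be non-empty")
  island <- paste(toupper(island_genes_dna), collapse = "")
  counts <- function(s) {
    v <- strsplit(s, "")[[1L]]
    c(g = sum(v == "G"), c = sum(v == "C"), n = length(v))
  }
  ic <- counts(island)
  gc_island <- (ic["g"] + ic["c"]) / ic["n"]
  per_gene <- vapply(toupper(genome_gene_dna), function(s) {
    x <- counts(s)
    (x["g"] + x["c"]) / x["n"]
  }, 0, USE.NAMES = FALSE)
  mu <- mean(per_gene)
  sdv <- stats::sd(per_gene)
  skew <- if (ic["g"] + ic["c"] > 0) (ic["g"] - ic["c"]) / (ic["g"] + ic["c"])
  else NA_real_
  list(gc_island = unname(gc_island), gc_genome_mean = mu,
       gc_genome_sd = sdv,
       gc_z = unname((gc_island - mu) / sdv),
       gc_skew_island = unname(skew))
}
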