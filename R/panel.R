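#' Run the all-pairs relatedness pipeline over a genome panel
#'
#' Orchestrates homology, relatedness and synteny (plus completeness and
#' island screening when the inputs are present) for every pair of genomes
#' in a panel, producing the symmetric statistic matrices that summarize a
#' set of co-occurring genomes: AAI, ortholog fraction, synteny fraction and
#' mean syntenous block length.
#'
#' The configuration is a single declarative list (or a YAML file with the
#' same structure) carrying every threshold, so a run is fully reproducible
#' from its config alone:
#' \preformatted{
#' genomes:            # >= 2 entries
#'   - id: A
#'     proteins: A.faa       # FASTA path (or a named character vector)
#'     genes: A.tsv          # 6-column gene table (or a genome_record)
#'     dna: A.ffn            # optional per-gene DNA FASTA
#' thresholds:
#'   evalue_max: 1e-5
#'   cov_min: 0.7
#'   pident_min: 0
#' synteny:
#'   gap_tolerance: 1
#'   min_block_size: 2
#'   allow_inversion: true
#' markers: markers.faa      # optional -> per-genome completeness
#' islands:
#'   min_run: 5
#'   max_panel_hits: 0
#' }
#' Precomputed directed hit tables may be given per pair as
#' \code{hits: [{a: A, b: B, ab: AB.tsv, ba: BA.tsv}, ...]}; pairs without
#' hit tables are aligned internally.
#'
#' @param config List as above, or path to a YAML file.
#' @param out Optional output directory; when given, one TSV per statistic
#'   plus \code{run_meta.json} are written. Existing per-pair ortholog TSVs
#'   in \code{out} are reused unless \code{force = TRUE}, making interrupted
#'   runs resumable.
#' @param force Recompute pairs even when cached ortholog tables exist.
#' @param quiet Suppress per-stage progress messages.
#' @return Object of class \code{panel_report}: list with \code{aai},
#'   \code{ortholog_fraction}, \code{synteny_fraction},
#'   \code{mean_block_length} (symmetric matrices), \code{summaries} (list
#'   of \code{relatedness_summary}), \code{completeness}, \code{islands},
#'   \code{meta}.
#' @export
run_panel <- function(config, out = NULL, force = FALSE, quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- panel_config(config)
  genomes <- lapply(cfg$genomes, load_panel_genome)
  names(genomes) <- vapply(genomes, function(g) g$genome$genome_id, "")
  ids <- names(genomes)
  if (!is.null(out) && !dir.exists(out)) dir.create(out, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)

  mk <- function() matrix(NA_real_, length(ids), length(ids),
                          dimnames = list(ids, ids))
  aai <- mk(); orf <- mk(); synf <- mk(); mbl <- mk()
  diag(aai) <- 100; diag(orf) <- 1; diag(synf) <- 1
  summaries <- list()
  orthomaps <- stats::setNames(vector("list", length(ids)), ids)
  for (i in ids) orthomaps[[i]] <- list()

  pairs <- utils::combn(ids, 2L, simplify = FALSE)
  for (pr in pairs) {
    a <- pr[1L]; b <- pr[2L]
    cache <- if (!is.null(out))
      file.path(out, sprintf("orthologs_%s_%s.tsv", a, b)) else NULL
    ga <- genomes[[a]]; gb <- genomes[[b]]
    if (!is.null(cache) && file.exists(cache) && !force) {
      say("[", a, " vs ", b, "] reusing cached orthologs")
      om <- read_orthologs(cache, a, b, n_genes(ga$genome), n_genes(gb$genome))
    } else {
      say("[", a, " vs ", b, "] aligning and calling orthologs")
      hits <- pair_hits(cfg, ga, gb)
      om <- call_rbh(hits$ab, hits$ba, a, b,
                     n_genes(ga$genome), n_genes(gb$genome),
                     evalue_max = cfg$thresholds$evalue_max,
                     cov_min = cfg$thresholds$cov_min,
                     pident_min = cfg$thresholds$pident_min)
      if (!is.null(cache)) write_orthologs(om, cache)
    }
    blocks <- find_synteny_blocks(om, ga$genome, gb$genome,
                                  gap_tolerance = cfg$synteny$gap_tolerance,
                                  min_block_size = cfg$synteny$min_block_size,
                                  allow_inversion = cfg$synteny$allow_inversion)
    sm <- relatedness_summary(om, blocks)
    summaries[[paste(a, b, sep = "|")]] <- sm
    aai[a, b] <- aai[b, a] <- sm$aai
    orf[a, b] <- orf[b, a] <- sm$ortholog_fraction
    synf[a, b] <- synf[b, a] <- sm$synteny_fraction
    mbl[a, b] <- mbl[b, a] <- sm$mean_block_length
    orthomaps[[a]][[b]] <- om
    orthomaps[[b]][[a]] <- swap_orthomap(om)
  }

  completeness <- NULL
  if (!is.null(cfg$markers)) {
    markers <- if (is.character(cfg$markers) && length(cfg$markers) == 1L)
      read_fasta(cfg$markers, "protein") else cfg$markers
    completeness <- lapply(ids, function(i)
      estimate_completeness(genomes[[i]]$genome$proteins, markers,
                            genome_id = i))
    names(completeness) <- ids
  }

  islands <- NULL
  if (!is.null(cfg$islands)) {
    islands <- do.call(rbind, lapply(ids, function(i)
      find_islands(genomes[[i]]$genome, orthomaps[[i]],
                   min_run = cfg$islands$min_run,
                   max_panel_hits = cfg$islands$max_panel_hits)))
  }

  meta <- list(tool = "pairplasma",
               version = as.character(utils::packageVersion("pairplasma")),
               n_genomes = length(ids), genome_ids = ids,
               thresholds = cfg$thresholds, synteny = cfg$synteny,
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  report <- structure(list(aai = aai, ortholog_fraction = orf,
                           synteny_fraction = synf, mean_block_length = mbl,
                           summaries = summaries,
                           completeness = completeness, islands = islands,
                           orthomaps = orthomaps, meta = meta),
                      class = "panel_report")
  if (!is.null(out)) write_panel_report(report, out)
  report
}

#' @export
print.panel_report <- function(x, ...) {
  cat("panel_report over", x$meta$n_genomes, "genomes\nAAI matrix (%):\n")
  print(round(x$aai, 1))
  invisible(x)
}

#' Write a panel report's matrices and tables as TSV + JSON metadata
#' @param report A \code{panel_report}.
#' @param out Output directory.
#' @return Invisibly, \code{out}.
#' @export
write_panel_report <- function(report, out) {
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  wm <- function(m, f) utils::write.table(
    data.frame(genome = rownames(m), m, check.names = FALSE),
    file.path(out, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wm(report$aai, "aai.tsv")
  wm(report$ortholog_fraction, "ortholog_fraction.tsv")
  wm(report$synteny_fraction, "synteny_fraction.tsv")
  wm(report$mean_block_length, "mean_block_length.tsv")
  if (!is.null(report$completeness)) {
    ct <- do.call(rbind, lapply(report$completeness, function(r)
      data.frame(genome = r$genome_id, n_markers = r$n_markers,
                 n_found = r$n_found, completeness_pct = r$completeness_pct)))
    utils::write.table(ct, file.path(out, "completeness.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(report$islands))
    utils::write.table(as.data.frame(report$islands),
                       file.path(out, "islands.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  jsonlite::write_json(report$meta, file.path(out, "run_meta.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out)
}

## ---- config handling ----

panel_config <- function(config) {
  if (is.null(config$genomes) || length(config$genomes) < 2L)
    stop("config must list at least 2 genomes")
  defaults <- list(
    thresholds = list(evalue_max = 1e-5, cov_min = 0.7, pident_min = 0),
    synteny = list(gap_tolerance = 1L, min_block_size = 2L,
                   allow_inversion = TRUE))
  cfg <- utils::modifyList(defaults, config)
  # fail fast: every referenced file must exist before any computation
  for (g in cfg$genomes) {
    for (f in c("proteins", "genes", "dna")) {
      v <- g[[f]]
      if (is.character(v) && length(v) == 1L && !file.exists(v))
        stop("missing input file for genome '", g$id, "': ", v)
    }
  }
  if (!is.null(cfg$hits)) {
    for (h in cfg$hits)
      for (f in c("ab", "ba"))
        if (is.character(h[[f]]) && !file.exists(h[[f]]))
          stop("missing hit table: ", h[[f]])
  }
  if (is.character(cfg$markers) && length(cfg$markers) == 1L &&
      !file.exists(cfg$markers))
    stop("missing marker FASTA: ", cfg$markers)
  cfg
}

load_panel_genome <- function(g) {
  genome <- if (inherits(g$genes, "genome_record")) g$genes
  else read_gene_table(g$genes, dialect = if (grepl("\\.gff3?$", g$genes))
    "gff3" else "tsv", genome_id = g$id)
  proteins <- if (is.character(g$proteins) && length(g$proteins) == 1L &&
                  file.exists(g$proteins)) read_fasta(g$proteins, "protein")
  else validate_protein_set(g$proteins)
  genome <- genome_record(genome$genome_id, genome$genes, proteins = proteins,
                          gene_dna = if (!is.null(g$dna) && is.character(g$dna) &&
                                         length(g$dna) == 1L && file.exists(g$dna))
                            read_fasta(g$dna, "dna") else g$dna)
  list(genome = genome, spec = g)
}

pair_hits <- function(cfg, ga, gb) {
  a <- ga$genome$genome_id; b <- gb$genome$genome_id
  if (!is.null(cfg$hits)) {
    for (h in cfg$hits) {
      if (identical(h$a, a) && identical(h$b, b)) {
        return(list(
          ab = read_hit_table(h$ab, ga$genome$proteins, gb$genome$proteins),
          ba = read_hit_table(h$ba, gb$genome$proteins, ga$genome$proteins)))
      }
    }
  }
  list(ab = align_all_vs_all(ga$genome$proteins, gb$genome$proteins,
                             evalue_max = cfg$thresholds$evalue_max),
       ba = align_all_vs_all(gb$genome$proteins, ga$genome$proteins,
                             evalue_max = cfg$thresholds$evalue_max))
}
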