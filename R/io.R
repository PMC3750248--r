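#' Read a FASTA file into a named character vector
#'
#' Protein sequences are uppercased and trailing stop characters (\code{*})
#' are stripped; residues are checked against the 20 canonical amino acids
#' plus \code{X}. DNA sequences are uppercased and checked against ACGTN.
#'
#' @param path Path to a FASTA file.
#' @param alphabet \code{"protein"} or \code{"dna"}.
#' @return Named character vector of sequences, names are the FASTA ids
#'   (first whitespace-delimited token of each header).
#' @export
read_fasta <- function(path, alphabet = c("protein", "dna")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("no such file: ", path)
  seqs <- if (alphabet == "protein") {
    Biostrings::readBStringSet(path)  # permissive read; validated below
  } else {
    Biostrings::readBStringSet(path)
  }
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids))
    stop("duplicate FASTA id: ", ids[duplicated(ids)][1L])
  out <- stats::setNames(toupper(as.character(seqs)), ids)
  if (alphabet == "protein") {
    out <- validate_protein_set(out)
  } else {
    bad <- regexpr("[^ACGTN]", out)
    if (any(bad > 0L)) {
      i <- which(bad > 0L)[1L]
      stop("illegal nucleotide in '", ids[i], "' at position ", bad[i])
    }
  }
  out
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return Invisibly, \code{path}.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(!is.null(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, max(nchar(s), 1L), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a gene-order table into a genome record
#'
#' Two dialects are supported: GFF3 (one row per CDS/gene feature; the gene id
#' is taken from the \code{ID=} or \code{locus_tag=} attribute) and a simple
#' 6-column TSV with header \code{genome, contig, gene_id, start, end, strand}.
#' Genes are sorted by (contig, start) and 0-based ordinals assigned per
#' contig.
#'
#' @param path Path to the table.
#' @param dialect \code{"tsv"} or \code{"gff3"}.
#' @param genome_id Genome identifier; for the TSV dialect defaults to the
#'   value in the \code{genome} column.
#' @param feature_types GFF3 feature types treated as genes.
#' @return A \code{genome_record} (without sequences).
#' @export
read_gene_table <- function(path, dialect = c("tsv", "gff3"), genome_id = NULL,
                            feature_types = c("CDS", "gene")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "tsv") {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE, quote = "",
                             comment.char = "")
    need <- c("genome", "contig", "gene_id", "start", "end", "strand")
    if (!all(need %in% names(tab)))
      stop("gene TSV must have columns: ", paste(need, collapse = ", "))
    if (is.null(genome_id)) {
      gid <- unique(tab$genome)
      if (length(gid) != 1L) stop("gene TSV mixes genome ids: ",
                                  paste(gid, collapse = ", "))
      genome_id <- gid
    }
    genes <- data.frame(gene_id = as.character(tab$gene_id),
                        contig_id = as.character(tab$contig),
                        start = tab$start, end = tab$end,
                        strand = as.character(tab$strand),
                        stringsAsFactors = FALSE)
    if ("annotation" %in% names(tab)) genes$annotation <- tab$annotation
  } else {
    lines <- readLines(path)
    lines <- lines[!grepl("^#", lines) & nzchar(lines)]
    if (!length(lines)) stop("GFF3 file has no feature rows: ", path)
    parts <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(parts) != 9L)) stop("malformed GFF3 row (need 9 columns)")
    m <- do.call(rbind, parts)
    keep <- m[, 3L] %in% feature_types
    m <- m[keep, , drop = FALSE]
    attr_id <- function(a) {
      id <- sub(".*(?:^|;)ID=([^;]+).*", "\\1", a)
      lt <- sub(".*(?:^|;)locus_tag=([^;]+).*", "\\1", a)
      ifelse(grepl("(^|;)ID=", a), id, ifelse(grepl("(^|;)locus_tag=", a), lt, NA))
    }
    ids <- attr_id(m[, 9L])
    if (anyNA(ids)) stop("GFF3 feature without ID or locus_tag attribute")
    if (is.null(genome_id))
      genome_id <- tools::file_path_sans_ext(basename(path))
    genes <- data.frame(gene_id = ids, contig_id = m[, 1L],
                        start = as.integer(m[, 4L]), end = as.integer(m[, 5L]),
                        strand = m[, 7L], stringsAsFactors = FALSE)
  }
  genome_record(genome_id, genes)
}

#' Write a genome's gene table as 6-column TSV
#'
#' @param genome A \code{genome_record}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_gene_table <- function(genome, path) {
  g <- genome$genes
  out <- data.frame(genome = genome$genome_id, contig = g$contig_id,
                    gene_id = g$gene_id, start = g$start, end = g$end,
                    strand = g$strand, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BLAST-style 12-column tabular hit file
#'
#' Columns follow the standard tabular dialect (outfmt 6): query, subject,
#' percent identity, alignment length, mismatches, gap opens, qstart, qend,
#' sstart, send, e-value, bit score. Query/subject coverage is computed as
#' aligned span divided by sequence length, which requires the sequence
#' lengths (supply directly or via the FASTA-derived sequence vectors).
#'
#' @param path Path to the tabular file.
#' @param query_lengths,subject_lengths Named integer vectors of sequence
#'   lengths, or named character vectors of sequences (lengths are taken with
#'   \code{nchar}).
#' @return data.frame of class \code{hit_table} with columns \code{query_id},
#'   \code{subject_id}, \code{pct_identity}, \code{aln_length},
#'   \code{evalue}, \code{bit_score}, \code{q_cov}, \code{s_cov}.
#' @export
read_hit_table <- function(path, query_lengths, subject_lengths) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  if (!length(lines)) return(empty_hit_table())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 12L))
    stop("hit table row ", which(lengths(parts) < 12L)[1L],
         " has fewer than 12 columns")
  m <- do.call(rbind, lapply(parts, `[`, 1:12))
  num <- function(col, name) {
    v <- suppressWarnings(as.numeric(m[, col]))
    if (anyNA(v))
      stop("non-numeric ", name, " at line ", which(is.na(v))[1L])
    v
  }
  q_len <- seq_lengths(query_lengths)
  s_len <- seq_lengths(subject_lengths)
  qid <- m[, 1L]; sid <- m[, 2L]
  if (anyNA(q_len[qid])) stop("query length unknown for: ",
                              qid[which(is.na(q_len[qid]))[1L]])
  if (anyNA(s_len[sid])) stop("subject length unknown for: ",
                              sid[which(is.na(s_len[sid]))[1L]])
  qstart <- num(7L, "qstart"); qend <- num(8L, "qend")
  sstart <- num(9L, "sstart"); send <- num(10L, "send")
  hits <- data.frame(
    query_id = qid, subject_id = sid,
    pct_identity = num(3L, "pident"),
    aln_length = as.integer(num(4L, "length")),
    evalue = num(11L, "evalue"),
    bit_score = num(12L, "bitscore"),
    q_cov = (abs(qend - qstart) + 1) / unname(q_len[qid]),
    s_cov = (abs(send - sstart) + 1) / unname(s_len[sid]),
    stringsAsFactors = FALSE
  )
  validate_hit_table(hits)
}

seq_lengths <- function(x) {
  if (is.character(x)) stats::setNames(nchar(x), names(x)) else x
}

empty_hit_table <- function() {
  h <- data.frame(query_id = character(), subject_id = character(),
                  pct_identity = numeric(), aln_length = integer(),
                  evalue = numeric(), bit_score = numeric(),
                  q_cov = numeric(), s_cov = numeric(),
                  stringsAsFactors = FALSE)
  class(h) <- c("hit_table", "data.frame")
  h
}

validate_hit_table <- function(hits) {
  stopifnot(all(hits$pct_identity >= 0 & hits$pct_identity <= 100),
            all(hits$evalue >= 0), all(hits$bit_score >= 0))
  hits$q_cov <- pmin(hits$q_cov, 1)
  hits$s_cov <- pmin(hits$s_cov, 1)
  class(hits) <- c("hit_table", "data.frame")
  hits
}

#' Write a hit table as TSV
#' @param hits A \code{hit_table}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_hit_table <- function(hits, path) {
  utils::write.table(as.data.frame(hits), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
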