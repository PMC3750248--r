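#' Detect collinear blocks of ortholog pairs in two gene orders
#'
#' A syntenous block is a maximal run of ortholog pairs whose ordinals
#' strictly increase in genome A and strictly increase (orientation
#' \code{"same"}) or strictly decrease (\code{"inverted"}) in genome B, with
#' at most \code{gap_tolerance} intervening genes between consecutive pairs
#' on each genome, never spanning a contig boundary. Gene strand is ignored:
#' only order carries the signal, and block orientation derives from the
#' ordinal direction.
#'
#' Blocks are built greedily left to right along genome A: the leftmost
#' unassigned pair seeds a block, which is extended by the candidate with the
#' smallest A-ordinal satisfying the gap and orientation rules among
#' unassigned pairs; the first extension fixes the orientation. Each
#' ortholog pair is assigned to at most one block, and blocks below
#' \code{min_block_size} are discarded (their pairs stay unplaced).
#'
#' @param orthomap An \code{ortholog_map}.
#' @param genome_a,genome_b \code{genome_record}s resolving every ortholog
#'   gene id to a (contig, ordinal).
#' @param gap_tolerance Maximum intervening genes between consecutive block
#'   members on each genome (default 1).
#' @param min_block_size Minimum pairs per reported block (default 2).
#' @param allow_inversion Permit inverted blocks (default TRUE).
#' @return Object of class \code{synteny_blocks}: list with \code{blocks}
#'   (one row per block: contig_a, contig_b, orientation, length, ordinal
#'   ranges) and \code{pairs} (every ortholog pair with its ordinals and the
#'   block id it was assigned to, NA if unplaced).
#' @export
find_synteny_blocks <- function(orthomap, genome_a, genome_b,
                                gap_tolerance = 1, min_block_size = 2,
                                allow_inversion = TRUE) {
  p <- orthomap$pairs
  if (!nrow(p)) {
    return(structure(list(blocks = empty_block_frame(),
                          pairs = empty_pair_frame()),
                     class = "synteny_blocks"))
  }
  pos_a <- gene_positions(genome_a, p$gene_a)
  pos_b <- gene_positions(genome_b, p$gene_b)
  d <- data.frame(gene_a = p$gene_a, gene_b = p$gene_b,
                  contig_a = pos_a$contig_id, a_ord = pos_a$ordinal,
                  contig_b = pos_b$contig_id, b_ord = pos_b$ordinal,
                  stringsAsFactors = FALSE)
  d <- d[order(d$contig_a, d$a_ord), , drop = FALSE]
  rownames(d) <- NULL
  d$block_id <- NA_integer_
  assigned <- logical(nrow(d))
  chains <- list()
  repeat {
    seed <- which(!assigned)[1L]
    if (is.na(seed)) break
    chain <- seed
    assigned[seed] <- TRUE
    orientation <- NA_character_
    cur <- seed
    repeat {
      nxt <- next_link(d, assigned, cur, orientation, gap_tolerance,
                       allow_inversion)
      if (is.na(nxt$idx)) break
      orientation <- nxt$orientation
      chain <- c(chain, nxt$idx)
      assigned[nxt$idx] <- TRUE
      cur <- nxt$idx
    }
    chains[[length(chains) + 1L]] <-
      list(idx = chain,
           orientation = if (is.na(orientation)) "same" else orientation)
  }
  keep <- vapply(chains, function(ch) length(ch$idx) >= min_block_size, TRUE)
  # pairs in dropped chains stay unplaced
  chains <- chains[keep]
  blocks <- lapply(seq_along(chains), function(b) {
    idx <- chains[[b]]$idx
    data.frame(block_id = b, contig_a = d$contig_a[idx[1L]],
               contig_b = d$contig_b[idx[1L]],
               orientation = chains[[b]]$orientation,
               length = length(idx),
               a_ord_start = min(d$a_ord[idx]), a_ord_end = max(d$a_ord[idx]),
               b_ord_start = min(d$b_ord[idx]), b_ord_end = max(d$b_ord[idx]),
               stringsAsFactors = FALSE)
  })
  blocks <- if (length(blocks)) do.call(rbind, blocks) else empty_block_frame()
  for (b in seq_along(chains)) d$block_id[chains[[b]]$idx] <- b
  if (nrow(blocks)) {
    o <- order(blocks$contig_a, blocks$a_ord_start)
    blocks <- blocks[o, , drop = FALSE]
    remap <- stats::setNames(seq_len(nrow(blocks)), blocks$block_id)
    blocks$block_id <- seq_len(nrow(blocks))
    d$block_id <- unname(remap[as.character(d$block_id)])
    rownames(blocks) <- NULL
  }
  structure(list(blocks = blocks, pairs = d), class = "synteny_blocks")
}

# the next unassigned pair extending the chain at index cur:
# smallest a-ordinal on the same contig pair within the gap window whose
# b-ordinal step matches (or, if unset, fixes) the orientation
next_link <- function(d, assigned, cur, orientation, gap_tolerance,
                      allow_inversion) {
  ca <- d$contig_a[cur]; cb <- d$contig_b[cur]
  ao <- d$a_ord[cur]; bo <- d$b_ord[cur]
  cand <- which(!assigned & d$contig_a == ca & d$contig_b == cb &
                  d$a_ord > ao & d$a_ord <= ao + gap_tolerance + 1L)
  if (!length(cand)) return(list(idx = NA_integer_, orientation = orientation))
  cand <- cand[order(d$a_ord[cand], d$b_ord[cand])]
  for (i in cand) {
    step <- d$b_ord[i] - bo
    ok_same <- step >= 1L && step <= gap_tolerance + 1L
    ok_inv <- allow_inversion && step <= -1L && step >= -(gap_tolerance + 1L)
    if (is.na(orientation)) {
      if (ok_same) return(list(idx = i, orientation = "same"))
      if (ok_inv) return(list(idx = i, orientation = "inverted"))
    } else if (orientation == "same" && ok_same) {
      return(list(idx = i, orientation = orientation))
    } else if (orientation == "inverted" && ok_inv) {
      return(list(idx = i, orientation = orientation))
    }
  }
  list(idx = NA_integer_, orientation = orientation)
}

empty_block_frame <- function() {
  data.frame(block_id = integer(), contig_a = character(),
             contig_b = character(), orientation = character(),
             length = integer(), a_ord_start = integer(),
             a_ord_end = integer(), b_ord_start = integer(),
             b_ord_end = integer(), stringsAsFactors = FALSE)
}

empty_pair_frame <- function() {
  data.frame(gene_a = character(), gene_b = character(),
             contig_a = character(), a_ord = integer(),
             contig_b = character(), b_ord = integer(),
             block_id = integer(), stringsAsFactors = FALSE)
}

#' @export
print.synteny_blocks <- function(x, ...) {
  cat("synteny_blocks: ", nrow(x$blocks), " block(s) covering ",
      sum(x$blocks$length), " of ", nrow(x$pairs), " ortholog pairs\n",
      sep = "")
  invisible(x)
}

#' Synteny-conservation statistics
#'
#' \code{synteny_fraction} is the number of syntenous orthologs (pairs placed
#' in blocks) divided by the total number of ortholog pairs;
#' \code{mean_block_length} is the average number of gene pairs per block
#' (NA when there are no blocks).
#'
#' @param blocks A \code{synteny_blocks} object.
#' @param orthomap The \code{ortholog_map} the blocks were derived from.
#' @return List with \code{n_syntenous}, \code{synteny_fraction},
#'   \code{mean_block_length}, \code{n_blocks}.
#' @export
synteny_metrics <- function(blocks, orthomap) {
  n_pairs <- nrow(orthomap$pairs)
  n_synt <- sum(blocks$blocks$length)
  n_blocks <- nrow(blocks$blocks)
  list(n_syntenous = as.integer(n_synt),
       synteny_fraction = if (n_pairs > 0L) n_synt / n_pairs else 0,
       mean_block_length = if (n_blocks > 0L) n_synt / n_blocks else NA_real_,
       n_blocks = n_blocks)
}
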