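#' Classify annotation evidence into confidence tiers
#'
#' Implements a four-tier manual-curation scheme for functional annotations
#' of predicted proteins, combining domain-database (TIGRFAM/Pfam-style) and
#' nr-style sequence hits:
#' \describe{
#'   \item{specific}{a specific-function domain hit with e-value at or below
#'     \code{specific_evalue} and coverage above \code{specific_cov}.}
#'   \item{putative}{a domain hit at or below \code{putative_evalue} with
#'     coverage at least \code{putative_cov} that falls short of specific, or
#'     a domain hit meeting the specific thresholds but conveying only
#'     general functional information.}
#'   \item{probable}{an nr hit with identity above \code{probable_pident}
#'     percent over coverage above \code{probable_cov}.}
#'   \item{hypothetical}{anything else.}
#' }
#' Precedence is specific > putative > probable > hypothetical. The
#' thresholds are read monotonically (evidence at least this strong), so
#' strengthening any piece of evidence can never lower the tier.
#'
#' @param evidence data.frame with columns \code{source}
#'   (\code{"domain_db"} or \code{"nr"}), \code{evalue}, \code{coverage}
#'   (fraction of the protein matched, 0-1), \code{pct_identity} (nr hits),
#'   and optional logical \code{general} marking domain hits that give only
#'   general functional information. May have zero rows.
#' @param gene_id Gene identifier carried into the call.
#' @param specific_evalue,specific_cov Specific-tier thresholds (1e-10, 0.70).
#' @param putative_evalue,putative_cov Putative-tier thresholds (1e-4, 0.50).
#' @param probable_pident,probable_cov Probable-tier thresholds (30, 0.70).
#' @return List with \code{gene_id} and \code{tier} (one of
#'   \code{"specific"}, \code{"putative"}, \code{"probable"},
#'   \code{"hypothetical"}).
#' @export
classify_tier <- function(evidence, gene_id = NA_character_,
                          specific_evalue = 1e-10, specific_cov = 0.70,
                          putative_evalue = 1e-4, putative_cov = 0.50,
                          probable_pident = 30, probable_cov = 0.70) {
  ev <- as.data.frame(evidence)
  if (!nrow(ev))
    return(list(gene_id = gene_id, tier = "hypothetical"))
  if (is.null(ev$general)) ev$general <- FALSE
  ev$general[is.na(ev$general)] <- FALSE
  dom <- ev[ev$source == "domain_db", , drop = FALSE]
  nr <- ev[ev$source == "nr", , drop = FALSE]
  specific <- nrow(dom) && any(!dom$general & dom$evalue <= specific_evalue &
                                 dom$coverage > specific_cov)
  putative <- nrow(dom) && any(dom$evalue <= putative_evalue &
                                 dom$coverage >= putative_cov)
  probable <- nrow(nr) && any(!is.na(nr$pct_identity) &
                                nr$pct_identity > probable_pident &
                                nr$coverage > probable_cov)
  tier <- if (specific) "specific"
  else if (putative) "putative"
  else if (probable) "probable"
  else "hypothetical"
  list(gene_id = gene_id, tier = tier)
}

#' Scan a protein for approximate motif matches
#'
#' Slides a window of the motif length along the protein and reports every
#' position where the Hamming distance to the pattern is at most
#' \code{max_mismatch}. Positions are 0-based, ascending. A pattern longer
#' than the protein yields an empty result, not an error.
#'
#' @param protein_seq Non-empty amino acid string.
#' @param pattern Motif pattern (plain residue string, length >= 4).
#' @param max_mismatch Maximum mismatches tolerated (default 0); must be
#'   smaller than the pattern length.
#' @return data.frame with columns \code{position} (0-based) and
#'   \code{mismatches}.
#' @export
scan_motif <- function(protein_seq, pattern, max_mismatch = 0L) {
  if (!nchar(protein_seq)) stop("empty protein sequence")
  k <- nchar(pattern)
  if (k < 4L) stop("motif pattern must be at least 4 residues")
  if (max_mismatch >= k) stop("max_mismatch must be below the pattern length")
  n <- nchar(protein_seq)
  empty <- data.frame(position = integer(), mismatches = integer())
  if (k > n) return(empty)
  s <- strsplit(toupper(protein_seq), "")[[1L]]
  p <- strsplit(toupper(pattern), "")[[1L]]
  # mismatch count per window via one vectorized pass per pattern position
  mism <- integer(n - k + 1L)
  for (j in seq_len(k)) mism <- mism + (s[seq_len(n - k + 1L) + j - 1L] != p[j])
  hit <- which(mism <= max_mismatch)
  if (!length(hit)) return(empty)
  data.frame(position = hit - 1L, mismatches = mism[hit])
}

#' Check a protein for a type I copper-binding site
#'
#' The type I (blue) copper site of cupredoxin-fold proteins such as
#' sulfocyanin and rusticyanin is coordinated by two histidines, one
#' cysteine and one methionine in the order H...C...H...M along the
#' sequence. The check scans left to right for the first placement of
#' those four residues whose inter-residue spacings fall inside the given
#' windows; defaults follow canonical cupredoxin architecture.
#'
#' @param protein_seq Amino acid string.
#' @param spacing List of inter-residue spacing windows (min/max residue
#'   offsets): \code{h1_c} first His to Cys, \code{c_h2} Cys to second His,
#'   \code{h2_m} second His to Met.
#' @return List with \code{found} (logical) and \code{positions} (named
#'   integer vector of 1-based positions for H1, C, H2, M; NA when absent).
#' @export
check_type1_copper_site <- function(protein_seq,
                                    spacing = list(h1_c = c(20L, 60L),
                                                   c_h2 = c(1L, 10L),
                                                   h2_m = c(1L, 15L))) {
  s <- strsplit(toupper(protein_seq), "")[[1L]]
  hpos <- which(s == "H"); cpos <- which(s == "C"); mpos <- which(s == "M")
  not_found <- list(found = FALSE,
                    positions = c(H1 = NA_integer_, C = NA_integer_,
                                  H2 = NA_integer_, M = NA_integer_))
  if (!length(hpos) || !length(cpos) || !length(mpos)) return(not_found)
  for (h1 in hpos) {
    cs <- cpos[cpos - h1 >= spacing$h1_c[1L] & cpos - h1 <= spacing$h1_c[2L]]
    for (cc in cs) {
      h2s <- hpos[hpos - cc >= spacing$c_h2[1L] & hpos - cc <= spacing$c_h2[2L]]
      for (h2 in h2s) {
        ms <- mpos[mpos - h2 >= spacing$h2_m[1L] & mpos - h2 <= spacing$h2_m[2L]]
        if (length(ms)) {
          return(list(found = TRUE,
                      positions = c(H1 = h1, C = cc, H2 = h2, M = ms[1L])))
        }
      }
    }
  }
  not_found
}

#' Built-in diagnostic motif table
#'
#' Ships the sulfocyanin motif FNFNGTS (diagnostic of the blue-copper
#' proteins of iron-oxidizing Ferroplasma-like archaea) and the aerobic
#' form II carbon monoxide dehydrogenase active-site motif AYRGAGR. The
#' rusticyanin-specific motifs are not included; supply them via a custom
#' motif table. Default mismatch tolerance is 1, since diagnostic motifs are
#' imperfectly conserved across lineages.
#'
#' @return data.frame with columns \code{motif_id}, \code{pattern},
#'   \code{max_mismatch}.
#' @export
builtin_motifs <- function() {
  data.frame(
    motif_id = c("sulfocyanin_FNFNGTS", "codh_form2_active_site"),
    pattern = c("FNFNGTS", "AYRGAGR"),
    max_mismatch = c(1L, 1L),
    stringsAsFactors = FALSE)
}

#' Scan a protein set against a motif table
#'
#' @param proteins Named character vector of protein sequences.
#' @param motif_table data.frame with \code{motif_id}, \code{pattern},
#'   \code{max_mismatch} (default [builtin_motifs()]).
#' @return data.frame with one row per match: \code{gene_id},
#'   \code{motif_id}, \code{position} (0-based), \code{mismatches}.
#' @export
scan_motif_table <- function(proteins, motif_table = builtin_motifs()) {
  out <- list()
  for (i in seq_len(nrow(motif_table))) {
    for (g in names(proteins)) {
      m <- scan_motif(proteins[[g]], motif_table$pattern[i],
                      motif_table$max_mismatch[i])
      if (nrow(m))
        out[[length(out) + 1L]] <-
          cbind(data.frame(gene_id = g, motif_id = motif_table$motif_id[i],
                           stringsAsFactors = FALSE), m)
    }
  }
  if (!length(out))
    return(data.frame(gene_id = character(), motif_id = character(),
                      position = integer(), mismatches = integer()))
  do.call(rbind, out)
}
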