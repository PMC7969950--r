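#' Scan a protein sequence for the LIR core consensus
#'
#' Finds every occurrence of the LC3-interacting-region (LIR) core
#' consensus \code{[WFY]xx[ILV]} — an aromatic residue, two arbitrary
#' residues and an aliphatic hydrophobic residue, the two anchors of
#' Atg8-family binding. Hits are reported in the hexamer convention of
#' LIR tables: the 4-residue core preceded by its two upstream flanking
#' residues, with 1-based inclusive coordinates, so the aromatic anchor
#' sits at hexamer position 3 and the hydrophobic anchor at position 6.
#' Overlapping matches are all reported, ordered by start. A core within
#' two residues of the N-terminus is reported with a truncated flank (the
#' nominal coordinates keep \code{end = start + 5}, so \code{start} may be
#' 0 or -1).
#'
#' Only the core consensus is applied; no position-specific scoring or
#' disorder filtering. Scanning a full-length sequence therefore returns
#' every consensus occurrence, typically a superset of curated LIR
#' candidates.
#'
#' @param sequence Protein sequence, uppercase one-letter codes (the 20
#'   standard residues plus X).
#' @param seq_id Identifier copied into the output.
#'
#' @return Data frame with columns \code{seq_id}, \code{start}, \code{end}
#'   (hexamer coordinates, 1-based inclusive), \code{hexamer},
#'   \code{core}, \code{aromatic} and \code{hydrophobic}; zero rows for an
#'   empty sequence.
#' @export
#' @examples
#' lir_scan("KEYAQV")        # one hit, core YAQV
#' lir_scan("QALSEF")        # no consensus hit
lir_scan <- function(sequence, seq_id = "seq") {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  empty <- data.frame(seq_id = character(), start = integer(),
                      end = integer(), hexamer = character(),
                      core = character(), aromatic = character(),
                      hydrophobic = character(), stringsAsFactors = FALSE)
  if (nchar(sequence) == 0L) return(empty)
  if (grepl("[^ACDEFGHIKLMNPQRSTVWYX]", sequence)) {
    stop("sequence contains characters outside the amino-acid alphabet ",
         "(20 standard codes plus X)", call. = FALSE)
  }
  # lookahead so overlapping cores are all found
  m <- gregexpr("(?=[WFY]..[ILV])", sequence, perl = TRUE)[[1L]]
  if (m[1L] == -1L) return(empty)
  core_starts <- as.integer(m)
  rows <- lapply(core_starts, function(cs) {
    start <- cs - 2L
    end <- cs + 3L
    hexamer <- substr(sequence, max(1L, start), end)
    data.frame(seq_id = seq_id, start = start, end = end,
               hexamer = hexamer,
               core = substr(sequence, cs, cs + 3L),
               aromatic = substr(sequence, cs, cs),
               hydrophobic = substr(sequence, cs + 3L, cs + 3L),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Check candidate hexamers against the LIR core consensus
#'
#' For each 6-residue candidate, reports whether positions 3--6 match the
#' core consensus \code{[WFY]xx[ILV]}. This is the check under which the
#' six CTNNA1 candidate regions (see \code{\link{ctnna1_lir_candidates}})
#' all match, while the experimentally mapped C-terminal LIR
#' \code{"QALSEF"} does not — its anchors fall outside the consensus
#' positions.
#'
#' @param hexamers Character vector of candidates, each exactly 6
#'   residues.
#'
#' @return Data frame with \code{hexamer}, \code{core} (positions 3--6)
#'   and logical \code{matches}.
#' @export
#' @examples
#' check_lir_candidates(c("KEYAQV", "QALSEF"))
check_lir_candidates <- function(hexamers) {
  stopifnot(is.character(hexamers), length(hexamers) >= 1L)
  bad <- nchar(hexamers) != 6L
  if (any(bad)) {
    stop("candidates must be exactly 6 residues; offending: ",
         paste(hexamers[bad], collapse = ", "), call. = FALSE)
  }
  data.frame(hexamer = hexamers,
             core = substr(hexamers, 3L, 6L),
             matches = grepl("^..[WFY]..[ILV]$", hexamers),
             stringsAsFactors = FALSE)
}

#' The six CTNNA1 candidate LIR hexamers
#'
#' The consensus-derived putative LIR regions of human alpha-E-catenin
#' (CTNNA1), in the hexamer reporting convention (two flanking residues
#' plus the 4-residue core), with 1-based start/end coordinates in the
#' full-length protein. The experimentally mapped C-terminal LIR
#' (895 QALSEF 900) is not among them because it does not follow the core
#' consensus.
#'
#' @return Data frame with \code{start}, \code{end} and \code{hexamer}.
#' @export
ctnna1_lir_candidates <- function() {
  data.frame(start = c(146L, 175L, 243L, 417L, 509L, 617L),
             end = c(151L, 180L, 248L, 422L, 514L, 622L),
             hexamer = c("DVYKLL", "IQYKAL", "LIYKQL",
                         "KEYAQV", "DDFLAV", "LVYDGI"),
             stringsAsFactors = FALSE)
}

#' Scan every record of a protein FASTA file
#'
#' Reads single- or multi-record FASTA via \pkg{Biostrings} and applies
#' \code{\link{lir_scan}} to each sequence.
#'
#' @param path FASTA file path.
#' @return Data frame of hits across all records (zero rows if none).
#' @export
lir_scan_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  hits <- lapply(seq_along(seqs), function(i) {
    lir_scan(toupper(as.character(seqs[[i]])), seq_id = names(seqs)[i])
  })
  do.call(rbind, hits)
}

#' Write LIR hits to TSV
#'
#' Columns \code{seq_id, start, end, hexamer, core}.
#'
#' @param hits Data frame from \code{\link{lir_scan}} or
#'   \code{\link{lir_scan_fasta}}.
#' @param path Output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_lir_hits <- function(hits, path) {
  utils::write.table(hits[, c("seq_id", "start", "end", "hexamer", "core")],
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
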