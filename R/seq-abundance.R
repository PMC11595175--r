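# Histone variant sequence comparison and abundance-weighted isoform
# statistics.
#
# Pairwise global alignment (match +1, mismatch 0, linear gap -1) is done by
# Biostrings; identity, substitution listing and the abundance weighting are
# computed here.  Residue numbering follows mature-protein convention (the
# initiator methionine, if present in the input, is position 0 relative to
# the numbering used for sites like S40 or K118).

align_pair <- function(seq_a, seq_b, match = 1, mismatch = 0, gap = 1) {
  if (!nchar(seq_a) || !nchar(seq_b)) stop("sequences must be non-empty")
  letters_ab <- unique(strsplit(paste0(seq_a, seq_b), "")[[1]])
  mat <- matrix(mismatch, length(letters_ab), length(letters_ab),
                dimnames = list(letters_ab, letters_ab))
  diag(mat) <- match
  aln <- Biostrings::pairwiseAlignment(
    seq_a, seq_b, type = "global", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = gap
  )
  list(
    a = strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]],
    b = strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]],
    score = Biostrings::score(aln)
  )
}

#' Percent identity of two sequences under global alignment
#'
#' Needleman-Wunsch global alignment with match +1, mismatch 0, linear gap
#' penalty -1.  Identity is reported with two denominator conventions:
#' alignment length (gap columns counted; the primary value) and the shorter
#' ungapped sequence length.
#'
#' @param seq_a,seq_b character scalars (one-letter amino acids).
#' @return list with `identity_pct` (alignment-length denominator),
#'   `identity_pct_shorter`, `matches`, `alignment_length`, `substitutions`
#'   (count of mismatched aligned columns), `indels` (gap columns).
#' @export
percent_identity <- function(seq_a, seq_b) {
  al <- align_pair(seq_a, seq_b)
  gaps <- al$a == "-" | al$b == "-"
  matches <- sum(!gaps & al$a == al$b)
  subs <- sum(!gaps & al$a != al$b)
  list(
    identity_pct = 100 * matches / length(al$a),
    identity_pct_shorter = 100 * matches / min(nchar(seq_a), nchar(seq_b)),
    matches = matches,
    alignment_length = length(al$a),
    substitutions = subs,
    indels = sum(gaps)
  )
}

#' List substitutions and indels between two aligned sequences
#'
#' Positions are reported in the reference (first) sequence's numbering plus
#' `offset` (use `offset = -1` when the reference still carries its initiator
#' methionine but sites are counted in mature numbering).
#'
#' @param seq_ref,seq_alt character scalars; `seq_ref` provides the numbering.
#' @param offset added to reference positions (default 0).
#' @return data.frame with columns `position`, `ref`, `alt`, `type`
#'   (`"substitution"`, `"deletion"` = gap in alt, `"insertion"` = gap in ref;
#'   insertions are numbered by the preceding reference position).
#' @export
list_substitutions <- function(seq_ref, seq_alt, offset = 0) {
  al <- align_pair(seq_ref, seq_alt)
  pos_ref <- cumsum(al$a != "-")
  rows <- which(al$a != al$b)
  if (!length(rows)) {
    return(data.frame(position = integer(), ref = character(),
                      alt = character(), type = character()))
  }
  data.frame(
    position = pos_ref[rows] + offset,
    ref = al$a[rows],
    alt = al$b[rows],
    type = ifelse(al$a[rows] == "-", "insertion",
                  ifelse(al$b[rows] == "-", "deletion", "substitution"))
  )
}

#' Read a FASTA file of protein sequences
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta_sequences <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Read a protein-abundance isoform table
#'
#' Tab-separated table with columns `id`, `sequence`, `abundance` (ppm-like,
#' unitless, non-negative) in the style of PaxDB exports.
#'
#' @param path TSV file.
#' @return data.frame with those columns.
#' @export
read_isoform_table <- function(path) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  needed <- c("id", "sequence", "abundance")
  if (!all(needed %in% names(tb))) {
    stop("isoform table must have columns: ", paste(needed, collapse = ", "))
  }
  if (any(tb$abundance < 0)) stop("abundances must be non-negative")
  bad <- grepl("[^ACDEFGHIKLMNPQRSTVWY]", tb$sequence)
  if (any(bad)) stop("non amino-acid letters in sequence of ", tb$id[bad][1])
  tb
}

#' Abundance-weighted fraction of isoforms carrying a residue at a position
#'
#' Each isoform sequence is mapped onto the reference numbering by global
#' alignment to `reference`; the result is the abundance-weighted fraction of
#' records whose residue at `position` (reference numbering) equals
#' `residue`.
#'
#' @param records data.frame from [read_isoform_table()].
#' @param position integer position in reference numbering.
#' @param residue one-letter residue.
#' @param reference reference sequence; defaults to the most abundant record.
#' @return fraction in [0, 1].
#' @export
residue_fraction <- function(records, position, residue, reference = NULL) {
  stopifnot(nrow(records) >= 1)
  if (is.null(reference)) {
    reference <- records$sequence[which.max(records$abundance)]
  }
  if (position < 1 || position > nchar(reference)) {
    stop("position ", position, " outside the reference sequence (1-",
         nchar(reference), ")")
  }
  at_pos <- vapply(records$sequence, function(s) {
    al <- align_pair(reference, s)
    pos_ref <- cumsum(al$a != "-")
    col <- match(position, pos_ref)
    if (is.na(col)) NA_character_ else al$b[col]
  }, character(1), USE.NAMES = FALSE)
  if (anyNA(at_pos)) stop("an isoform does not cover reference position ", position)
  total <- sum(records$abundance)
  if (total == 0) stop("total abundance is zero")
  sum(records$abundance[at_pos == residue]) / total
}

#' Packaged H2A variant sequences
#'
#' Returns the packaged mature-protein sequences of canonical H2A isoform 2
#' (the H2AC4/H2AC8 product) and H2A.J used throughout the package's worked
#' examples.  The FASTA also ships the C-tail motifs.
#'
#' @return named character vector of sequences.
#' @export
h2a_sequences <- function() {
  read_fasta_sequences(system.file("extdata", "h2a_variants.fasta",
                                   package = "nuctraj", mustWork = TRUE))
}
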