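#' In-silico tryptic digestion
#'
#' Cleaves a protein sequence after every lysine (K) or arginine (R) unless
#' the next residue is proline (P), with zero missed cleavages. Peptides are
#' returned in N-to-C order and tile the protein exactly: concatenating
#' them reconstructs the input.
#'
#' @param sequence a single amino-acid string over the 20 standard one-letter
#'   codes.
#' @return Character vector of peptides.
#' @examples
#' digestProtein("MKWVTFRPK")  # R-P bond is not cleaved
#' @export
digestProtein <- function(sequence) {
  stopIfNot(is.character(sequence) && length(sequence) == 1L &&
              nzchar(sequence), "sequence must be a non-empty string")
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% AA_STANDARD)
  if (length(bad))
    stop("non-standard residue '", chars[bad[1]], "' at position ", bad[1],
         call. = FALSE)
  n <- length(chars)
  isKR <- chars == "K" | chars == "R"
  nextP <- c(chars[-1] == "P", FALSE)
  ends <- which(isKR & !nextP)
  if (!length(ends) || ends[length(ends)] != n) ends <- c(ends, n)
  starts <- c(1L, ends[-length(ends)] + 1L)
  substring(sequence, starts, ends)
}

#' Filter peptides to the detectable length range
#'
#' Mass spectrometry reliably identifies tryptic peptides of intermediate
#' length; the quantification keeps peptides of 7-40 residues (inclusive).
#'
#' @param peptides character vector of peptide sequences.
#' @param minLen,maxLen inclusive length bounds (defaults 7 and 40).
#' @return The in-range subset, order preserved.
#' @export
peptideFilter <- function(peptides, minLen = 7, maxLen = 40) {
  if (minLen > maxLen)
    stop("minLen must not exceed maxLen", call. = FALSE)
  len <- nchar(peptides)
  peptides[len >= minLen & len <= maxLen]
}

#' Per-protein length correction factor
#'
#' The detectable length of a protein is the summed length of its in-range
#' tryptic peptides; the correction factor is its reciprocal. It converts a
#' length-weighted PSM tally into a per-protein, molar-like quantity.
#'
#' @param inRange character vector of in-range peptides for one protein.
#' @return list with `detectableLength` and `factor = 1/detectableLength`.
#' @export
correctionFactor <- function(inRange) {
  if (!length(inRange))
    stop("no in-range peptides: correction factor undefined", call. = FALSE)
  dl <- sum(nchar(inRange))
  list(detectableLength = dl, factor = 1 / dl)
}

#' Digest a sequence collection into a peptide table
#'
#' @param sequences a named character vector or [Biostrings::AAStringSet].
#' @param minLen,maxLen detectable length range passed to [peptideFilter()].
#' @return data.frame with columns `protein`, `peptide`, `length`,
#'   `inRange`; peptides appear in N-to-C order within each protein.
#' @export
peptideTable <- function(sequences, minLen = 7, maxLen = 40) {
  if (is(sequences, "AAStringSet")) sequences <- as.character(sequences)
  stopIfNot(!is.null(names(sequences)) && all(nzchar(names(sequences))),
            "sequences must be named by protein id")
  peps <- lapply(sequences, digestProtein)
  out <- data.frame(
    protein = rep(names(peps), lengths(peps)),
    peptide = unlist(peps, use.names = FALSE),
    stringsAsFactors = FALSE)
  out$length <- nchar(out$peptide)
  out$inRange <- out$length >= minLen & out$length <= maxLen
  rownames(out) <- NULL
  out
}

#' Detectable lengths for a sequence collection
#'
#' @inheritParams peptideTable
#' @return Named numeric vector of per-protein detectable lengths (sum of
#'   in-range peptide lengths). Proteins with no in-range peptide get 0 and
#'   trigger a warning; they are excluded from ppm quantification.
#' @export
detectableLengths <- function(sequences, minLen = 7, maxLen = 40) {
  tab <- peptideTable(sequences, minLen, maxLen)
  ids <- unique(tab$protein)
  dl <- vapply(split(tab$length[tab$inRange], tab$protein[tab$inRange]),
               sum, numeric(1))
  out <- setNames(rep(0, length(ids)), ids)
  out[names(dl)] <- dl
  if (any(out == 0))
    warning(sum(out == 0), " protein(s) have no in-range peptide; ",
            "correction factor undefined")
  out
}
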