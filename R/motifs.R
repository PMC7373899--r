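# IUPAC consensus scanning for GAS and ISRE promoter elements.
#
# Matching uses Biostrings with the pattern's IUPAC ambiguities expanded and
# the subject taken literally, so an N in the subject is matched only by an N
# (or other code covering all four bases) in the pattern. All overlapping
# matches are reported; reverse-strand hits are reported in forward
# coordinates (0-based, half-open).

#' Consensus patterns of the two interferon-responsive promoter elements
#' @return named character vector: GAS `TTNCNNNAA`, ISRE `TTTCNNTTYY`.
#' @export
motif_patterns <- function() c(GAS = "TTNCNNNAA", ISRE = "TTTCNNTTYY")

.iupac_ok <- function(s) grepl("^[ACGTRYSWKMBDHVN]+$", s)

#' Scan a sequence for an IUPAC consensus pattern
#'
#' @param sequence character DNA sequence over A, C, G, T, N (or a
#'   `Biostrings::DNAString`).
#' @param pattern IUPAC consensus (length >= 4).
#' @param both_strands scan the reverse strand as well (default TRUE).
#' @param name pattern name recorded in the output.
#' @return data.frame with 0-based half-open coordinates: `start`, `end`,
#'   `strand` (+/-), `match` (forward-strand subsequence), `pattern`.
#' @export
scan_motif <- function(sequence, pattern, both_strands = TRUE,
                       name = deparse(substitute(pattern))) {
  pattern <- toupper(as.character(pattern))
  if (nchar(pattern) < 4 || !.iupac_ok(pattern))
    stop("pattern must be a legal IUPAC string of length >= 4")
  seq_chr <- toupper(as.character(sequence))
  bad <- regexpr("[^ACGTN]", seq_chr)
  if (bad > 0)
    stop("illegal character '", substr(seq_chr, bad, bad),
         "' in sequence at position ", bad)
  if (nchar(seq_chr) < nchar(pattern))
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), match = character(0),
                      pattern = character(0)))
  subject <- Biostrings::DNAString(seq_chr)
  pat <- Biostrings::DNAString(pattern)
  hit_df <- function(p, strand) {
    m <- Biostrings::matchPattern(p, subject, fixed = "subject")
    if (length(m) == 0)
      return(NULL)
    data.frame(start = Biostrings::start(m) - 1L,
               end = Biostrings::end(m),
               strand = strand,
               match = as.character(m),
               pattern = name, stringsAsFactors = FALSE)
  }
  out <- hit_df(pat, "+")
  if (both_strands)
    out <- rbind(out, hit_df(Biostrings::reverseComplement(pat), "-"))
  if (is.null(out))
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), match = character(0),
                      pattern = character(0)))
  out[order(out$start, out$strand), , drop = FALSE]
}

#' Classify a promoter by its GAS/ISRE content near the TSS
#'
#' @param hits_gas,hits_isre hit tables from [scan_motif()] in promoter
#'   coordinates (TSS at position `tss`).
#' @param window length-2 vector of positions relative to the TSS defining
#'   the classification window (default c(-1250, 1750), the scanned region).
#' @param tss TSS position within the promoter coordinates (default 1250).
#' @return one of `"GAS_only"`, `"ISRE_only"`, `"both"`, `"none"`.
#' @export
classify_promoter <- function(hits_gas, hits_isre,
                              window = c(-1250, 1750), tss = 1250) {
  inside <- function(h) {
    if (nrow(h) == 0) return(FALSE)
    rel <- h$start - tss
    any(rel >= window[1] & rel <= window[2])
  }
  g <- inside(hits_gas); i <- inside(hits_isre)
  if (g && i) "both" else if (g) "GAS_only" else if (i) "ISRE_only" else "none"
}

#' Scan promoter sequences from a FASTA file
#'
#' @param fasta path to a FASTA file of promoter sequences.
#' @param patterns named IUPAC patterns (default [motif_patterns()]).
#' @param both_strands see [scan_motif()].
#' @return BED-like data.frame: `seqid`, `start`, `end`, `name`, `strand`.
#' @export
scan_promoters <- function(fasta, patterns = motif_patterns(),
                           both_strands = TRUE) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  out <- list()
  for (i in seq_along(seqs)) for (pn in names(patterns)) {
    h <- scan_motif(seqs[[i]], patterns[[pn]], both_strands, name = pn)
    if (nrow(h))
      out[[length(out) + 1]] <- data.frame(
        seqid = names(seqs)[i], start = h$start, end = h$end,
        name = pn, strand = h$strand)
  }
  if (!length(out))
    return(data.frame(seqid = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      strand = character(0)))
  do.call(rbind, out)
}
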