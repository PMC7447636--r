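#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnbinom runif setNames p.adjust median sd quantile
#' @importFrom utils read.delim write.table head
NULL

STOP_CODONS <- c("TAA", "TAG", "TGA")

# Codons that never encode a stop; used when drawing random coding sequence.
non_stop_codons <- function() {
  bases <- c("A", "C", "G", "T")
  all <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  setdiff(all, STOP_CODONS)
}

#' Translate a nucleotide sequence in frame 0 until the first stop codon
#'
#' Thin wrapper around [Biostrings::translate()] that trims the sequence to a
#' codon multiple, translates, and cuts at the first stop symbol.
#'
#' @param nt character(1), nucleotide sequence (A/C/G/T).
#' @return list with `aa` (peptide before the first stop), `hit_stop`
#'   (logical: a stop codon was reached), and `n_codons_translated`.
#' @export
translate_to_stop <- function(nt) {
  n <- nchar(nt) %/% 3L * 3L
  if (n == 0L) {
    return(list(aa = "", hit_stop = FALSE, n_codons_translated = 0L))
  }
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(nt, 1L, n)),
    no.init.codon = TRUE
  ))
  stop_at <- regexpr("*", aa, fixed = TRUE)
  if (stop_at > 0L) {
    list(aa = substr(aa, 1L, stop_at - 1L), hit_stop = TRUE,
         n_codons_translated = as.integer(stop_at))
  } else {
    list(aa = aa, hit_stop = FALSE, n_codons_translated = nchar(aa))
  }
}

reverse_complement <- function(nt) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt)))
}

# Draw a derived seed for a sub-stream, kept within 32-bit integer range.
derive_seed <- function(master, index) {
  as.integer((as.numeric(master) * 48271 + as.numeric(index) * 9973) %%
               2147483587) + 1L
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
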