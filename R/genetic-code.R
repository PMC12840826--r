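#' The standard nuclear codon table
#'
#' Named character vector mapping the 64 DNA codons to single-letter amino
#' acids, with `*` for the three stop codons.  Taken from
#' [Biostrings::GENETIC_CODE]; no alternative codon tables are supported.
#'
#' @return Named character vector of length 64.
#' @export
codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
}

# single-codon lookup; non-ACGT codons give "X"
codon_to_aa <- function(codons) {
  aa <- unname(codon_table()[codons])
  aa[is.na(aa)] <- "X"
  aa
}

#' Translate a coding sequence
#'
#' Translates an in-frame CDS with the standard nuclear genetic code.  The
#' terminal stop codon is rendered as `*` and counted as a protein position
#' (a complete 6414-nt CDS therefore yields 2138 positions).  Codons
#' containing a non-ACGT base translate to `X` with a warning; internal stop
#' codons are reported via a warning and the `internal_stops` attribute, not
#' silently truncated.
#'
#' @param cds character scalar (or `DNAString`) of length divisible by 3.
#' @return Single-letter amino-acid string; attribute `internal_stops` holds
#'   the codon indices of any stop codon before the final one.
#' @examples
#' translate_cds("ATGTTATAA")  # "ML*"
#' @export
translate_cds <- function(cds) {
  cds <- toupper(as.character(cds))
  if (length(cds) != 1L) {
    kdr_stop("`cds` must be a single sequence", "kdr_input_error")
  }
  n <- nchar(cds)
  if (n == 0L) {
    return(structure("", internal_stops = integer(0)))
  }
  if (n %% 3L != 0L) {
    kdr_stop(sprintf("CDS length %d is not a multiple of 3", n),
             "kdr_frame_error")
  }
  starts <- seq.int(1L, n, by = 3L)
  codons <- substring(cds, starts, starts + 2L)
  aa <- unname(codon_table()[codons])
  bad <- is.na(aa)
  if (any(bad)) {
    aa[bad] <- "X"
    warning(sprintf("%d codon(s) contain non-ACGT bases; translated as 'X' (codon %s)",
                    sum(bad), paste(which(bad), collapse = ", ")),
            call. = FALSE)
  }
  internal <- which(aa == "*" & seq_along(aa) < length(aa))
  if (length(internal)) {
    warning(sprintf("internal stop codon(s) at protein position(s) %s",
                    paste(internal, collapse = ", ")),
            call. = FALSE)
  }
  structure(paste(aa, collapse = ""), internal_stops = internal)
}
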