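# Independent oracles and tiny fixture builders for the test suite.

# Hard-coded standard nuclear genetic code (64 entries), written out by hand
# so translation/classification tests do not depend on the implementation's
# own codon-table source.
ORACLE_CODE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

# brute-force class oracle for a single-base codon substitution
oracle_class <- function(ref_codon, alt_codon) {
  ra <- ORACLE_CODE[[ref_codon]]
  aa <- ORACLE_CODE[[alt_codon]]
  if (aa == "*" && ra != "*") "stop_gained"
  else if (ra == "*" && aa != "*") "stop_lost"
  else if (ra == aa) "synonymous"
  else "nonsynonymous"
}

# brute-force Spearman rho via explicit mid-ranks
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# the 16-nt toy gene used across gene-model tests
toy_model <- function() {
  gene_model("toy", "AAATGGTTTCCTAAGG",
             data.frame(start = c(3L, 10L), end = c(8L, 15L)))
}

# a small random-but-valid multi-exon model for property tests
random_toy_model <- function(seed) {
  withr::with_seed(seed, {
    n_ex <- sample(2:5, 1)
    exon_len <- sample(6:30, n_ex, replace = TRUE)
    exon_len[n_ex] <- exon_len[n_ex] + (3 - sum(exon_len) %% 3) %% 3
    intron_len <- sample(5:40, n_ex - 1, replace = TRUE)
    pieces <- character(0)
    starts <- ends <- integer(n_ex)
    pos <- 0L
    for (i in seq_len(n_ex)) {
      starts[i] <- pos + 1L
      ends[i] <- pos + exon_len[i]
      pieces <- c(pieces, paste(sample(c("A", "C", "G", "T"), exon_len[i],
                                       replace = TRUE), collapse = ""))
      pos <- ends[i]
      if (i < n_ex) {
        pieces <- c(pieces, paste(sample(c("A", "C", "G", "T"), intron_len[i],
                                         replace = TRUE), collapse = ""))
        pos <- pos + intron_len[i]
      }
    }
    gene_model(paste0("rand", seed), paste(pieces, collapse = ""),
               data.frame(start = starts, end = ends))
  })
}
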