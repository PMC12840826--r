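#' Packaged VGSC benchmark fixture
#'
#' A complete, deterministic benchmark dataset for the whole pipeline: 37
#' single-nucleotide variants (31 synonymous, 6 nonsynonymous) of the
#' *Liriomyza trifolii* voltage-gated sodium channel surveyed across five
#' Hainan populations, together with a gene model, channel topology,
#' canonical-numbering map, resistance-site catalog and population
#' coordinates.
#'
#' The variant counts, region labels, codon changes and population
#' coordinates are curated survey values shipped as plain-text files under
#' `inst/extdata` (see their headers for recorded errata).  The gene model
#' is **synthetic**: the survey's exon coordinates are not public, so a
#' deterministic 13-exon gene is constructed with the reported dimensions —
#' 36,774 bp genomic, 6414 bp CDS (2138 protein positions including the
#' terminal stop), 30,360 bp of intron — with each variant's reference
#' codon planted at its reported codon index, a start ATG, terminal TAA and
#' no internal stops.  Every derived quantity (genomic variant positions,
#' classes, labels, frequencies) is recomputed from this model by the
#' package's own functions.
#'
#' @return List with elements `model` ([gene_model()]), `topology`,
#'   `canonical`, `catalog`, `variants` (tibble: `label`,
#'   `genomic_position`, `ref`, `alt`), `counts` (long tibble: `label`,
#'   `population`, `f`, `g`), `recorded` (tibble of recorded display
#'   percentages: `label`, `region`, `class`, `ref_codon`, `alt_codon`, one
#'   `<POP>_pct` column per population), `populations`, and `errata`
#'   (tibble naming cells whose recorded percentage disagrees with its own
#'   counts).
#' @examples
#' fx <- vgsc_fixture()
#' gene_lengths(fx$model)
#' @export
vgsc_fixture <- function() {
  ext <- function(f) system.file("extdata", f, package = "kdrscreen",
                                 mustWork = TRUE)
  tab <- utils::read.delim(ext("vgsc_variant_counts.tsv"), comment.char = "#",
                           check.names = FALSE, stringsAsFactors = FALSE)
  cfg <- read_topology_config(ext("vgsc_topology.yaml"))
  populations <- read_populations(ext("populations.tsv"))

  codon_index <- as.integer(gsub("[^0-9]", "", tab$snp))
  model <- fixture_gene_model(codon_index, tab$ref_codon)

  # variant genomic coordinates derived from the planted codons
  off <- codon_diff_offset(tab$ref_codon, tab$alt_codon)
  cds_pos <- (codon_index - 1L) * 3L + 1L + off
  variants <- tibble::tibble(
    label = tab$snp,
    genomic_position = cds_to_genomic(model, cds_pos),
    ref = substr(tab$ref_codon, off + 1L, off + 1L),
    alt = substr(tab$alt_codon, off + 1L, off + 1L)
  )

  pops <- populations$name
  counts <- counts_from_wide(tab, tab$snp, pops)

  recorded <- tibble::as_tibble(
    tab[c("snp", "region", "class", "ref_codon", "alt_codon",
          paste0(pops, "_pct"))]
  )
  names(recorded)[1] <- "label"

  errata <- tibble::tibble(label = "Y866Y", population = "TY",
                           recorded = 22.23, recomputed = 22.22)

  list(model = model, topology = cfg$topology, canonical = cfg$canonical,
       catalog = cfg$catalog, variants = variants, counts = counts,
       recorded = recorded, populations = populations, errata = errata)
}

# 0-based offset of the single differing position between two codons
codon_diff_offset <- function(ref_codon, alt_codon) {
  vapply(seq_along(ref_codon), function(i) {
    d <- which(strsplit(ref_codon[i], "")[[1]] != strsplit(alt_codon[i], "")[[1]])
    if (length(d) != 1L) {
      kdr_stop(sprintf("codons %s/%s differ at %d positions (expected 1)",
                       ref_codon[i], alt_codon[i], length(d)),
               "kdr_input_error")
    }
    d - 1L
  }, integer(1))
}

# Deterministic synthetic gene realising the reported dimensions.
# Exon lengths are seeded from the exon-length column of the 13 sequenced
# gene fragments (last one adjusted so the total is exactly 6414); intron
# lengths sum to 30,360 with canonical GT...AG ends.
fixture_gene_model <- function(codon_index, ref_codon) {
  exon_len <- c(215L, 188L, 236L, 713L, 565L, 610L, 697L, 796L, 225L, 301L,
                584L, 327L, 957L)
  intron_len <- c(1483L, 2575L, 1269L, 3136L, 3953L, 1201L, 3561L, 783L,
                  4062L, 3960L, 3256L, 1121L)
  stopifnot(sum(exon_len) == 6414L, sum(intron_len) == 30360L)

  n_codons <- sum(exon_len) %/% 3L   # 2138
  filler <- rep(c("GCA", "GAA", "TTG", "TCA", "AAA", "GGA", "CTG", "ATT",
                  "CCA", "GTG"),
                length.out = n_codons)
  filler[1L] <- "ATG"
  filler[n_codons] <- "TAA"
  stopifnot(all(codon_index > 1L & codon_index < n_codons),
            !anyDuplicated(codon_index))
  filler[codon_index] <- ref_codon
  cds <- paste(filler, collapse = "")

  intron_seq <- vapply(intron_len, function(L) {
    body <- strtrim(strrep("TATTTACTTTCATTTG", ceiling((L - 4L) / 16L)), L - 4L)
    paste0("GT", body, "AG")
  }, character(1))

  starts <- ends <- integer(length(exon_len))
  pieces <- character(0)
  pos <- 0L
  cds_at <- 1L
  for (i in seq_along(exon_len)) {
    starts[i] <- pos + 1L
    ends[i] <- pos + exon_len[i]
    pieces <- c(pieces, substring(cds, cds_at, cds_at + exon_len[i] - 1L))
    cds_at <- cds_at + exon_len[i]
    pos <- ends[i]
    if (i < length(exon_len)) {
      pieces <- c(pieces, intron_seq[i])
      pos <- pos + intron_len[i]
    }
  }
  gene_model("LtVGSC_synthetic", paste(pieces, collapse = ""),
             data.frame(start = starts, end = ends))
}
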