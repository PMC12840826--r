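#' Classify variants against a gene model
#'
#' Codon-aware consequence calling for single-nucleotide variants on one
#' gene.  Each exonic variant's codon is reconstructed from the assembled
#' CDS, the alternate base is substituted at the variant's codon offset
#' (single-SNP assumption: the other two positions carry the reference
#' base), and both codons are translated with the standard genetic code.
#'
#' Effect classes are `intronic`, `flanking`, `synonymous`, `nonsynonymous`,
#' `stop_gained` (alternate amino acid is a stop, reference is not) and
#' `stop_lost`.  Labels use the native residue numbering with the long form
#' for synonymous changes (`"N931N"`); [short_label()] renders the compact
#' display form (`"N931"`).  Variants falling on the first or last two bases
#' of an exon are flagged in `near_exon_boundary` (splice-disruption calling
#' is out of scope).
#'
#' @param model a [gene_model()].
#' @param variants data frame with columns `genomic_position`, `ref`, `alt`
#'   (single A/C/G/T bases, `alt != ref`, `ref` matching the model sequence).
#' @return Tibble with one row per variant: the input columns plus `region`,
#'   `cds_position`, `codon_index`, `codon_offset`, `ref_codon`, `alt_codon`,
#'   `ref_aa`, `alt_aa`, `effect_class`, `label`, `nucleotide_alteration`
#'   and `near_exon_boundary`.
#' @examples
#' gm <- gene_model("toy", "AAATGGTTTCCTAAGG",
#'                  data.frame(start = c(3, 10), end = c(8, 15)))
#' annotate_variants(gm, data.frame(genomic_position = 7, ref = "T", alt = "A"))
#' @export
annotate_variants <- function(model, variants) {
  validate_gene_model(model)
  variants <- as.data.frame(variants)
  need <- c("genomic_position", "ref", "alt")
  if (!all(need %in% names(variants))) {
    kdr_stop("`variants` needs columns genomic_position, ref, alt",
             "kdr_input_error")
  }
  if (nrow(variants) == 0L) {
    return(empty_effects())
  }
  pos <- as.integer(variants$genomic_position)
  ref <- toupper(as.character(variants$ref))
  alt <- toupper(as.character(variants$alt))
  if (any(nchar(ref) != 1L) || any(nchar(alt) != 1L) ||
      any(!ref %in% c("A", "C", "G", "T")) || any(!alt %in% c("A", "C", "G", "T"))) {
    kdr_stop("ref and alt must be single A/C/G/T bases (SNPs only)",
             "kdr_input_error")
  }
  degen <- alt == ref
  if (any(degen)) {
    kdr_stop(sprintf("degenerate variant (alt equals ref) at position %s",
                     paste(pos[degen], collapse = ", ")),
             "kdr_degenerate_variant")
  }
  seen <- substring(model$sequence, pos, pos)
  bad <- seen != ref
  if (any(bad)) {
    k <- which(bad)[1L]
    kdr_stop(sprintf("reference mismatch at genomic position %d: variant ref '%s' but gene model has '%s'",
                     pos[k], ref[k], seen[k]),
             "kdr_ref_mismatch")
  }

  map <- genomic_to_cds(model, pos)
  cds <- assemble_cds(model)

  ref_codon <- rep(NA_character_, nrow(map))
  alt_codon <- rep(NA_character_, nrow(map))
  exonic <- map$region == "exonic"
  if (any(exonic)) {
    cstart <- (map$codon_index[exonic] - 1L) * 3L + 1L
    ref_codon[exonic] <- substring(cds, cstart, cstart + 2L)
    alt_codon[exonic] <- mapply(function(cod, o, a) {
      substr(cod, o + 1L, o + 1L) <- a
      cod
    }, ref_codon[exonic], map$codon_offset[exonic], alt[exonic],
    USE.NAMES = FALSE)
  }

  ref_aa <- ifelse(is.na(ref_codon), NA_character_, codon_to_aa(ref_codon))
  alt_aa <- ifelse(is.na(alt_codon), NA_character_, codon_to_aa(alt_codon))

  effect_class <- map$region  # intronic / flanking carried through
  effect_class[exonic] <- classify_codon_change(ref_aa[exonic], alt_aa[exonic])

  label <- rep(NA_character_, nrow(map))
  label[exonic] <- paste0(ref_aa[exonic], map$codon_index[exonic], alt_aa[exonic])

  alteration <- rep(NA_character_, nrow(map))
  alteration[exonic] <- paste(ref_codon[exonic], ">", alt_codon[exonic])

  near <- near_exon_boundary(model, pos, exonic)

  out <- tibble::tibble(
    genomic_position = pos, ref = ref, alt = alt,
    region = map$region,
    cds_position = map$cds_position,
    codon_index = map$codon_index,
    codon_offset = map$codon_offset,
    ref_codon = ref_codon, alt_codon = alt_codon,
    ref_aa = ref_aa, alt_aa = alt_aa,
    effect_class = effect_class,
    label = label,
    nucleotide_alteration = alteration,
    near_exon_boundary = near
  )
  if ("id" %in% names(variants)) out <- tibble::add_column(out, id = variants$id, .before = 1)
  out
}

empty_effects <- function() {
  tibble::tibble(
    genomic_position = integer(0), ref = character(0), alt = character(0),
    region = character(0), cds_position = integer(0),
    codon_index = integer(0), codon_offset = integer(0),
    ref_codon = character(0), alt_codon = character(0),
    ref_aa = character(0), alt_aa = character(0),
    effect_class = character(0), label = character(0),
    nucleotide_alteration = character(0), near_exon_boundary = logical(0)
  )
}

classify_codon_change <- function(ref_aa, alt_aa) {
  ifelse(alt_aa == "*" & ref_aa != "*", "stop_gained",
  ifelse(ref_aa == "*" & alt_aa != "*", "stop_lost",
  ifelse(ref_aa == alt_aa, "synonymous", "nonsynonymous")))
}

near_exon_boundary <- function(model, pos, exonic) {
  ex <- model$exons
  out <- rep(FALSE, length(pos))
  if (any(exonic)) {
    i <- findInterval(pos[exonic], ex$start)
    out[exonic] <- (pos[exonic] - ex$start[i] < 2L) |
      (ex$end[i] - pos[exonic] < 2L)
  }
  out
}

#' Compact display label for an annotated variant
#'
#' Synonymous variants are conventionally displayed without the repeated
#' amino acid (`"N931"`); nonsynonymous and stop changes keep the long form.
#'
#' @param effects tibble from [annotate_variants()] (or its `label` /
#'   `effect_class` columns as vectors via `label=` and `effect_class=`).
#' @return Character vector of display labels.
#' @export
short_label <- function(effects) {
  ifelse(effects$effect_class == "synonymous",
         sub("([A-Z*])$", "", effects$label),
         effects$label)
}

#' Partition annotated effects by class
#'
#' Splits an effect table into nonsynonymous, synonymous, and everything
#' else (intronic, flanking, and stop changes — the latter never enter the
#' dN/dS count ratio).
#'
#' @param effects tibble from [annotate_variants()].
#' @return List with tibbles `nonsynonymous`, `synonymous`, `other`.
#' @export
partition_effects <- function(effects) {
  cls <- effects$effect_class
  list(nonsynonymous = effects[cls == "nonsynonymous", , drop = FALSE],
       synonymous    = effects[cls == "synonymous", , drop = FALSE],
       other         = effects[!cls %in% c("nonsynonymous", "synonymous"), ,
                               drop = FALSE])
}
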