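#' Construct and validate a gene model
#'
#' A gene model couples the genomic sequence of a coding gene (sense strand,
#' plus-strand orientation only) with its ordered exon intervals.  All
#' user-facing coordinates in this package are 1-based inclusive; BED input
#' is converted at the I/O boundary (see [read_gene_model()]).
#'
#' @param gene_id character scalar identifier.
#' @param sequence genomic DNA as a character scalar or `DNAString`
#'   (A/C/G/T/N).
#' @param exons data frame with integer columns `start` and `end`, 1-based
#'   inclusive, strictly increasing and non-overlapping, all within the
#'   sequence; the concatenated exon length must be a positive multiple of 3.
#' @return An object of class `gene_model` with elements `gene_id`,
#'   `sequence` and `exons`.
#' @examples
#' gm <- gene_model("toy", "AAATGGTTTCCTAAGG",
#'                  data.frame(start = c(3, 10), end = c(8, 15)))
#' assemble_cds(gm)
#' @export
gene_model <- function(gene_id, sequence, exons) {
  sequence <- toupper(as.character(sequence))
  exons <- as.data.frame(exons)
  if (!all(c("start", "end") %in% names(exons))) {
    kdr_stop("`exons` needs columns `start` and `end`", "kdr_input_error")
  }
  exons <- data.frame(start = as.integer(exons$start),
                      end   = as.integer(exons$end))
  obj <- structure(list(gene_id = as.character(gene_id),
                        sequence = sequence,
                        exons = exons),
                   class = "gene_model")
  validate_gene_model(obj)
}

#' Validate a gene model's invariants
#'
#' Checks the alphabet, exon bounds and ordering, and the reading frame
#' (total exonic length a positive multiple of 3).  Conservation of length
#' (exons + introns = genomic length) holds by construction and is exposed
#' through [gene_lengths()].
#'
#' @param model a `gene_model`.
#' @return The validated model, invisibly usable in a pipeline.
#' @export
validate_gene_model <- function(model) {
  stopifnot(inherits(model, "gene_model"))
  if (grepl("[^ACGTN]", model$sequence)) {
    kdr_stop("genomic sequence contains characters outside A/C/G/T/N",
             "kdr_input_error")
  }
  ex <- model$exons
  n <- nchar(model$sequence)
  if (nrow(ex) < 1L) kdr_stop("at least one exon is required", "kdr_input_error")
  if (any(is.na(ex$start)) || any(is.na(ex$end))) {
    kdr_stop("exon intervals contain NA", "kdr_input_error")
  }
  if (any(ex$start > ex$end)) {
    kdr_stop("exon start exceeds exon end", "kdr_coordinate_error")
  }
  if (any(ex$start < 1L) || any(ex$end > n)) {
    kdr_stop(sprintf("exon interval outside [1, %d]", n), "kdr_coordinate_error")
  }
  if (nrow(ex) > 1L && any(ex$start[-1] <= ex$end[-nrow(ex)])) {
    kdr_stop("exons must be strictly increasing and non-overlapping",
             "kdr_coordinate_error")
  }
  cds_len <- sum(ex$end - ex$start + 1L)
  if (cds_len %% 3L != 0L) {
    kdr_stop(sprintf("concatenated exon length %d is not a multiple of 3",
                     cds_len),
             "kdr_frame_error")
  }
  model
}

#' @export
print.gene_model <- function(x, ...) {
  L <- gene_lengths(x)
  cat(sprintf("<gene_model> %s: %d bp genomic, %d exons, CDS %d nt (%d aa incl. stop), introns %d nt\n",
              x$gene_id, L$genomic, nrow(x$exons), L$cds,
              L$protein_positions, L$intron))
  invisible(x)
}

#' Length arithmetic of a gene model
#'
#' @param model a `gene_model`.
#' @return List with `genomic`, `cds`, `intron` (nucleotides),
#'   `protein_positions` (`cds / 3`, counting the terminal stop as a
#'   position) and `n_exons`.
#' @export
gene_lengths <- function(model) {
  validate_gene_model(model)
  cds <- sum(model$exons$end - model$exons$start + 1L)
  genomic <- nchar(model$sequence)
  list(genomic = genomic,
       cds = cds,
       intron = genomic - cds,
       protein_positions = cds %/% 3L,
       n_exons = nrow(model$exons))
}

#' Assemble the coding sequence from a gene model
#'
#' Concatenates the exon substrings in genomic order.
#'
#' @param model a `gene_model`.
#' @return Character scalar CDS whose length equals the sum of exon lengths.
#' @export
assemble_cds <- function(model) {
  validate_gene_model(model)
  paste(substring(model$sequence, model$exons$start, model$exons$end),
        collapse = "")
}

# cumulative CDS length before each exon
cds_offsets <- function(exons) {
  len <- exons$end - exons$start + 1L
  c(0L, cumsum(len))[seq_len(nrow(exons))]
}

#' Map genomic positions to CDS/codon coordinates
#'
#' Exonic positions map bijectively and order-preservingly onto
#' `1..CDS length`; each exonic position carries its codon index
#' (`ceil(cds_position / 3)`) and 0-based offset within the codon.  Intronic
#' positions get `region = "intronic"` and the distance to the nearest exon
#' boundary; positions in the gene but before the first or after the last
#' exon get `region = "flanking"`.
#'
#' @param model a `gene_model`.
#' @param genomic_pos integer vector of 1-based positions within the gene.
#' @return Tibble with columns `genomic_position`, `region`, `cds_position`,
#'   `codon_index`, `codon_offset`, `distance_to_exon` (NA for exonic rows).
#' @export
genomic_to_cds <- function(model, genomic_pos) {
  validate_gene_model(model)
  genomic_pos <- as.integer(genomic_pos)
  n <- nchar(model$sequence)
  if (any(is.na(genomic_pos)) || any(genomic_pos < 1L) || any(genomic_pos > n)) {
    kdr_stop(sprintf("genomic position outside gene bounds [1, %d]", n),
             "kdr_coordinate_error")
  }
  ex <- model$exons
  off <- cds_offsets(ex)
  i <- findInterval(genomic_pos, ex$start)
  exonic <- i >= 1L & genomic_pos <= ifelse(i >= 1L, ex$end[pmax(i, 1L)], 0L)

  cds_position <- rep(NA_integer_, length(genomic_pos))
  cds_position[exonic] <- off[i[exonic]] + genomic_pos[exonic] -
    ex$start[i[exonic]] + 1L

  region <- ifelse(exonic, "exonic",
                   ifelse(genomic_pos < ex$start[1L] | genomic_pos > ex$end[nrow(ex)],
                          "flanking", "intronic"))

  # distance to the nearest exon boundary for non-exonic positions
  dist <- rep(NA_integer_, length(genomic_pos))
  ni <- which(!exonic)
  if (length(ni)) {
    bounds <- sort(c(ex$start, ex$end))
    dist[ni] <- vapply(genomic_pos[ni],
                       function(p) min(abs(bounds - p)), integer(1))
  }

  tibble::tibble(
    genomic_position = genomic_pos,
    region = region,
    cds_position = cds_position,
    codon_index = ifelse(is.na(cds_position), NA_integer_,
                         (cds_position - 1L) %/% 3L + 1L),
    codon_offset = ifelse(is.na(cds_position), NA_integer_,
                          (cds_position - 1L) %% 3L),
    distance_to_exon = dist
  )
}

#' Map CDS positions back to genomic positions
#'
#' Inverse of [genomic_to_cds()] on exonic positions.
#'
#' @param model a `gene_model`.
#' @param cds_pos integer vector of 1-based CDS positions.
#' @return Integer vector of genomic positions.
#' @export
cds_to_genomic <- function(model, cds_pos) {
  validate_gene_model(model)
  cds_pos <- as.integer(cds_pos)
  L <- gene_lengths(model)
  if (any(is.na(cds_pos)) || any(cds_pos < 1L) || any(cds_pos > L$cds)) {
    kdr_stop(sprintf("CDS position outside [1, %d]", L$cds),
             "kdr_coordinate_error")
  }
  ex <- model$exons
  off <- cds_offsets(ex)
  j <- findInterval(cds_pos, off + 1L)
  ex$start[j] + (cds_pos - off[j] - 1L)
}
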