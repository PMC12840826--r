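#' Read a gene model from FASTA + exon intervals
#'
#' The FASTA must contain a single record (the gene's sense-strand genomic
#' sequence).  Exon intervals may be BED (3+ columns, 0-based half-open —
#' converted to 1-based inclusive here, at the I/O boundary) or a 2-column
#' TSV of 1-based inclusive `start`/`end` values.  Files ending in `.bed`
#' are treated as BED; otherwise 3+ columns with a leading name column are
#' BED, 2 columns are TSV.
#'
#' @param fasta_path path to single-record FASTA.
#' @param exons_path path to BED or 2-column TSV.
#' @param gene_id identifier (default: the FASTA record name).
#' @param format `"auto"`, `"bed"` or `"tsv"`.
#' @return A validated [gene_model()].
#' @export
read_gene_model <- function(fasta_path, exons_path, gene_id = NULL,
                            format = c("auto", "bed", "tsv")) {
  format <- match.arg(format)
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seqs) != 1L) {
    kdr_stop(sprintf("expected a single FASTA record in '%s', found %d",
                     fasta_path, length(seqs)),
             "kdr_input_error")
  }
  if (is.null(gene_id)) gene_id <- sub("\\s.*$", "", names(seqs)[1])

  tab <- utils::read.delim(exons_path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", exons_path, ignore.case = TRUE) ||
                  ncol(tab) >= 3L) "bed" else "tsv"
  }
  exons <- if (format == "bed") {
    data.frame(start = as.integer(tab[[2]]) + 1L, end = as.integer(tab[[3]]))
  } else {
    data.frame(start = as.integer(tab[[1]]), end = as.integer(tab[[2]]))
  }
  gene_model(gene_id, as.character(seqs[[1]]), exons)
}

#' Write a gene model to FASTA + BED
#'
#' @param model a [gene_model()].
#' @param fasta_path,bed_path output paths.
#' @return Invisibly, the model.
#' @export
write_gene_model <- function(model, fasta_path, bed_path) {
  validate_gene_model(model)
  seq <- Biostrings::DNAStringSet(model$sequence)
  names(seq) <- model$gene_id
  Biostrings::writeXStringSet(seq, fasta_path)
  bed <- data.frame(chrom = model$gene_id,
                    start = model$exons$start - 1L,  # back to 0-based half-open
                    end = model$exons$end)
  utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(model)
}

#' Read a variant table (reference TSV format)
#'
#' The reference interchange format: tab-separated with columns
#' `genomic_position`, `ref`, `alt`, then an `<POP>_f`/`<POP>_g` pair per
#' population (empty/NA cells = variant not detected in that population).
#' Lines starting with `#` are comments.
#'
#' @param path TSV path.
#' @return List with `variants` (tibble: `genomic_position`, `ref`, `alt`)
#'   and `counts` (long tibble: `label` = row index as character unless a
#'   `label` column is present, `population`, `f`, `g`).
#' @export
read_variant_tsv <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                           stringsAsFactors = FALSE)
  need <- c("genomic_position", "ref", "alt")
  if (!all(need %in% names(tab))) {
    kdr_stop(sprintf("'%s': variant TSV needs columns %s", path,
                     paste(need, collapse = ", ")),
             "kdr_input_error")
  }
  labels <- if ("label" %in% names(tab)) as.character(tab$label)
            else as.character(seq_len(nrow(tab)))
  variants <- tibble::tibble(
    label = labels,
    genomic_position = as.integer(tab$genomic_position),
    ref = toupper(tab$ref), alt = toupper(tab$alt)
  )
  fcols <- grep("_f$", names(tab), value = TRUE)
  pops <- sub("_f$", "", fcols)
  counts <- counts_from_wide(tab, labels, pops)
  list(variants = variants, counts = counts, populations = pops)
}

counts_from_wide <- function(tab, labels, pops) {
  rows <- lapply(pops, function(p) {
    f <- suppressWarnings(as.integer(tab[[paste0(p, "_f")]]))
    g <- suppressWarnings(as.integer(tab[[paste0(p, "_g")]]))
    keep <- !is.na(f) & !is.na(g)
    tibble::tibble(label = labels[keep], population = p,
                   f = f[keep], g = g[keep])
  })
  out <- dplyr::bind_rows(rows)
  out[order(match(out$label, labels)), , drop = FALSE]
}

#' Write a variant table in the reference TSV format
#'
#' @param variants tibble with `label`, `genomic_position`, `ref`, `alt`.
#' @param counts long counts tibble (`label`, `population`, `f`, `g`).
#' @param path output path.
#' @param populations population column order (default: order of appearance).
#' @return Invisibly, the written wide data frame.
#' @export
write_variant_tsv <- function(variants, counts, path,
                              populations = unique(counts$population)) {
  wide <- as.data.frame(variants)
  for (p in populations) {
    cc <- counts[counts$population == p, , drop = FALSE]
    i <- match(wide$label, cc$label)
    wide[[paste0(p, "_f")]] <- cc$f[i]
    wide[[paste0(p, "_g")]] <- cc$g[i]
  }
  utils::write.table(wide, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(wide)
}

#' Read variants from a minimal VCF
#'
#' Supports a VCFv4.x subset: SNP records only, with per-population counts
#' carried in INFO keys `CT_<POP>=f,g` (observations without / with the
#' change).  Multi-allelic records must be split into one line per
#' alternate allele.
#'
#' @param path VCF path.
#' @return Same structure as [read_variant_tsv()].
#' @export
read_variant_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    return(list(variants = tibble::tibble(label = character(0),
                                          genomic_position = integer(0),
                                          ref = character(0), alt = character(0)),
                counts = tibble::tibble(label = character(0),
                                        population = character(0),
                                        f = integer(0), g = integer(0)),
                populations = character(0)))
  }
  bad <- nchar(fix$REF) != 1L | nchar(fix$ALT) != 1L | grepl(",", fix$ALT)
  if (any(bad)) {
    kdr_stop(sprintf("VCF line(s) %s: only biallelic SNP records are supported",
                     paste(which(bad), collapse = ", ")),
             "kdr_input_error")
  }
  labels <- ifelse(is.na(fix$ID) | fix$ID == ".",
                   as.character(seq_len(nrow(fix))), fix$ID)
  variants <- tibble::tibble(label = labels,
                             genomic_position = as.integer(fix$POS),
                             ref = fix$REF, alt = fix$ALT)
  info <- vcfR::getINFO(v)
  keys <- unique(unlist(regmatches(info, gregexpr("CT_[A-Za-z0-9]+", info))))
  pops <- sub("^CT_", "", keys)
  rows <- lapply(pops, function(p) {
    val <- vcfR::extract.info(v, paste0("CT_", p))
    keep <- !is.na(val)
    fg <- do.call(rbind, strsplit(val[keep], ","))
    tibble::tibble(label = labels[keep], population = p,
                   f = as.integer(fg[, 1]), g = as.integer(fg[, 2]))
  })
  counts <- dplyr::bind_rows(rows)
  if (nrow(counts)) counts <- counts[order(match(counts$label, labels)), ]
  list(variants = variants, counts = counts, populations = pops)
}

#' Read population metadata
#'
#' TSV with columns `name`, `latitude`, `longitude` (decimal degrees) and
#' optional extras; `#` lines are comments.
#'
#' @param path TSV path.
#' @return Tibble of population metadata.
#' @export
read_populations <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("name", "latitude") %in% names(tab))) {
    kdr_stop(sprintf("'%s': population metadata needs columns name, latitude",
                     path),
             "kdr_input_error")
  }
  if (anyDuplicated(tab$name)) {
    kdr_stop("population names must be unique", "kdr_input_error")
  }
  tibble::as_tibble(tab)
}

#' Read a topology / canonical-map / catalog configuration
#'
#' One structured YAML file with three sections: `regions` (list of
#' `label`/`aa_start`/`aa_end`), `canonical` (list of
#' `native_start`/`native_end`/`offset`) and `catalog` (list of
#' `canonical_label`/`binding_site`/`compound_class`/`status`/`note`).
#' Missing `canonical` or `catalog` sections fall back to an identity-free
#' empty map and the default catalog.
#'
#' @param path YAML path.
#' @return List with `topology` ([topology_map()]), `canonical`
#'   ([canonical_map()]) and `catalog` ([known_site_catalog()]).
#' @export
read_topology_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$regions)) {
    kdr_stop(sprintf("'%s': config has no `regions` section", path),
             "kdr_input_error")
  }
  topo <- topology_map(dplyr::bind_rows(lapply(cfg$regions, tibble::as_tibble)))
  canon <- if (is.null(cfg$canonical)) {
    canonical_map(data.frame(native_start = integer(0),
                             native_end = integer(0), offset = integer(0)))
  } else {
    canonical_map(dplyr::bind_rows(lapply(cfg$canonical, tibble::as_tibble)))
  }
  catalog <- if (is.null(cfg$catalog)) known_site_catalog() else {
    known_site_catalog(dplyr::bind_rows(lapply(cfg$catalog, tibble::as_tibble)))
  }
  list(topology = topo, canonical = canon, catalog = catalog)
}

#' Write a topology configuration YAML
#'
#' @param topology a [topology_map()].
#' @param canonical a [canonical_map()].
#' @param catalog a [known_site_catalog()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_topology_config <- function(topology, canonical, catalog, path) {
  cfg <- list(
    regions = unname(apply(topology$regions, 1, function(r) {
      list(label = unname(r[["label"]]),
           aa_start = as.integer(r[["aa_start"]]),
           aa_end = as.integer(r[["aa_end"]]))
    })),
    canonical = unname(lapply(seq_len(nrow(canonical$intervals)), function(i) {
      as.list(canonical$intervals[i, ])
    })),
    catalog = unname(lapply(seq_len(nrow(catalog)), function(i) {
      as.list(catalog[i, c("canonical_label", "binding_site",
                           "compound_class", "status", "note")])
    }))
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Write a machine-readable run manifest
#'
#' Every pipeline output directory gets a JSON manifest recording the
#' package version, timestamp, input paths and seed, for provenance.
#'
#' @param out_dir output directory.
#' @param inputs named list of input paths/values.
#' @param seed seed used, if any.
#' @return Invisibly, the manifest path.
#' @export
write_run_manifest <- function(out_dir, inputs = list(), seed = NULL) {
  manifest <- list(
    package = "kdrscreen",
    version = as.character(packageVersion("kdrscreen")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    inputs = inputs,
    seed = seed
  )
  path <- file.path(out_dir, "run_manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(path)
}
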