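#' Pipeline run configuration
#'
#' Bundles and validates the file paths and options consumed by
#' [run_annotate()] and [run_summarize()].
#'
#' @param gene_fasta single-record FASTA of the gene's genomic sequence.
#' @param exons BED or 2-column TSV of exon intervals.
#' @param variants variant TSV (reference format, see
#'   [read_variant_tsv()]) or VCF (`.vcf`, see [read_variant_vcf()]).
#' @param topology_config YAML with `regions`/`canonical`/`catalog`
#'   sections, or `NULL` to skip region/canonical/catalog annotation.
#' @param populations population metadata TSV, or `NULL` (disables the
#'   latitude-trend block).
#' @param out_dir output directory (created if needed).
#' @param min_total cells with `f + g` below this are treated as absent
#'   (default 1, i.e. any reported cell counts).
#' @param digits display rounding for percentages.
#' @return List of class `run_config`.
#' @export
run_config <- function(gene_fasta, exons, variants, topology_config = NULL,
                       populations = NULL, out_dir = ".", min_total = 1,
                       digits = 2) {
  paths <- c(gene_fasta = gene_fasta, exons = exons, variants = variants,
             topology_config = topology_config, populations = populations)
  missing_files <- paths[!file.exists(paths)]
  if (length(missing_files)) {
    kdr_stop(sprintf("input file(s) not found: %s",
                     paste(missing_files, collapse = ", ")),
             "kdr_input_error")
  }
  structure(list(gene_fasta = gene_fasta, exons = exons, variants = variants,
                 topology_config = topology_config,
                 populations = populations, out_dir = out_dir,
                 min_total = min_total, digits = digits),
            class = "run_config")
}

read_config_inputs <- function(config) {
  model <- read_gene_model(config$gene_fasta, config$exons)
  vv <- if (grepl("\\.vcf(\\.gz)?$", config$variants, ignore.case = TRUE)) {
    read_variant_vcf(config$variants)
  } else {
    read_variant_tsv(config$variants)
  }
  topo <- if (!is.null(config$topology_config)) {
    read_topology_config(config$topology_config)
  } else NULL
  pops <- if (!is.null(config$populations)) {
    read_populations(config$populations)
  } else NULL
  if (!is.null(pops) && length(vv$populations) &&
      !all(vv$populations %in% pops$name)) {
    kdr_stop(sprintf("variant-file population(s) %s missing from metadata",
                     paste(setdiff(vv$populations, pops$name), collapse = ", ")),
             "kdr_input_error")
  }
  # the min-total gate: under-covered cells are treated as absent
  vv$counts <- vv$counts[vv$counts$f + vv$counts$g >= config$min_total, ,
                         drop = FALSE]
  list(model = model, variants = vv$variants, counts = vv$counts,
       var_pops = vv$populations, topo = topo, pops = pops)
}

#' Annotate a variant file against a gene model
#'
#' File-level driver: reads the inputs named in `config`, classifies every
#' variant ([annotate_variants()]), attaches topology regions, canonical
#' positions and known-site matches when a topology config is given,
#' renders per-population frequency columns (`"-"` for absent cells,
#' display-rounded), writes `annotated_variants.tsv` and a run manifest to
#' `config$out_dir`, and returns the annotated table.  Rows are ordered by
#' genomic position.  An empty variant file yields a header-only output
#' with a warning.
#'
#' @param config a [run_config()].
#' @return The annotated tibble, invisibly.
#' @export
run_annotate <- function(config) {
  stopifnot(inherits(config, "run_config"))
  inp <- read_config_inputs(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  eff <- annotate_variants(inp$model, inp$variants)
  if (nrow(eff) > 0L && !"label" %in% names(inp$variants)) {
    inp$variants$label <- eff$label
  }
  if (nrow(eff) > 0L) {
    # carry the user-facing label used by the counts table
    eff <- tibble::add_column(eff, variant_label = inp$variants$label,
                              .before = 1)
  } else {
    eff <- tibble::add_column(eff, variant_label = character(0), .before = 1)
    warning("variant file contains no records; writing header-only output",
            call. = FALSE)
  }

  if (!is.null(inp$topo)) {
    eff <- add_region_labels(eff, inp$topo$topology)
    eff <- add_canonical_positions(eff, inp$topo$canonical)
    matches <- match_known_sites(eff, inp$topo$canonical, inp$topo$catalog)
    full <- matches[matches$match_type == "full", , drop = FALSE]
    eff$known_site <- vapply(eff$label, function(lb) {
      if (is.na(lb)) return("")
      hit <- full[full$label == lb, , drop = FALSE]
      if (nrow(hit) == 0L) "" else {
        paste(sprintf("%s[%s]", hit$matched_label, hit$binding_site),
              collapse = ";")
      }
    }, character(1), USE.NAMES = FALSE)
  }

  pop_order <- if (!is.null(inp$pops)) {
    inp$pops$name
  } else unique(inp$counts$population)
  for (p in pop_order) {
    cc <- inp$counts[inp$counts$population == p, , drop = FALSE]
    i <- match(eff$variant_label, cc$label)
    pct <- ifelse(is.na(i), NA_real_,
                  ifelse(cc$f[i] + cc$g[i] > 0,
                         100 * cc$g[i] / (cc$f[i] + cc$g[i]), NA_real_))
    eff[[paste0(p, "_frequency")]] <-
      ifelse(is.na(pct), "-",
             sprintf("%.*f (%d, %d)", config$digits,
                     round_half_away(pct, config$digits), cc$f[i], cc$g[i]))
  }

  eff <- eff[order(eff$genomic_position), , drop = FALSE]
  out_path <- file.path(config$out_dir, "annotated_variants.tsv")
  utils::write.table(eff, out_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  write_run_manifest(config$out_dir,
                     inputs = config[c("gene_fasta", "exons", "variants",
                                       "topology_config", "populations")])
  invisible(eff)
}

#' Summarise a variant file into population-level statistics
#'
#' File-level driver: annotates (in-run) and then computes the full
#' [summarize_variants()] block — frequency and presence matrices, class
#' counts, dN/dS count ratio, per-class presence summaries, frequency
#' extremes and (when population coordinates are supplied) per-variant
#' latitude-frequency rank correlations.  Writes `frequency_matrix.tsv`,
#' `presence_matrix.tsv`, `summary_stats.tsv`, `latitude_trend.tsv` and a
#' run manifest to `config$out_dir`.
#'
#' @param config a [run_config()].
#' @return The `vgsc_summary` object, invisibly.
#' @export
run_summarize <- function(config) {
  stopifnot(inherits(config, "run_config"))
  inp <- read_config_inputs(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  eff <- annotate_variants(inp$model, inp$variants)
  if (nrow(eff) > 0L) eff$label <- inp$variants$label

  if (is.null(inp$pops)) {
    warning("no population coordinates supplied; latitude trend skipped",
            call. = FALSE)
  }
  summ <- summarize_variants(eff, inp$counts, populations = inp$pops,
                             digits = config$digits)

  write_matrix_tsv(summ$frequency, file.path(config$out_dir,
                                             "frequency_matrix.tsv"))
  write_matrix_tsv(summ$presence * 1L, file.path(config$out_dir,
                                                 "presence_matrix.tsv"))

  stats_rows <- list(c("n_nonsynonymous", summ$n_ns),
                     c("n_synonymous", summ$n_s),
                     c("n_other", summ$n_other))
  if (!is.null(summ$dnds)) {
    stats_rows <- c(stats_rows,
                    list(c("dnds_count_ratio", sprintf("%.4f", summ$dnds$ratio)),
                         c("dnds_regime", summ$dnds$regime),
                         c("dnds_caveat", summ$dnds$caveat)))
  }
  for (cls in names(summ$by_class)) {
    b <- summ$by_class[[cls]]
    if (is.null(b)) next
    stats_rows <- c(stats_rows,
                    list(c(paste0(cls, "_shared_in_all"), b$shared_in_all),
                         c(paste0(cls, "_unique_to_one"), b$unique_to_one)))
  }
  if (!is.null(summ$extremes)) {
    stats_rows <- c(stats_rows, list(
      c("max_frequency", sprintf("%.2f (%s: %s)",
                                 summ$extremes$max$frequency[1],
                                 summ$extremes$max$label[1],
                                 summ$extremes$max$population[1]))))
  }
  stats_df <- data.frame(statistic = vapply(stats_rows, `[`, "", 1L),
                         value = vapply(stats_rows, `[`, "", 2L))
  utils::write.table(stats_df, file.path(config$out_dir, "summary_stats.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  if (!is.null(summ$trend)) {
    utils::write.table(summ$trend,
                       file.path(config$out_dir, "latitude_trend.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  }
  write_run_manifest(config$out_dir,
                     inputs = config[c("gene_fasta", "exons", "variants",
                                       "topology_config", "populations")])
  invisible(summ)
}

write_matrix_tsv <- function(m, path) {
  df <- data.frame(label = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read back a matrix written by the summarise driver
#'
#' Inverse of the frequency/presence matrix writer, for round-tripping.
#'
#' @param path TSV path with a leading `label` column.
#' @return Numeric matrix with row names.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
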