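#' Simulation configuration
#'
#' Parameters for the synthetic gene and population allele-count generator.
#' Defaults describe the study conditions the package targets: five Hainan
#' populations, 37 variant sites with a 6/37 nonsynonymous fraction, a
#' 36,774-bp gene with a 6414-bp CDS over 13 exons, per-cell total counts
#' spanning 36-156 observations, and 30% of variant-by-population cells
#' unreported.  True per-cell change frequencies follow a latitude-linked
#' logistic trend (the package's own formalisation of a southward-increase
#' pattern): `logit(p) = baseline + trend_slope * (max(latitude) -
#' latitude)`, with per-variant baselines drawn uniformly from
#' `baseline_range`.
#'
#' @param seed mandatory integer seed; the generator uses one locally
#'   scoped RNG stream and leaves global RNG state untouched.
#' @param n_exons number of exons.
#' @param cds_length,genomic_length exact gene dimensions (CDS a multiple
#'   of 3); set either to `NULL` to draw exon/intron lengths from the
#'   ranges instead.
#' @param exon_length_range,intron_length_range length ranges (nt) used
#'   when exact dimensions are not requested.
#' @param n_variants number of variant sites.
#' @param fraction_nonsynonymous expected nonsynonymous fraction in `[0,1]`.
#' @param populations data frame with `name`, `latitude` (default: the five
#'   fixture populations).
#' @param trend_slope logits per degree of latitude *decrease* (default 3,
#'   the scale of the observed kdr gradient across the 0.65-degree Hainan
#'   span).
#' @param baseline_range range of per-variant baseline logits at the
#'   northernmost population.
#' @param depth_range inclusive range of per-cell total counts `f + g`.
#' @param missing_rate probability that a variant-by-population cell is
#'   unreported.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(seed,
                              n_exons = 13,
                              cds_length = 6414,
                              genomic_length = 36774,
                              exon_length_range = c(150, 1300),
                              intron_length_range = c(500, 4500),
                              n_variants = 37,
                              fraction_nonsynonymous = 6 / 37,
                              populations = NULL,
                              trend_slope = 3,
                              baseline_range = c(-3, 1.5),
                              depth_range = c(36, 156),
                              missing_rate = 0.3) {
  if (missing(seed)) kdr_stop("`seed` is mandatory", "kdr_config_error")
  if (is.null(populations)) {
    populations <- read_populations(system.file("extdata", "populations.tsv",
                                                package = "kdrscreen",
                                                mustWork = TRUE))
  }
  cfg <- list(seed = as.integer(seed), n_exons = as.integer(n_exons),
              cds_length = cds_length, genomic_length = genomic_length,
              exon_length_range = exon_length_range,
              intron_length_range = intron_length_range,
              n_variants = as.integer(n_variants),
              fraction_nonsynonymous = fraction_nonsynonymous,
              populations = populations, trend_slope = trend_slope,
              baseline_range = baseline_range,
              depth_range = as.integer(depth_range),
              missing_rate = missing_rate)
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  with(cfg, {
    if (fraction_nonsynonymous < 0 || fraction_nonsynonymous > 1 ||
        missing_rate < 0 || missing_rate > 1) {
      kdr_stop("proportions must lie in [0, 1]", "kdr_config_error")
    }
    if (depth_range[1] < 1L || depth_range[2] < depth_range[1]) {
      kdr_stop("depth range must satisfy 1 <= min <= max", "kdr_config_error")
    }
    if (n_exons < 1L) kdr_stop("need at least one exon", "kdr_config_error")
    if (!is.null(cds_length)) {
      if (cds_length %% 3 != 0) {
        kdr_stop("cds_length must be a multiple of 3", "kdr_config_error")
      }
      if (cds_length < n_exons * 9) {
        kdr_stop("cds_length too small for n_exons", "kdr_config_error")
      }
      if (!is.null(genomic_length) && n_exons > 1 &&
          genomic_length - cds_length < (n_exons - 1) * 20) {
        kdr_stop("genomic_length leaves too little intron for n_exons",
                 "kdr_config_error")
      }
    }
  })
  invisible(cfg)
}

# sample() on a length-1 vector would sample from 1:x; these never do
sample_range <- function(lo, hi, n) {
  lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
}
shuffle <- function(x) x[sample.int(length(x))]

# random composition of `total` into `k` parts, each >= minimum
random_composition <- function(total, k, minimum) {
  if (k == 1L) return(total)
  spare <- total - k * minimum
  if (spare < 0) kdr_stop("infeasible length constraints", "kdr_config_error")
  cuts <- sort(sample.int(spare + k - 1L, k - 1L))
  parts <- diff(c(0L, cuts, spare + k)) - 1L
  as.integer(parts + minimum)
}

#' Simulate a gene model
#'
#' Draws a random multi-exon gene model satisfying all [gene_model()]
#' invariants: in-frame CDS with a start ATG, terminal stop, no internal
#' stop codons, and introns with canonical GT...AG ends.  Reproducible
#' given `config$seed`.
#'
#' @param config a [simulation_config()].
#' @return A validated [gene_model()].
#' @export
simulate_gene <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_rng(config$seed * 2L + 1L, {
    k <- config$n_exons
    if (!is.null(config$cds_length)) {
      exon_len <- random_composition(as.integer(config$cds_length), k, 9L)
      intron_total <- if (!is.null(config$genomic_length)) {
        as.integer(config$genomic_length - config$cds_length)
      } else if (k > 1L) {
        sum(sample_range(config$intron_length_range[1],
                         config$intron_length_range[2], k - 1L))
      } else 0L
      intron_len <- if (k > 1L) random_composition(intron_total, k - 1L, 20L)
                    else integer(0)
    } else {
      exon_len <- sample_range(config$exon_length_range[1],
                               config$exon_length_range[2], k)
      rem <- sum(exon_len) %% 3L
      exon_len[k] <- exon_len[k] + (3L - rem) %% 3L
      intron_len <- if (k > 1L) {
        sample_range(config$intron_length_range[1],
                     config$intron_length_range[2], k - 1L)
      } else integer(0)
    }

    n_codons <- sum(exon_len) %/% 3L
    sense <- setdiff(names(codon_table()),
                     names(codon_table())[codon_table() == "*"])
    cds_codons <- c("ATG", sample(sense, n_codons - 2L, replace = TRUE), "TAA")
    cds <- paste(cds_codons, collapse = "")

    intron_seq <- vapply(intron_len, function(L) {
      paste0("GT", paste(sample(c("A", "C", "G", "T"), L - 4L, replace = TRUE),
                         collapse = ""), "AG")
    }, character(1))

    starts <- ends <- integer(k)
    pieces <- character(0)
    pos <- 0L; cds_at <- 1L
    for (i in seq_len(k)) {
      starts[i] <- pos + 1L
      ends[i] <- pos + exon_len[i]
      pieces <- c(pieces, substring(cds, cds_at, cds_at + exon_len[i] - 1L))
      cds_at <- cds_at + exon_len[i]
      pos <- ends[i]
      if (i < k) {
        pieces <- c(pieces, intron_seq[i])
        pos <- pos + intron_len[i]
      }
    }
    gene_model(sprintf("sim_gene_seed%d", config$seed),
               paste(pieces, collapse = ""),
               data.frame(start = starts, end = ends))
  })
}

#' Simulate variant observations with known ground truth
#'
#' Plants `n_variants` single-base substitutions at distinct internal
#' codons of the model's CDS.  Each site's class (synonymous or
#' nonsynonymous) is drawn Bernoulli(`fraction_nonsynonymous`) and realised
#' by choosing uniformly among the codon's single-base substitutions of
#' that class (codons with no substitution of the requested class are
#' resampled; stop-creating substitutions are never planted).  True
#' per-population frequencies follow the latitude-linked logistic trend;
#' observed counts per reported cell are `g ~ Binomial(depth, p)` with
#' `f = depth - g` and `depth` uniform on `depth_range`; each cell is
#' independently unreported with probability `missing_rate` (every variant
#' keeps at least one reported cell).
#'
#' @param model a [gene_model()].
#' @param config a [simulation_config()].
#' @return List with `variants` (tibble: `label`, `genomic_position`,
#'   `ref`, `alt`), `counts` (long tibble: `label`, `population`, `f`,
#'   `g`), and `truth` (tibble: `label`, `codon_index`, `true_class`,
#'   `ref_codon`, `alt_codon`, plus one `p_<POP>` column of true
#'   frequencies per population).
#' @export
simulate_observations <- function(model, config) {
  stopifnot(inherits(config, "simulation_config"))
  validate_gene_model(model)
  tab <- codon_table()
  with_rng(config$seed * 2L, {
    cds <- assemble_cds(model)
    n_codons <- nchar(cds) %/% 3L
    if (n_codons - 2L < config$n_variants) {
      kdr_stop("gene too short for n_variants", "kdr_config_error")
    }
    candidates <- shuffle(2:(n_codons - 1L))  # internal codons, random order
    picked <- list()
    used <- 0L
    for (ci in candidates) {
      if (used >= config$n_variants) break
      want_ns <- runif(1) < config$fraction_nonsynonymous
      cod <- substring(cds, (ci - 1L) * 3L + 1L, ci * 3L)
      subs <- codon_substitutions(cod, tab)
      pool <- subs[subs$class == (if (want_ns) "nonsynonymous" else "synonymous"), ,
                   drop = FALSE]
      if (nrow(pool) == 0L) next  # resample a codon with the same draw spent
      pick <- pool[sample.int(nrow(pool), 1L), ]
      used <- used + 1L
      picked[[used]] <- tibble::tibble(
        codon_index = ci, codon_offset = pick$offset,
        ref_codon = cod, alt_codon = pick$alt_codon,
        ref = substr(cod, pick$offset + 1L, pick$offset + 1L),
        alt = substr(pick$alt_codon, pick$offset + 1L, pick$offset + 1L),
        true_class = pick$class
      )
    }
    if (used < config$n_variants) {
      kdr_stop("could not place all variants (gene too constrained)",
               "kdr_config_error")
    }
    plan <- dplyr::bind_rows(picked)
    plan <- plan[order(plan$codon_index), , drop = FALSE]
    plan$label <- paste0(codon_to_aa(plan$ref_codon), plan$codon_index,
                         codon_to_aa(plan$alt_codon))
    cds_pos <- (plan$codon_index - 1L) * 3L + 1L + plan$codon_offset
    plan$genomic_position <- cds_to_genomic(model, cds_pos)

    pops <- config$populations
    lat_ref <- max(pops$latitude)
    baseline <- runif(nrow(plan), config$baseline_range[1],
                      config$baseline_range[2])
    p_true <- outer(baseline, config$trend_slope * (lat_ref - pops$latitude),
                    "+")
    p_true <- stats::plogis(p_true)
    colnames(p_true) <- pops$name

    cells <- expand.grid(v = seq_len(nrow(plan)), p = seq_len(nrow(pops)))
    report <- runif(nrow(cells)) >= config$missing_rate
    # guarantee each variant at least one reported cell
    for (v in seq_len(nrow(plan))) {
      idx <- which(cells$v == v)
      if (!any(report[idx])) report[idx[sample.int(length(idx), 1L)]] <- TRUE
    }
    depth <- sample_range(config$depth_range[1], config$depth_range[2],
                          nrow(cells))
    g <- rbinom(nrow(cells), depth, p_true[as.matrix(cells)])
    counts <- tibble::tibble(
      label = plan$label[cells$v],
      population = pops$name[cells$p],
      f = as.integer(depth - g), g = as.integer(g)
    )[report, , drop = FALSE]
    counts <- counts[order(match(counts$label, plan$label)), , drop = FALSE]

    truth <- tibble::tibble(label = plan$label,
                            codon_index = plan$codon_index,
                            true_class = plan$true_class,
                            ref_codon = plan$ref_codon,
                            alt_codon = plan$alt_codon)
    for (p in pops$name) truth[[paste0("p_", p)]] <- p_true[, p]

    list(variants = tibble::tibble(label = plan$label,
                                   genomic_position = plan$genomic_position,
                                   ref = plan$ref, alt = plan$alt),
         counts = counts, truth = truth)
  })
}

# all 9 single-base substitutions of a codon, classified, stops excluded
codon_substitutions <- function(codon, tab = codon_table()) {
  bases <- c("A", "C", "G", "T")
  ref_aa <- unname(tab[codon])
  out <- list()
  for (o in 0:2) {
    b0 <- substr(codon, o + 1L, o + 1L)
    for (b in setdiff(bases, b0)) {
      alt <- codon
      substr(alt, o + 1L, o + 1L) <- b
      alt_aa <- unname(tab[alt])
      if (identical(ref_aa, "*") || identical(alt_aa, "*")) next
      out[[length(out) + 1L]] <- tibble::tibble(
        offset = o, alt_codon = alt,
        class = if (alt_aa == ref_aa) "synonymous" else "nonsynonymous")
    }
  }
  if (length(out) == 0L) {
    return(tibble::tibble(offset = integer(0), alt_codon = character(0),
                          class = character(0)))
  }
  dplyr::bind_rows(out)
}
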