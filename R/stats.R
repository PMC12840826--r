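#' Per-population change frequency
#'
#' The frequency statistic used throughout: given `f` observations without
#' the nucleotide change and `g` observations with it,
#' `frequency = 100 * g / (f + g)` percent.  Display values are rounded to
#' two decimal places, half away from zero; pass `digits = NULL` for the
#' full-precision value (summary statistics are always computed on full
#' precision).
#'
#' @param f,g non-negative integer counts (vectorised; `f + g > 0`).
#' @param digits decimal places for display rounding, or `NULL` for none.
#' @return Numeric vector of percentages in `[0, 100]`.
#' @examples
#' snp_frequency(11, 110)  # 90.91
#' snp_frequency(0, 64)    # 100
#' @export
snp_frequency <- function(f, g, digits = 2) {
  f <- as.numeric(f); g <- as.numeric(g)
  if (any(is.na(f)) || any(is.na(g)) || any(f < 0) || any(g < 0)) {
    kdr_stop("counts must be non-negative and non-missing", "kdr_input_error")
  }
  tot <- f + g
  if (any(tot == 0)) {
    kdr_stop("undefined frequency: f + g = 0", "kdr_undefined_frequency")
  }
  p <- 100 * g / tot
  if (!is.null(digits)) p <- round_half_away(p, digits)
  p
}

#' Variant-by-population frequency matrix
#'
#' @param counts long-format tibble with columns `label`, `population`, `f`,
#'   `g`; a (label, population) pair absent from the table means the variant
#'   was not detected there and yields `NA`.
#' @param populations character vector fixing column order (default: order
#'   of appearance).
#' @param digits display rounding for [snp_frequency()] (`NULL` = full
#'   precision).
#' @return Numeric matrix, rows = variant labels (order of appearance),
#'   columns = populations.
#' @export
frequency_table <- function(counts, populations = unique(counts$population),
                            digits = 2) {
  labels <- unique(counts$label)
  m <- matrix(NA_real_, nrow = length(labels), ncol = length(populations),
              dimnames = list(labels, populations))
  freq <- snp_frequency(counts$f, counts$g, digits = digits)
  m[cbind(match(counts$label, labels),
          match(counts$population, populations))] <- freq
  m
}

#' Count-based dN/dS ratio
#'
#' The ratio of nonsynonymous to synonymous SNP counts — a raw count ratio,
#' not a codon-model (NG86/GY94-style) estimator; it ignores the differing
#' numbers of nonsynonymous and synonymous sites and is reported with an
#' interpretive caveat.  A ratio below 1 is read as consistent with
#' purifying selection, above 1 with positive selection, and within
#' `neutral_band` of 1 as neutral-consistent.
#'
#' @param n_ns,n_s nonsynonymous and synonymous SNP counts (`n_s > 0`).
#' @param neutral_band half-width of the neutral-consistent band around 1.
#' @return Object of class `dnds_ratio`: list with `n_ns`, `n_s`, `ratio`,
#'   `regime` and `caveat`.
#' @examples
#' dnds_count_ratio(6, 31)
#' @export
dnds_count_ratio <- function(n_ns, n_s, neutral_band = 0.1) {
  n_ns <- as.integer(n_ns); n_s <- as.integer(n_s)
  if (is.na(n_ns) || is.na(n_s) || n_ns < 0 || n_s < 0) {
    kdr_stop("counts must be non-negative integers", "kdr_input_error")
  }
  if (n_s == 0L) {
    kdr_stop("undefined dN/dS: no synonymous variants (never reported as infinite)",
             "kdr_undefined_ratio")
  }
  ratio <- n_ns / n_s
  regime <- if (abs(ratio - 1) <= neutral_band) "neutral-consistent"
            else if (ratio < 1) "purifying-consistent"
            else "positive-consistent"
  structure(list(
    n_ns = n_ns, n_s = n_s, ratio = ratio, regime = regime,
    caveat = paste("count-based ratio from population-level SNPs;",
                   "interpretation as a selection signature requires caution")
  ), class = "dnds_ratio")
}

#' @export
print.dnds_ratio <- function(x, ...) {
  cat(sprintf("dN/dS (count ratio) = %d/%d = %.2f [%s]\n",
              x$n_ns, x$n_s, x$ratio, x$regime))
  cat("note:", x$caveat, "\n")
  invisible(x)
}

#' Presence/absence summary across populations
#'
#' A variant is *present* in a population iff counts were reported for that
#' cell (a missing cell means not detected).  Reported cells with `g = 0`
#' would count as present-but-unchanged and are flagged separately.
#'
#' @param counts long-format tibble with columns `label`, `population`, `f`,
#'   `g`.
#' @param populations character vector of all surveyed populations (needed
#'   so "present in all" is judged against the full panel, default: those
#'   appearing in `counts`).
#' @return List with `per_variant` (tibble: `label`, `n_present`,
#'   `populations`, `max_population`, `max_frequency`, `min_population`,
#'   `min_frequency`), `shared_in_all`, `unique_to_one`, and
#'   `zero_change_cells`.
#' @export
presence_summary <- function(counts, populations = unique(counts$population)) {
  if (length(populations) < 1L) {
    kdr_stop("at least one population is required", "kdr_input_error")
  }
  counts <- counts[counts$population %in% populations, , drop = FALSE]
  freq <- snp_frequency(counts$f, counts$g, digits = NULL)
  per <- lapply(split(seq_len(nrow(counts)), factor(counts$label, levels = unique(counts$label))),
                function(idx) {
    fr <- freq[idx]; pp <- counts$population[idx]
    tibble::tibble(
      n_present = length(idx),
      populations = paste(pp, collapse = ","),
      max_population = pp[which.max(fr)], max_frequency = max(fr),
      min_population = pp[which.min(fr)], min_frequency = min(fr)
    )
  })
  per_variant <- dplyr::bind_rows(per, .id = "label")
  zero <- counts[counts$g == 0 & counts$f > 0, c("label", "population")]
  list(per_variant = per_variant,
       shared_in_all = sum(per_variant$n_present == length(populations)),
       unique_to_one = sum(per_variant$n_present == 1L),
       zero_change_cells = tibble::as_tibble(zero))
}

#' Latitude-frequency rank correlation
#'
#' Spearman rank correlation between population latitude and a variant's
#' change frequency, the package's formalisation of a "frequency increases
#' with decreasing latitude" trend (a negative correlation).  Populations
#' with no reported frequency are excluded pairwise; ties are mid-ranked.
#' This is an artifact-defined descriptive statistic; no significance claim
#' is attached.
#'
#' @param populations data frame with columns `name`, `latitude`.
#' @param freqs named numeric vector of per-population frequencies (names
#'   are population names; `NA` or absent = not detected).
#' @return List with `rho` (Spearman correlation, `NA` when undefined),
#'   `n` (populations used) and `flag` (`"ok"`, `"insufficient-data"` for
#'   fewer than 3 points, `"degenerate"` for constant input).
#' @export
latitude_trend <- function(populations, freqs) {
  if (!all(c("name", "latitude") %in% names(populations))) {
    kdr_stop("`populations` needs columns name, latitude", "kdr_input_error")
  }
  lat <- populations$latitude[match(names(freqs), populations$name)]
  keep <- !is.na(freqs) & !is.na(lat)
  x <- lat[keep]; y <- as.numeric(freqs)[keep]
  if (length(x) < 3L) {
    return(list(rho = NA_real_, n = length(x), flag = "insufficient-data"))
  }
  if (length(unique(y)) == 1L || length(unique(x)) == 1L) {
    return(list(rho = NA_real_, n = length(x), flag = "degenerate"))
  }
  list(rho = unname(cor(x, y, method = "spearman")), n = length(x), flag = "ok")
}

#' Full per-dataset summary statistics
#'
#' Bundles the frequency matrix, presence matrix, class counts, dN/dS count
#' ratio, presence summaries per class, frequency extremes and (when
#' population coordinates are supplied) per-variant latitude trends.
#' Statistics are computed on full-precision frequencies; `digits` only
#' affects the display matrix.
#'
#' @param effects annotated effect table ([annotate_variants()]), one row
#'   per variant, with `label` and `effect_class`.
#' @param counts long-format counts tibble (`label`, `population`, `f`, `g`).
#' @param populations optional data frame with `name`, `latitude` (and
#'   `longitude`); enables the trend block and fixes population order.
#' @param digits display rounding for the frequency matrix.
#' @return Object of class `vgsc_summary`.
#' @export
summarize_variants <- function(effects, counts, populations = NULL, digits = 2) {
  pop_names <- if (!is.null(populations)) populations$name else unique(counts$population)
  parts <- partition_effects(effects)
  dnds <- if (nrow(parts$synonymous) > 0L) {
    dnds_count_ratio(nrow(parts$nonsynonymous), nrow(parts$synonymous))
  } else NULL

  freq_full <- frequency_table(counts, pop_names, digits = NULL)
  freq_disp <- round_half_away(freq_full, digits)
  presence <- !is.na(freq_full)

  by_class <- lapply(parts[c("nonsynonymous", "synonymous")], function(p) {
    if (nrow(p) == 0L) return(NULL)
    presence_summary(counts[counts$label %in% p$label, , drop = FALSE],
                     populations = pop_names)
  })

  extremes <- frequency_extremes(freq_full)

  trend <- NULL
  if (!is.null(populations) && "latitude" %in% names(populations)) {
    trend <- dplyr::bind_rows(lapply(rownames(freq_full), function(lb) {
      tr <- latitude_trend(populations, freq_full[lb, ])
      tibble::tibble(label = lb, rho = tr$rho, n = tr$n, flag = tr$flag)
    }))
  }

  structure(list(
    frequency = freq_disp, frequency_full = freq_full, presence = presence,
    n_ns = nrow(parts$nonsynonymous), n_s = nrow(parts$synonymous),
    n_other = nrow(parts$other),
    dnds = dnds, by_class = by_class, extremes = extremes, trend = trend,
    populations = populations
  ), class = "vgsc_summary")
}

frequency_extremes <- function(freq_full) {
  if (all(is.na(freq_full))) return(NULL)
  w_max <- which(freq_full == max(freq_full, na.rm = TRUE), arr.ind = TRUE)
  w_min <- which(freq_full == min(freq_full, na.rm = TRUE), arr.ind = TRUE)
  list(
    max = tibble::tibble(label = rownames(freq_full)[w_max[, 1]],
                         population = colnames(freq_full)[w_max[, 2]],
                         frequency = round_half_away(max(freq_full, na.rm = TRUE), 2)),
    min = tibble::tibble(label = rownames(freq_full)[w_min[, 1]],
                         population = colnames(freq_full)[w_min[, 2]],
                         frequency = round_half_away(min(freq_full, na.rm = TRUE), 2))
  )
}

#' @export
print.vgsc_summary <- function(x, ...) {
  cat(sprintf("<vgsc_summary> %d variants x %d populations\n",
              nrow(x$frequency), ncol(x$frequency)))
  cat(sprintf("  nonsynonymous: %d, synonymous: %d, other: %d\n",
              x$n_ns, x$n_s, x$n_other))
  if (!is.null(x$dnds)) {
    cat(sprintf("  dN/dS count ratio: %d/%d = %.2f [%s]\n",
                x$dnds$n_ns, x$dnds$n_s, x$dnds$ratio, x$dnds$regime))
  }
  for (cls in names(x$by_class)) {
    b <- x$by_class[[cls]]
    if (is.null(b)) next
    cat(sprintf("  %s: %d in all populations, %d in exactly one\n",
                cls, b$shared_in_all, b$unique_to_one))
  }
  if (!is.null(x$extremes)) {
    cat(sprintf("  max frequency: %.2f%% (%s: %s)\n",
                x$extremes$max$frequency[1], x$extremes$max$label[1],
                x$extremes$max$population[1]))
  }
  invisible(x)
}
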