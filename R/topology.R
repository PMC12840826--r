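#' Channel topology map
#'
#' Ordered, non-overlapping protein intervals labelled with VGSC regions.
#' Label grammar follows the field's convention: `"D II-S5"` (helix segment
#' 5 of domain II), `"D II-S45-L"` (linker between S4 and S5 of domain II),
#' `"D II-III-L"` (inter-domain linker), `"D IV < L"` (the region
#' C-terminal of domain IV).  The union need not cover every residue;
#' positions outside all regions are `"unassigned"`.
#'
#' @param regions data frame with columns `label`, `aa_start`, `aa_end`
#'   (1-based inclusive protein positions).
#' @return Object of class `topology_map`.
#' @export
topology_map <- function(regions) {
  regions <- as.data.frame(regions)
  if (!all(c("label", "aa_start", "aa_end") %in% names(regions))) {
    kdr_stop("`regions` needs columns label, aa_start, aa_end", "kdr_input_error")
  }
  regions <- data.frame(label = as.character(regions$label),
                        aa_start = as.integer(regions$aa_start),
                        aa_end = as.integer(regions$aa_end))
  if (any(regions$aa_start < 1L) || any(regions$aa_start > regions$aa_end)) {
    kdr_stop("invalid region interval", "kdr_coordinate_error")
  }
  regions <- regions[order(regions$aa_start), , drop = FALSE]
  if (nrow(regions) > 1L &&
      any(regions$aa_start[-1] <= regions$aa_end[-nrow(regions)])) {
    kdr_stop("topology regions overlap", "kdr_coordinate_error")
  }
  structure(list(regions = regions), class = "topology_map")
}

#' @export
print.topology_map <- function(x, ...) {
  cat(sprintf("<topology_map> %d regions spanning residues %d-%d\n",
              nrow(x$regions), min(x$regions$aa_start), max(x$regions$aa_end)))
  invisible(x)
}

#' Region label for protein positions
#'
#' @param topology a [topology_map()].
#' @param protein_pos integer vector of 1-based protein positions.
#' @return Character vector: the covering region's label, or `"unassigned"`.
#' @export
region_label <- function(topology, protein_pos) {
  stopifnot(inherits(topology, "topology_map"))
  protein_pos <- as.integer(protein_pos)
  if (any(is.na(protein_pos)) || any(protein_pos < 1L)) {
    kdr_stop("protein positions must be >= 1", "kdr_coordinate_error")
  }
  rg <- topology$regions
  i <- findInterval(protein_pos, rg$aa_start)
  hit <- i >= 1L & protein_pos <= rg$aa_end[pmax(i, 1L)]
  ifelse(hit, rg$label[pmax(i, 1L)], "unassigned")
}

#' Piecewise-offset canonical numbering map
#'
#' Converts native residue numbering to the canonical numbering used for
#' cross-species comparison of resistance sites (classically the house-fly
#' channel).  Within each native interval, `canonical = native + offset`;
#' positions outside every interval are unmapped (`NA`).
#'
#' @param intervals data frame with columns `native_start`, `native_end`,
#'   `offset` (non-overlapping intervals).
#' @return Object of class `canonical_map`.
#' @export
canonical_map <- function(intervals) {
  intervals <- as.data.frame(intervals)
  need <- c("native_start", "native_end", "offset")
  if (!all(need %in% names(intervals))) {
    kdr_stop("`intervals` needs columns native_start, native_end, offset",
             "kdr_input_error")
  }
  intervals <- data.frame(native_start = as.integer(intervals$native_start),
                          native_end = as.integer(intervals$native_end),
                          offset = as.integer(intervals$offset))
  if (any(intervals$native_start > intervals$native_end)) {
    kdr_stop("invalid canonical-map interval", "kdr_coordinate_error")
  }
  intervals <- intervals[order(intervals$native_start), , drop = FALSE]
  if (nrow(intervals) > 1L &&
      any(intervals$native_start[-1] <= intervals$native_end[-nrow(intervals)])) {
    kdr_stop("canonical-map intervals overlap", "kdr_coordinate_error")
  }
  structure(list(intervals = intervals), class = "canonical_map")
}

#' Convert native to canonical residue numbering
#'
#' @param map a [canonical_map()].
#' @param native_pos integer vector of native residue positions.
#' @return Integer vector of canonical positions, `NA` where unmapped.
#' @export
to_canonical <- function(map, native_pos) {
  stopifnot(inherits(map, "canonical_map"))
  native_pos <- as.integer(native_pos)
  iv <- map$intervals
  i <- findInterval(native_pos, iv$native_start)
  hit <- i >= 1L & native_pos <= iv$native_end[pmax(i, 1L)]
  ifelse(hit, native_pos + iv$offset[pmax(i, 1L)], NA_integer_)
}

#' Catalog of known VGSC resistance sites
#'
#' The default catalog carries the four sites with confirmed resistance
#' association in leafminer screening — the PyR1 pyrethroid sites M918T and
#' L1014F, the PyR2 site T933I, and the D IVS6 sodium-channel-blocker
#' (indoxacarb/metaflumizone) site V1845I — plus literature-reported
#' substitutions at the same residues (M918L/V, L1014S/H/C/W, T929C,
#' T933C/V) flagged `"literature-only"`.
#'
#' @param entries optional data frame with columns `canonical_label`,
#'   `binding_site`, `compound_class`, `status`, `note` to replace the
#'   default catalog.
#' @return Object of class `known_site_catalog`: a tibble with the parsed
#'   `ref_aa`, `position`, `alt_aa` columns added.
#' @export
known_site_catalog <- function(entries = NULL) {
  if (is.null(entries)) entries <- default_catalog_entries()
  entries <- tibble::as_tibble(entries)
  need <- c("canonical_label", "binding_site", "compound_class", "status")
  if (!all(need %in% names(entries))) {
    kdr_stop("catalog needs columns canonical_label, binding_site, compound_class, status",
             "kdr_input_error")
  }
  m <- regmatches(entries$canonical_label,
                  regexec("^([A-Z])([0-9]+)([A-Z])$", entries$canonical_label))
  if (any(lengths(m) != 4L)) {
    kdr_stop("canonical_label must parse as refAA + integer + altAA",
             "kdr_input_error")
  }
  entries$ref_aa <- vapply(m, `[`, "", 2L)
  entries$position <- as.integer(vapply(m, `[`, "", 3L))
  entries$alt_aa <- vapply(m, `[`, "", 4L)
  if (!"note" %in% names(entries)) entries$note <- ""
  class(entries) <- c("known_site_catalog", class(entries))
  entries
}

default_catalog_entries <- function() {
  tibble::tribble(
    ~canonical_label, ~binding_site, ~compound_class, ~status, ~note,
    "M918T", "PyR1", "pyrethroid", "confirmed",
      "classic super-kdr site; strongest protection against type I/II pyrethroids",
    "L1014F", "PyR1", "pyrethroid", "confirmed",
      "first kdr mutation described (house fly); widespread across insect orders",
    "T933I", "PyR2", "pyrethroid", "confirmed",
      "species-native numbering; reported in thrips, whitefly and beetle pests",
    "V1845I", "D IVS6", "sodium-channel blocker (indoxacarb/metaflumizone)", "confirmed",
      "species-native numbering; functionally validated SCBI resistance site",
    "M918L", "PyR1", "pyrethroid", "literature-only", "reported in Hyalella azteca",
    "M918V", "PyR1", "pyrethroid", "literature-only", "reported in Bemisia tabaci",
    "L1014S", "PyR1", "pyrethroid", "literature-only", "",
    "L1014H", "PyR1", "pyrethroid", "literature-only", "",
    "L1014C", "PyR1", "pyrethroid", "literature-only", "",
    "L1014W", "PyR1", "pyrethroid", "literature-only", "",
    "T929C", "PyR2", "pyrethroid", "literature-only",
      "reported in Frankliniella occidentalis",
    "T933C", "PyR2", "pyrethroid", "literature-only", "",
    "T933V", "PyR2", "pyrethroid", "literature-only", ""
  )
}

#' Attach topology region labels to annotated effects
#'
#' @param effects tibble from [annotate_variants()].
#' @param topology a [topology_map()].
#' @return `effects` with a `region_label` column (`NA` for non-exonic rows).
#' @export
add_region_labels <- function(effects, topology) {
  out <- effects
  out$region_label <- NA_character_
  ex <- !is.na(out$codon_index)
  if (any(ex)) out$region_label[ex] <- region_label(topology, out$codon_index[ex])
  out
}

#' Attach canonical residue numbering to annotated effects
#'
#' @param effects tibble from [annotate_variants()].
#' @param map a [canonical_map()].
#' @return `effects` with a `canonical_position` column (`NA` where
#'   unmapped or non-exonic).
#' @export
add_canonical_positions <- function(effects, map) {
  out <- effects
  out$canonical_position <- NA_integer_
  ex <- !is.na(out$codon_index)
  if (any(ex)) out$canonical_position[ex] <- to_canonical(map, out$codon_index[ex])
  out
}

#' Match nonsynonymous effects against the resistance-site catalog
#'
#' A *full* match requires amino-acid equality (both reference and
#' alternate) plus position equality with the catalog entry under either
#' numbering system: the canonical numbering (via `map`) or the native
#' numbering.  The native fallback exists because resistance catalogs mix
#' numbering systems — sites first described in a given species (e.g. the
#' SCBI site V1845I) are conventionally cited by that species' own residue
#' number.  *Partial* matches (position equality with a different amino-acid
#' substitution) are reported separately, never merged with full matches.
#'
#' @param effects tibble from [annotate_variants()] (nonsynonymous rows are
#'   matched; other rows yield no matches).
#' @param map a [canonical_map()].
#' @param catalog a [known_site_catalog()].
#' @return Tibble with one row per (effect, catalog entry) match: `label`,
#'   `codon_index`, `canonical_position`, `matched_label`, `binding_site`,
#'   `compound_class`, `status`, `match_type` (`"full"`/`"position_only"`)
#'   and `numbering` (`"canonical"`/`"native"`).
#' @export
match_known_sites <- function(effects, map, catalog = known_site_catalog()) {
  stopifnot(inherits(catalog, "known_site_catalog"))
  ns <- effects[effects$effect_class == "nonsynonymous", , drop = FALSE]
  empty <- tibble::tibble(label = character(0), codon_index = integer(0),
                          canonical_position = integer(0),
                          matched_label = character(0),
                          binding_site = character(0),
                          compound_class = character(0), status = character(0),
                          match_type = character(0), numbering = character(0))
  if (nrow(ns) == 0L) return(empty)
  canon <- to_canonical(map, ns$codon_index)
  rows <- lapply(seq_len(nrow(ns)), function(k) {
    hit_can <- !is.na(canon[k]) & catalog$position == canon[k]
    hit_nat <- catalog$position == ns$codon_index[k]
    hit <- hit_can | hit_nat
    if (!any(hit)) return(NULL)
    cat_hit <- catalog[hit, , drop = FALSE]
    full <- cat_hit$ref_aa == ns$ref_aa[k] & cat_hit$alt_aa == ns$alt_aa[k]
    tibble::tibble(
      label = ns$label[k],
      codon_index = ns$codon_index[k],
      canonical_position = canon[k],
      matched_label = cat_hit$canonical_label,
      binding_site = cat_hit$binding_site,
      compound_class = cat_hit$compound_class,
      status = cat_hit$status,
      match_type = ifelse(full, "full", "position_only"),
      numbering = ifelse(hit_can[hit], "canonical", "native")
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) empty else out
}
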