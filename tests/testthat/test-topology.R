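# channel topology, canonical numbering, known-site matching

fixture_cfg <- function() {
  read_topology_config(system.file("extdata", "vgsc_topology.yaml",
                                   package = "kdrscreen", mustWork = TRUE))
}

test_that("region lookup returns the covering label or unassigned", {
  topo <- fixture_cfg()$topology
  expect_identical(region_label(topo, 922), "D II-S45-L")
  expect_identical(region_label(topo, 145), "D I-S1")
  expect_identical(region_label(topo, 2036), "D IV < L")
  expect_identical(region_label(topo, 1), "unassigned")
  expect_error(region_label(topo, 0), class = "kdr_coordinate_error")
  expect_error(
    topology_map(data.frame(label = c("a", "b"), aa_start = c(1, 5),
                            aa_end = c(6, 9))),
    class = "kdr_coordinate_error")  # overlap
})

test_that("canonical conversion applies piecewise offsets, else unmapped", {
  cm <- fixture_cfg()$canonical
  expect_identical(to_canonical(cm, 922L), 918L)
  expect_identical(to_canonical(cm, 1018L), 1014L)
  expect_identical(to_canonical(cm, 933L), 933L)
  expect_identical(to_canonical(cm, 1845L), 1851L)
  expect_true(is.na(to_canonical(cm, 1285L)))
  expect_true(is.na(to_canonical(cm, 2036L)))

  ident <- canonical_map(data.frame(native_start = 1, native_end = 100,
                                    offset = 0))
  expect_identical(to_canonical(ident, 5:10), 5:10)

  # strictly monotonic within each interval
  iv <- cm$intervals
  for (i in seq_len(nrow(iv))) {
    xs <- iv$native_start[i]:iv$native_end[i]
    expect_true(all(diff(to_canonical(cm, xs)) == 1L))
  }
  # round trip through the inverse map is the identity on mapped positions
  inv <- canonical_map(data.frame(native_start = iv$native_start + iv$offset,
                                  native_end = iv$native_end + iv$offset,
                                  offset = -iv$offset))
  mapped <- unlist(lapply(seq_len(nrow(iv)),
                          function(i) iv$native_start[i]:iv$native_end[i]))
  expect_identical(to_canonical(inv, to_canonical(cm, mapped)), mapped)
})

test_that("known-site matching requires amino-acid and position equality", {
  cfg <- fixture_cfg()
  fx <- vgsc_fixture()
  eff <- annotate_variants(fx$model, fx$variants)

  m <- match_known_sites(eff, cfg$canonical, cfg$catalog)
  full <- m[m$match_type == "full" & m$status == "confirmed", ]
  expect_setequal(full$label, c("M922T", "T933I", "L1018F", "V1845I"))
  expect_identical(full$matched_label[full$label == "L1018F"], "L1014F")
  expect_identical(full$binding_site[full$label == "L1018F"], "PyR1")
  expect_identical(full$binding_site[full$label == "M922T"], "PyR1")
  expect_identical(full$binding_site[full$label == "T933I"], "PyR2")
  expect_identical(full$binding_site[full$label == "V1845I"], "D IVS6")
  # the SCBI site is matched under its species-native numbering
  expect_identical(full$numbering[full$label == "V1845I"], "native")

  # Q1285H and D2036E match nothing (absent from the catalog)
  expect_false(any(m$label %in% c("Q1285H", "D2036E")))

  # position-only matches (other substitutions at the same residue) are
  # reported separately, never as full matches
  pos_only <- m[m$match_type == "position_only", ]
  expect_true(all(pos_only$status == "literature-only"))
  expect_true("M918L" %in% pos_only$matched_label[pos_only$label == "M922T"])

  # synonymous effects yield no matches at all
  syn <- eff[eff$effect_class == "synonymous", ]
  expect_identical(nrow(match_known_sites(syn, cfg$canonical, cfg$catalog)), 0L)
})

test_that("catalog labels parse and malformed ones are rejected", {
  cat <- known_site_catalog()
  expect_identical(cat$position[cat$canonical_label == "M918T"], 918L)
  expect_identical(cat$ref_aa[cat$canonical_label == "L1014F"], "L")
  expect_error(
    known_site_catalog(data.frame(canonical_label = "kdr-1014",
                                  binding_site = "PyR1",
                                  compound_class = "pyrethroid",
                                  status = "confirmed")),
    class = "kdr_input_error")
})
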