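# codon-aware variant classification

# a gene whose CDS is under full control: one exon = the CDS itself
cds_only_model <- function(cds) {
  gene_model("cds", cds, data.frame(start = 1L, end = nchar(cds)))
}

test_that("classifier agrees with the brute-force oracle on all 576 cases", {
  bases <- c("A", "C", "G", "T")
  checked <- 0L
  for (codon in names(ORACLE_CODE)) {
    # embed the codon as codon 2 of a 4-codon CDS (start, codon, pad, stop);
    # ATG/TAA context never interferes with the substituted codon
    cds <- paste0("ATG", codon, "GGG", "TAA")
    gm <- cds_only_model(cds)
    for (off in 0:2) {
      ref_base <- substr(codon, off + 1, off + 1)
      for (alt_base in setdiff(bases, ref_base)) {
        alt_codon <- codon
        substr(alt_codon, off + 1, off + 1) <- alt_base
        eff <- annotate_variants(gm, data.frame(genomic_position = 4L + off,
                                                ref = ref_base,
                                                alt = alt_base))
        expect_identical(eff$effect_class, oracle_class(codon, alt_codon))
        expect_identical(eff$ref_codon, codon)
        expect_identical(eff$alt_codon, alt_codon)
        expect_identical(eff$codon_index, 2L)
        checked <- checked + 1L
      }
    }
  }
  expect_identical(checked, 576L)
})

test_that("annotation is pure and fills label/alteration fields", {
  gm <- cds_only_model("ATGTTATAA")  # M L *
  v <- data.frame(genomic_position = 6L, ref = "A", alt = "G")  # TTA -> TTG
  e1 <- annotate_variants(gm, v)
  e2 <- annotate_variants(gm, v)
  expect_identical(e1, e2)
  expect_identical(e1$effect_class, "synonymous")
  expect_identical(e1$label, "L2L")
  expect_identical(short_label(e1), "L2")
  expect_identical(e1$nucleotide_alteration, "TTA > TTG")

  # stop_lost at the terminal stop codon
  sl <- annotate_variants(gm, data.frame(genomic_position = 9L,
                                         ref = "A", alt = "C"))  # TAA -> TAC
  expect_identical(sl$effect_class, "stop_lost")

  # nonsynonymous label carries the alternate amino acid
  ns <- annotate_variants(gm, data.frame(genomic_position = 5L,
                                         ref = "T", alt = "C"))  # TTA -> TCA
  expect_identical(ns$label, "L2S")
  expect_identical(short_label(ns), "L2S")
})

test_that("intronic variants and error paths behave as specified", {
  gm <- toy_model()  # exons 3-8, 10-15; position 9 intronic
  seqs <- strsplit(gm$sequence, "")[[1]]
  eff <- annotate_variants(gm, data.frame(genomic_position = 9L,
                                          ref = seqs[9], alt = "G"))
  expect_identical(eff$effect_class, "intronic")
  expect_true(is.na(eff$codon_index) && is.na(eff$label))

  expect_error(
    annotate_variants(gm, data.frame(genomic_position = 3L, ref = "C", alt = "G")),
    "position 3.*'C'.*'A'", class = "kdr_ref_mismatch")
  expect_error(
    annotate_variants(gm, data.frame(genomic_position = 3L, ref = "A", alt = "A")),
    class = "kdr_degenerate_variant")
})

test_that("exon-boundary variants are classified but flagged", {
  gm <- toy_model()  # exon 1 = 3..8
  v <- data.frame(genomic_position = c(4L, 5L),
                  ref = c("T", "G"), alt = c("A", "A"))
  eff <- annotate_variants(gm, v)
  expect_identical(eff$near_exon_boundary, c(TRUE, FALSE))
  expect_false(any(is.na(eff$effect_class)))
})

test_that("partition splits classes deterministically; stops go to other", {
  gm <- cds_only_model("ATGTTATGGTAA")  # M L W *
  v <- data.frame(
    genomic_position = c(6L, 5L, 8L),
    ref = c("A", "T", "G"),
    alt = c("G", "C", "A")  # TTA>TTG syn; TTA>TCA nonsyn; TGG>TGA stop_gained
  )
  parts <- partition_effects(annotate_variants(gm, v))
  expect_identical(nrow(parts$synonymous), 1L)
  expect_identical(nrow(parts$nonsynonymous), 1L)
  expect_identical(parts$other$effect_class, "stop_gained")

  empty <- partition_effects(annotate_variants(gm, v[0, ]))
  expect_true(all(vapply(empty, nrow, 0L) == 0L))
})
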