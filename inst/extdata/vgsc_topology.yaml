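# VGSC topology, canonical-numbering map and resistance-site catalog for the
# packaged Liriomyza trifolii benchmark fixture.
#
# Domain blocks of the 2138-position protein (terminal stop counted):
# D I = 1-415, D II = 416-1029, D III = 1030-1560, D IV = 1561-2138
# (cumulative sums of the 415/614/531/578 per-domain amino-acid counts; each
# block spans from the end of the previous domain's S6 so it contains the
# preceding inter-domain linker plus helices S1-S6).  Segment-level
# boundaries inside the blocks are not published for this gene; the values
# below are chosen to respect the block partition, the physical S1->S6
# ordering, and the region assignment of every fixture variant, and are
# otherwise arbitrary.  Edit freely for other gene models.
regions:
  - {label: "D I-S1",      aa_start: 130,  aa_end: 155}
  - {label: "D I-S56-L",   aa_start: 280,  aa_end: 360}
  - {label: "D I-II-L",    aa_start: 416,  aa_end: 805}
  - {label: "D II-S1",     aa_start: 806,  aa_end: 830}
  - {label: "D II-S23-L",  aa_start: 855,  aa_end: 875}
  - {label: "D II-S45-L",  aa_start: 915,  aa_end: 925}
  - {label: "D II-S5",     aa_start: 926,  aa_end: 945}
  - {label: "D II-S56-L",  aa_start: 960,  aa_end: 1005}
  - {label: "D II-S6",     aa_start: 1006, aa_end: 1029}
  - {label: "D II-III-L",  aa_start: 1030, aa_end: 1300}
  - {label: "D III-S3",    aa_start: 1360, aa_end: 1380}
  - {label: "D III-S56-L", aa_start: 1460, aa_end: 1500}
  - {label: "D IV-S6",     aa_start: 1830, aa_end: 1855}
  - {label: "D IV < L",    aa_start: 1856, aa_end: 2137}
# Canonical (house-fly style) numbering as piecewise offsets on native
# residue intervals: canonical = native + offset.  The recorded offsets are
# taken verbatim from the survey's cross-species equivalences (922->918,
# 1018->1014, 933 identity, 1845->1851) and are deliberately not reconciled:
# the +6 offset at the SCBI site has the opposite sign to the -4 kdr offsets
# and the reference species of each numbering is unstated.  Positions outside
# all intervals (e.g. 1285, 2036) are unmapped.
canonical:
  - {native_start: 915,  native_end: 925,  offset: -4}
  - {native_start: 926,  native_end: 945,  offset: 0}
  - {native_start: 1006, native_end: 1029, offset: -4}
  - {native_start: 1830, native_end: 1855, offset: 6}
# Known resistance sites.  status "confirmed" = resistance association
# established for this substitution; "literature-only" = substitution
# reported at the same residue in other species.
catalog:
  - {canonical_label: "M918T",  binding_site: "PyR1",   compound_class: "pyrethroid", status: "confirmed",
     note: "classic super-kdr site"}
  - {canonical_label: "L1014F", binding_site: "PyR1",   compound_class: "pyrethroid", status: "confirmed",
     note: "first kdr mutation described (house fly)"}
  - {canonical_label: "T933I",  binding_site: "PyR2",   compound_class: "pyrethroid", status: "confirmed",
     note: "species-native numbering"}
  - {canonical_label: "V1845I", binding_site: "D IVS6", compound_class: "sodium-channel blocker (indoxacarb/metaflumizone)", status: "confirmed",
     note: "species-native numbering; functionally validated SCBI site"}
  - {canonical_label: "M918L",  binding_site: "PyR1", compound_class: "pyrethroid", status: "literature-only", note: ""}
  - {canonical_label: "M918V",  binding_site: "PyR1", compound_class: "pyrethroid", status: "literature-only", note: ""}
  - {canonical_label: "L1014S", binding_site: "PyR1", compound_class: "pyrethroid", status: "literature-only", note: ""}
  - {canonical_label: "L1014H", binding_site: "PyR1", compound_class: "pyrethroid", status: "literature-only", note: ""}
  - {canonical_label: "L1014C", binding_site: "PyR1", compound_class: "pyrethroid", status: "literature-only", note: ""}
  - {canonical_label: "L1014W", binding_site: "PyR1", compound_class: "pyrethroid", status: "literature-only", note: ""}
  - {canonical_label: "T929C",  binding_site: "PyR2", compound_class: "pyrethroid", status: "literature-only", note: ""}
  - {canonical_label: "T933C",  binding_site: "PyR2", compound_class: "pyrethroid", status: "literature-only", note: ""}
  - {canonical_label: "T933V",  binding_site: "PyR2", compound_class: "pyrethroid", status: "literature-only", note: ""}
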