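test_that("cross-product enumeration yields the full library with provenance", {
  lib <- enumerate_library(toy_definition())
  expect_s3_class(lib, "compound_library")
  expect_equal(library_size(lib), 6L)
  expect_false(anyDuplicated(lib$members$smiles) > 0)
  prov <- lib$members[, c("r1_idx", "r2_idx")]
  expect_setequal(interaction(prov$r1_idx, prov$r2_idx, drop = TRUE),
                  interaction(rep(1:2, 3), rep(1:3, each = 2), drop = TRUE))

  one <- enumerate_library(
    markush_definition("c1ccc([*:1])cc1", list("*C")))
  expect_equal(library_size(one), 1L)
  expect_equal(one$members$smiles, canonical_smiles("Cc1ccccc1"))
})

test_that("identical products from symmetric scaffolds are deduplicated, keeping first provenance", {
  # symmetric urea: swapping R1/R2 duplicates every pair drawn from the
  # shared substituents; 12 products collapse to 9 distinct molecules
  # (expected set derived with an independent toolkit and frozen here)
  md <- markush_definition("O=C(N[*:1])N[*:2]",
                           list(c("*C", "*CC", "*O"),
                                c("*C", "*CC", "*O", "*N")))
  lib <- enumerate_library(md)
  expect_equal(library_size(lib), 9L)
  frozen <- c("CCNC(=O)NC", "CCNC(=O)NCC", "CCNC(=O)NN", "CCNC(=O)NO",
              "CNC(=O)NC", "CNC(=O)NN", "CNC(=O)NO", "NNC(=O)NO",
              "O=C(NO)NO")
  expect_setequal(lib$members$smiles, canonical_smiles(frozen))
  # first-encountered provenance retained: (1,1) survives, not a later dup
  expect_true(any(lib$members$r1_idx == 1 & lib$members$r2_idx == 1))
})

test_that("enumeration cap and fragment validation raise informative errors", {
  big <- markush_definition("O=C(N[*:1])N[*:2]",
                            list(paste0("*", strrep("C", 1:40)),
                                 paste0("*", strrep("C", 1:40))))
  expect_error(enumerate_library(big, cap = 1000), "1,600")
  expect_error(markush_definition("c1ccc([*:1])cc1", list(c("*C", "*C(Q"))),
               "position 1, index 2")
  expect_error(markush_definition("c1ccc([*:1])cc1", list("CC")),
               "exactly one attachment")
  expect_error(markush_definition("c1ccc([*:1])cc1", list("C*C")),
               "start with its attachment")
  expect_error(markush_definition("c1ccccc1", list("*C")), "\\[\\*:1\\]")
})

test_that("ring-closure labels are remapped when splicing cyclic fragments", {
  # aromatic fragment spliced inside an open ring of the scaffold must not
  # collide with the scaffold's ring bond numbering
  md <- markush_definition("c1cc([*:1])ccc1C", list(c("*c1ccc(F)cc1", "*C1CC1")))
  lib <- enumerate_library(md)
  expect_equal(library_size(lib), 2L)
  expect_setequal(lib$members$smiles,
                  canonical_smiles(c("Cc1ccc(-c2ccc(F)cc2)cc1", "Cc1ccc(C2CC2)cc1")))
})

test_that("fragment recombination spans exactly the observed substituents", {
  lib <- enumerate_library(toy_definition())
  # members using {F} x {C, CC} plus one with Cl: used sets {F,Cl} x {C,CC}
  sel <- which((lib$members$r1_idx == 1 & lib$members$r2_idx %in% 1:2) |
                 (lib$members$r1_idx == 2 & lib$members$r2_idx == 1))
  bcl <- recombine_fragments(lib, sel)
  expect_equal(library_size(bcl), 4L)          # 2 x 2 cross product
  expect_true(all(bcl$members$smiles %in% lib$members$smiles))
  expect_true(all(lib$members$smiles[sel] %in% bcl$members$smiles))

  # closure: recombining the whole parent returns the parent set
  whole <- recombine_fragments(lib, seq_len(library_size(lib)))
  expect_setequal(whole$members$smiles, lib$members$smiles)

  # idempotence: recombining the BCL's own members is a fixed point
  again <- recombine_fragments(bcl, seq_len(library_size(bcl)))
  expect_setequal(again$members$smiles, bcl$members$smiles)
})

test_that("library round-trips preserve structures, ids and provenance", {
  lib <- enumerate_library(toy_definition())
  for (ext in c("smi", "csv")) {
    f <- withr::local_tempfile(fileext = paste0(".", ext))
    write_library(lib, f)
    back <- read_library(f)
    expect_equal(back$members$smiles, lib$members$smiles)
    expect_equal(back$members$id, lib$members$id)
    expect_equal(back$members$r1_idx, lib$members$r1_idx)
    expect_equal(back$members$r2_idx, lib$members$r2_idx)
  }
  f <- withr::local_tempfile(fileext = ".sdf")
  write_library(lib, f)
  back <- read_library(f)
  expect_setequal(back$members$smiles, lib$members$smiles)
  expect_equal(sort(back$members$id), sort(lib$members$id))
})

test_that("malformed SDF records are skipped with a warning", {
  lib <- enumerate_library(toy_definition())
  f <- withr::local_tempfile(fileext = ".sdf")
  write_library(lib, f)
  txt <- readLines(f)
  # corrupt the counts line of the second record
  starts <- grep("V2000", txt)
  txt[starts[2]] <- "garbage counts line"
  writeLines(txt, f)
  expect_warning(back <- read_library(f), "malformed")
  expect_equal(library_size(back), library_size(lib) - 1L)
})

test_that("Markush definitions round-trip through YAML and JSON", {
  md <- toy_definition()
  for (ext in c("yml", "json")) {
    f <- withr::local_tempfile(fileext = paste0(".", ext))
    write_markush(md, f)
    back <- read_markush(f)
    expect_equal(back$scaffold, md$scaffold)
    expect_equal(back$fragment_sets, md$fragment_sets)
  }
})

test_that("subset declarations resolve structures by canonical lookup", {
  lib <- enumerate_library(toy_definition())
  # non-canonical spellings of members 1 and 3
  bd <- subset_declaration(lib, smiles = c("CN(C)C(=O)c1ccc(F)cc1",
                                           "O=C(c1ccc(F)cc1)N(C)CC"))
  expect_equal(sort(bd$member_ids), sort(match(
    canonical_smiles(c("CN(C)C(=O)c1ccc(F)cc1", "O=C(c1ccc(F)cc1)N(C)CC")),
    lib$members$smiles)))
  expect_error(subset_declaration(lib, smiles = "c1ccncc1"), "not found")
  expect_error(subset_declaration(lib, member_ids = c(1, 1)), "unique")
  expect_error(subset_declaration(lib, member_ids = 99), "1..6")
})
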