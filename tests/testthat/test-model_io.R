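test_that("activity vocabulary is total on the 7 codes and rejects others", {
  expect_length(activity_codes(), 7)
  for (code in activity_codes()) {
    expect_identical(parse_activities(code), code)
  }
  expect_identical(parse_activities("F;G-"), c("F", "Gneg"))
  expect_identical(parse_activities("G+;G"), c("Gpos", "G"))
  expect_error(parse_activities("Q", id = "p9"), "unknown activity code")
  expect_error(parse_activities("", id = "p9"), "empty activity set: p9")
  expect_identical(activity_display(c("Gpos", "Gneg", "F")),
                   c("G+", "G-", "F"))
})

test_that("read_fasta preserves order, concatenates wrapped lines, flags oddities", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "KWKLF"), fa)
  expect_identical(read_fasta(fa), c(a = "KWKLF"))

  writeLines(c(">a", "KWK", "LF", ">b", "CC"), fa)
  expect_identical(read_fasta(fa), c(a = "KWKLF", b = "CC"))

  writeLines(c(">a", "kwk"), fa)
  expect_identical(unname(read_fasta(fa)), "KWK")

  writeLines(c(">a", "KXK"), fa)
  expect_warning(read_fasta(fa), "non-standard residues")

  writeLines(c(">a", "KK", ">a", "CC"), fa)
  expect_error(read_fasta(fa), "duplicate id: a")

  writeLines(character(0), fa)
  expect_error(read_fasta(fa), "empty FASTA")
})

test_that("read_annotations parses activities and blank structural cells", {
  fa <- withr::local_tempfile(fileext = ".fa")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(">p1", "KWKLF", ">p2", "CCGGCC", ">p3", "AAA"), fa)
  header <- paste(c("peptide_id", "activities", "cath_class", "cath_arch",
                    "scop_class", "scop_fold", "tm_cluster", "trace_path"),
                  collapse = "\t")
  writeLines(c(header,
               "p1\tF;Gneg\t\t\t\t\t\t",
               "p2\tF\tAlpha Beta\t2-Layer Sandwich\t\t\t1\t"), tsv)
  d <- read_annotations(tsv, read_fasta(fa))
  expect_equal(n_peptides(d), 2)
  expect_identical(d$peptides$activities[[1]], c("F", "Gneg"))
  expect_true(is.na(d$peptides$cath_class[1]))
  expect_identical(d$peptides$cath_class[2], "Alpha Beta")
  expect_identical(d$peptides$cath_arch[2], "2-Layer Sandwich")
  expect_identical(d$peptides$tm_cluster[2], "1")
  expect_true(is.na(d$peptides$scop_class[2]))

  writeLines(c(header, "p3\t\t\t\t\t\t\t"), tsv)
  expect_error(read_annotations(tsv, read_fasta(fa)),
               "empty activity set: p3")
  writeLines(c(header, "p1\tZZ\t\t\t\t\t\t"), tsv)
  expect_error(read_annotations(tsv, read_fasta(fa)),
               "unknown activity code: ZZ")
})

test_that("dataset write/read round trip is exact", {
  g <- generate_amp_dataset(synthetic_config(n_families = 5,
                                             family_size = 4, seed = 11))
  d <- g$dataset
  fa <- withr::local_tempfile(fileext = ".fa")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_fasta(setNames(d$peptides$sequence, d$peptides$id), fa)
  write_annotations(d, tsv)
  d2 <- read_annotations(tsv, read_fasta(fa))
  expect_identical(d2$peptides$id, d$peptides$id)
  expect_identical(d2$peptides$sequence, d$peptides$sequence)
  expect_identical(unclass(d2$peptides$activities),
                   unclass(d$peptides$activities))
  for (col in c("cath_class", "cath_arch", "scop_class", "scop_fold",
                "tm_cluster")) {
    expect_identical(d2$peptides[[col]], d$peptides[[col]])
  }
})

test_that("amp_dataset enforces its invariants", {
  df <- data.frame(id = c("a", "a"), sequence = c("KK", "CC"))
  df$activities <- I(list("G", "F"))
  expect_error(amp_dataset(df), "duplicate id: a")
  df <- data.frame(id = "a", sequence = "KK")
  df$activities <- I(list(character(0)))
  expect_error(amp_dataset(df), "empty activity set")
})

write_test_pdb <- function(path) {
  atom <- function(serial, elety, alt, res, chain, resno, x, y, z) {
    sprintf("ATOM  %5d %4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            serial, paste0(" ", elety), alt, res, chain, resno, x, y, z)
  }
  lines <- c(
    "MODEL        1",
    atom(1, "N  ", " ", "ALA", "A", 1, 0, 0, 0),
    vapply(1:12, function(i)
      atom(i + 1, "CA ", " ", "ALA", "A", i, i * 1.0, 0, 0), character(1)),
    atom(20, "CA ", "B", "ALA", "A", 5, 99, 99, 99),
    atom(21, "CA ", " ", "GLY", "B", 1, 5, 5, 5),
    atom(22, "CA ", " ", "GLY", "B", 2, 6, 5, 5),
    atom(23, "CA ", " ", "GLY", "B", 3, 7, 5, 5),
    "ENDMDL",
    "MODEL        2",
    atom(1, "CA ", " ", "ALA", "A", 1, 77, 77, 77),
    "ENDMDL",
    "END")
  writeLines(lines, path)
}

test_that("read_ca_trace takes model 1, requested chain, kept altLocs only", {
  pdb <- withr::local_tempfile(fileext = ".pdb")
  write_test_pdb(pdb)
  tr <- read_ca_trace(pdb)                       # default: first chain (A)
  expect_s3_class(tr, "ca_trace")
  expect_equal(nrow(tr), 12)                     # altLoc B dropped, N dropped
  expect_false(any(tr[, 1] > 50))                # no model-2 or altLoc-B rows
  trB <- read_ca_trace(pdb, chain = "B")
  expect_equal(nrow(trB), 3)
  expect_equal(trB[1, ], c(5, 5, 5))
  expect_error(read_ca_trace(pdb, chain = "Z"), "chain Z not found")
})

test_that("C-alpha trace write/read round trip preserves coordinates", {
  tr <- make_trace("helix", 20, noise_sigma = 0.3, seed = 5)
  pdb <- withr::local_tempfile(fileext = ".pdb")
  write_ca_trace(tr, pdb)
  tr2 <- read_ca_trace(pdb)
  expect_equal(nrow(tr2), 20)
  expect_lt(max(abs(unclass(tr2) - unclass(tr))), 1e-3)
})
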