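test_that("revComp is a length-preserving involution and sites the probe", {
  expect_identical(revComp("ACGT"), "ACGT")
  withr::with_seed(11, {
    for (i in 1:25) {
      s <- randomDna(sample(1:80, 1))
      expect_identical(revComp(revComp(s)), s)
      expect_identical(nchar(revComp(s)), nchar(s))
    }
  })
  rc_probe <- revComp(table1_seqs[["Probe-Rox"]])
  expect_identical(rc_probe, "CCGCTTCAGCAAGACTCACT")
  expect_true(grepl(rc_probe, table1_seqs[["EXOpcr-69-bio"]], fixed = TRUE))
})

test_that("revComp rejects non-ACGT input naming the offending position", {
  expect_error(revComp("ACGNT"), "position 4")
  expect_error(revComp("acgt"), "position 1")
})

test_that("ligation reproduces the printed full-length template", {
  lig <- ligateOligos(table1, "Proximity_C1", "Proximity_C2",
                      "Proximity_cnct")
  expect_identical(as.character(lig[[1]]), table1_seqs[["C1C2"]])
  expect_identical(unname(Biostrings::width(lig)), 111L)
  expect_identical(names(lig), "Proximity_C1+Proximity_C2")
})

test_that("ligation requires a downstream 5'-phosphate and non-empty strands", {
  # C1 itself has no 5'-phosphate, so it cannot be the downstream strand
  expect_error(ligateOligos(table1, "Proximity_C2", "Proximity_C1"),
               "5'-phosphate")
  expect_error(oligoSet(c(empty = "")), "non-empty")
  withr::with_seed(12, {
    for (i in 1:10) {
      a <- randomDna(sample(5:40, 1)); b <- randomDna(sample(5:40, 1))
      ol <- oligoSet(c(up = a, down = b), mod5 = c("none", "phosphate"))
      lig <- ligateOligos(ol, "up", "down")
      expect_identical(unname(Biostrings::width(lig)), nchar(a) + nchar(b))
    }
  })
})

test_that("amplicon search uses exact matching with 0-based half-open coords", {
  hit <- findAmplicon(table1, "C1C2", "Proximity_F", "Proximity_R")
  expect_identical(hit@start, 2L)
  expect_identical(hit@end, 89L)
  expect_identical(ampliconLength(hit), 87L)
  # forward primer used as its own reverse partner: its rc is absent
  expect_error(findAmplicon(table1, "C1C2", "Proximity_F", "Proximity_F"),
               "no amplicon.*reverse")
  # the printed EXO reverse primer mismatches the 69-mer 3' end
  expect_error(findAmplicon(table1, "EXOpcr-69-bio", "EXO-F", "EXO-R"),
               "no amplicon")
  expect_error(findAmplicon(table1, "C1C2", "TaqMan_SLC", "Proximity_R"),
               NA)  # TaqMan probe region lies upstream of the reverse site
})

test_that("amplicon search distinguishes missing primer from wrong geometry", {
  # reverse site upstream of the forward site
  ol <- oligoSet(c(tmpl = paste0(revComp("GGGAATCAAGGTAACGGACTTTAG"),
                                 "AAAA", "CATCGCCCTTGGACTACGA"),
                   f = "CATCGCCCTTGGACTACGA",
                   r = "GGGAATCAAGGTAACGGACTTTAG"))
  expect_error(findAmplicon(ol, "tmpl", "f", "r"), "upstream")
  expect_error(findAmplicon(ol, "tmpl", "r", "f"), "not found")
})

test_that("FASTA IO round-trips records with modification tags", {
  tf <- withr::local_tempfile(fileext = ".fasta")
  writeOligos(table1, tf)
  back <- readOligos(tf)
  expect_identical(as.character(back), as.character(table1))
  expect_identical(oligoMod5(back), oligoMod5(table1))
  expect_identical(oligoMod3(back), oligoMod3(table1))

  empty <- withr::local_tempfile(fileext = ".fasta")
  file.create(empty)
  expect_length(readOligos(empty), 0L)

  dup <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT", ">a", "GGCC"), dup)
  expect_error(readOligos(dup), "duplicate")
})

test_that("the packaged design table matches the published oligo set", {
  expect_length(table1, 13L)
  expect_identical(nchar(table1_seqs[["EXOpcr-69-bio"]]), 69L)
  expect_identical(unname(oligoMod5(table1)["EXOpcr-69-bio"]), "biotin")
  expect_identical(unname(oligoMod5(table1)["Proximity_C2"]), "phosphate")
  expect_identical(unname(oligoMod3(table1)["TaqMan_SLC"]), "MGB")
  expect_true(grepl(table1_seqs[["Proximity_F"]],
                    table1_seqs[["Proximity_C1"]], fixed = TRUE))
  expect_true(grepl(revComp(table1_seqs[["Proximity_R"]]),
                    table1_seqs[["Proximity_C2"]], fixed = TRUE))
  expect_true(startsWith(table1_seqs[["EXOpcr-69-bio"]],
                         table1_seqs[["EXO-F"]]))
})
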