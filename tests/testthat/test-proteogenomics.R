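test_that("the variant database substitutes all 20 residues at the stop", {
  db <- build_readthrough_db("MK", "AA")
  expect_length(db$variants, 20)
  expect_true(all(nchar(db$variants) == 5))
  expect_true("MKWAA" %in% db$variants)
  expect_equal(anyDuplicated(db$variants), 0)
  # variants differ only at the readthrough position
  expect_equal(length(unique(substr(db$variants, 1, 2))), 1)
  expect_equal(length(unique(substr(db$variants, 4, 5))), 1)

  empty <- build_readthrough_db("MKL", "")
  expect_true(all(nchar(empty$variants) == 4))

  expect_error(build_readthrough_db("MKZ", "AA"), "InvalidResidue")

  # a 33-residue extension makes each variant 34 aa longer than base
  set.seed(4)
  base <- paste(sample(AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                       859, replace = TRUE), collapse = "")
  ext <- paste(sample(AA, 33, replace = TRUE), collapse = "")
  big <- build_readthrough_db(base, ext)
  expect_true(all(nchar(big$variants) - nchar(base) == 34))
})

test_that("tryptic digestion applies the K/R-not-before-P rule", {
  # fully cleaved products of the antibody-epitope peptide
  d0 <- tryptic_digest("RQNAVTSLDRRKLSKP", max_missed = 0)
  expect_equal(d0$peptide, c("R", "QNAVTSLDR", "R", "K", "LSKP"))
  expect_equal(d0$missed_cleavages, rep(0L, 5))
  # concatenation of 0-missed products restores the protein
  expect_equal(paste(d0$peptide, collapse = ""), "RQNAVTSLDRRKLSKP")

  # no K/R: a single peptide
  expect_equal(tryptic_digest("MAGICDEW", 0)$peptide, "MAGICDEW")

  # one allowed missed cleavage
  d1 <- tryptic_digest("AKCKD", max_missed = 1)
  expect_setequal(d1$peptide, c("AK", "CK", "D", "AKCK", "CKD"))

  # trypsin/p cleaves before proline too
  dp <- tryptic_digest("AKPD", 0, rule = "trypsin/p")
  expect_equal(dp$peptide, c("AK", "PD"))
  expect_equal(tryptic_digest("AKPD", 0)$peptide, "AKPD")
})

test_that("digest agrees with the brute-force enumeration oracle", {
  set.seed(55)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:15) {
    prot <- paste(sample(aa, 50, replace = TRUE,
                         prob = ifelse(aa %in% c("K", "R", "P"), 3, 1)),
                  collapse = "")
    for (mm in c(0L, 2L, 5L)) {
      got <- tryptic_digest(prot, mm)
      want <- oracle_digest(prot, mm)
      key <- function(d) sort(paste(d$peptide, d$start, d$missed_cleavages))
      expect_equal(key(got), key(want))
    }
    # trypsin/p variant against the oracle without the proline exception
    got_p <- tryptic_digest(prot, 1L, rule = "trypsin/p")
    want_p <- oracle_digest(prot, 1L, proline_rule = FALSE)
    expect_equal(sort(got_p$peptide), sort(want_p$peptide))
  }
})

test_that("extension-specific peptides are flagged by position and uniqueness", {
  base <- "MAAAAAKGGGGGR"          # 13 aa
  ext <- "QNAVTSLDRRKLSK"          # K/R-rich extension
  db <- build_readthrough_db(base, ext)
  proteome <- c(p1 = "MMMMQNAVTSLDRMMMM",  # contains one extension peptide
                p2 = "MAAAAAKGGGGGRLLLL")

  pep <- find_extension_specific_peptides(db, proteome, max_missed = 5,
                                          min_len = 1, max_len = Inf)
  expect_true(all(pep$unique_to_extension <= pep$overlaps_extension))

  # peptides entirely within the base never overlap the extension
  inside <- pep[pep$end <= nchar(base), ]
  expect_true(all(!inside$overlaps_extension))
  expect_true("GGGGGR" %in% inside$peptide)

  # an extension peptide also present in the proteome is not unique
  expect_true("QNAVTSLDR" %in% pep$peptide)
  expect_false(any(pep$unique_to_extension[pep$peptide == "QNAVTSLDR"]))

  # an extension peptide absent from the proteome is unique
  expect_true(any(pep$unique_to_extension[pep$peptide == "RKLSK"]))

  # every peptide that does not span the readthrough position is shared by
  # all variants -- except that under the proline rule the variant with P
  # at the readthrough position suppresses the cut at the base C-terminus
  base_pep <- pep[pep$end <= nchar(base), ]
  counts <- table(base_pep$parent)
  expect_length(unique(counts[names(counts) != "rt_P"]), 1)
  pep_tp <- find_extension_specific_peptides(db, proteome, max_missed = 5,
                                             min_len = 1, max_len = Inf,
                                             rule = "trypsin/p")
  counts_tp <- table(pep_tp$parent[pep_tp$end <= nchar(base)])
  expect_length(unique(counts_tp), 1)

  # I/L equivalence turns an L-for-I proteome match into a hit
  db2 <- build_readthrough_db("MK", "ELVISK")
  prot2 <- c(q = "XXELVLSKXX")
  prot2 <- gsub("X", "G", prot2)
  pep2 <- find_extension_specific_peptides(db2, prot2, min_len = 1,
                                           max_len = Inf)
  expect_true(any(pep2$unique_to_extension[pep2$peptide == "ELVISK"]))
  pep2_il <- find_extension_specific_peptides(db2, prot2, min_len = 1,
                                              max_len = Inf,
                                              il_equivalent = TRUE)
  expect_false(any(pep2_il$unique_to_extension[pep2_il$peptide == "ELVISK"]))
})

test_that("peptide length bounds restrict the report", {
  db <- build_readthrough_db("MAAAAAKGGGGGR", "QNAVTSLDRRKLSK")
  pep <- find_extension_specific_peptides(db, c(p = "MMMM"))
  expect_true(all(nchar(pep$peptide) >= 7 & nchar(pep$peptide) <= 40))
})

test_that("variant FASTA export round-trips", {
  db <- build_readthrough_db("MKAY", "RR")
  path <- withr::local_tempfile(fileext = ".fasta")
  write_protein_fasta(db, path)
  back <- Biostrings::readAAStringSet(path)
  expect_length(back, 20)
  expect_equal(as.character(back[["rt_A"]]), "MKAYARR")
})
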