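# One reference run of the fingerprint routine produced these set-bit
# positions (0-based, radius 2, 2048 bits) for the packaged peptide and
# oligosaccharide examples; frozen as regression fixtures.
FROZEN_BITS_PEPTIDE1 <- c(
  66, 139, 222, 298, 366, 428, 438, 468, 547, 555, 670, 782, 810, 821, 838,
  860, 977, 991, 1025, 1038, 1042, 1056, 1068, 1080, 1101, 1185, 1206, 1304,
  1347, 1440, 1538, 1546, 1563, 1567, 1607, 1619, 1708, 1731, 1795, 1943,
  1948, 1975, 2037)
FROZEN_BITS_OLIGO1 <- c(
  27, 139, 152, 198, 328, 338, 365, 375, 410, 440, 472, 560, 649, 757, 850,
  887, 937, 973, 991, 1255, 1386, 1426, 1460, 1553, 1626, 1652, 1693, 1725,
  1737, 1838, 1989)

test_that("fingerprints are deterministic, canonical and non-empty", {
  fp1 <- featurizeSmiles("CCO")
  fp2 <- featurizeSmiles("OCC")
  expect_identical(fp1, fp2)
  expect_length(fp1, 2048L)
  expect_gt(sum(fp1), 0)
  expect_true(all(fp1 %in% c(0L, 1L)))
  # plastic example from the packaged fixture
  fp3 <- featurizeSmiles("C(Cl)CCC(c1ccccc1)CCC(Cl)C")
  expect_length(fp3, 2048L)
  expect_gt(sum(fp3), 0)
})

test_that("frozen regression fingerprints of the packaged molecules match", {
  tab <- fixtureSmiles()
  expect_identical(unname(which(featurizeSmiles(tab$smiles[3]) == 1L)) - 1L,
                   as.integer(FROZEN_BITS_PEPTIDE1))
  expect_identical(unname(which(featurizeSmiles(tab$smiles[5]) == 1L)) - 1L,
                   as.integer(FROZEN_BITS_OLIGO1))
})

test_that("nBits changes length only and radius grows the bit set", {
  for (nb in c(64L, 512L, 1024L)) {
    fp <- featurizeSmiles("CC(c1ccccc1)CCC(CC)CCCC(C)C", fingerprintConfig(nBits = nb))
    expect_length(fp, nb)
  }
  s <- "OC(=O)[C@]([H])(CO)NC(=O)[C@]([H])(C1CCCN1)NC(=O)[C@]([H])([H])N"
  b0 <- sum(featurizeSmiles(s, fingerprintConfig(radius = 0)))
  b2 <- sum(featurizeSmiles(s, fingerprintConfig(radius = 2)))
  expect_lte(b0, b2)
})

test_that("featurizeTable preserves rows, labels and determinism", {
  tab <- fixtureSmiles()
  cfg <- fingerprintConfig(nBits = 512)
  fm <- featurizeTable(tab$smiles, tab$label, cfg)
  expect_identical(dim(fm), c(6L, 512L))
  expect_identical(as.integer(table(sampleLabels(fm))[c("Plastic", "Peptide",
                                                        "Oligosaccharide")]),
                   c(2L, 2L, 2L))
  expect_identical(featureNames(fm)[1], "bit_0000")
  expect_identical(featureNames(fm)[512], "bit_0511")
  # duplicated record gives identical rows
  fm2 <- featurizeTable(rep(tab$smiles[1], 2), rep("Plastic", 2), cfg)
  expect_identical(featureValues(fm2)[1, ], featureValues(fm2)[2, ])
  # row order matches input order
  expect_equal(featureValues(fm)[1, ],
               as.numeric(featurizeSmiles(tab$smiles[1], cfg)),
               ignore_attr = TRUE)
})

test_that("invalid SMILES abort with the offending rows named", {
  expect_error(featurizeTable(c("CCO", "C(Cl(", "not a smiles"), c("a", "b", "c")),
               "2, 3")
  expect_error(featurizeSmiles("C(Cl("), "unparsable")
  expect_error(featurizeTable(character(0), character(0)), "at least one")
  expect_error(featurizeTable(c("CCO"), c("")), "non-empty")
})

test_that("stereo stripping collapses stereoisomeric spellings", {
  achiral <- fingerprintConfig(useChirality = FALSE)
  expect_identical(featurizeSmiles("C[C@H](N)C(=O)O", achiral),
                   featurizeSmiles("C[C@@H](N)C(=O)O", achiral))
})

test_that("feature CSV round-trips densely and sparsely", {
  tab <- fixtureSmiles()
  fm <- featurizeTable(tab$smiles, tab$label, fingerprintConfig(nBits = 64))
  dense <- tempfile(fileext = ".csv")
  writeFeatureCsv(fm, dense)
  back <- readFeatureCsv(dense)
  expect_equal(featureValues(back), featureValues(fm))
  expect_identical(as.character(sampleLabels(back)),
                   as.character(sampleLabels(fm)))
  sparse <- tempfile(fileext = ".txt")
  writeFeatureCsv(fm, sparse, sparse = TRUE)
  trip <- utils::read.table(sparse, header = TRUE)
  expect_identical(nrow(trip), sum(featureValues(fm) != 0))
  expect_identical(readLines(paste0(sparse, ".labels")),
                   as.character(sampleLabels(fm)))
})
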