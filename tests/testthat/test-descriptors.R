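# Molecule parsing and the 179-descriptor featurization contract.

test_that("descriptor names define the 8 + 24 + 147 block structure", {
  nm <- descriptor_names()
  expect_length(nm, 179L)
  expect_false(anyDuplicated(nm) > 0)
  expect_true(all(startsWith(nm[1:8], "DL_")))
  expect_true(all(startsWith(nm[9:32], "BCUT_")))
  expect_true(all(startsWith(nm[33:179], "PF_")))
})

test_that("descriptor vectors honour length, finiteness and bit discipline", {
  for (smi in c("CCO", "c1ccccc1", "CC(=O)Oc1ccccc1C(=O)O",
                "[NH3+]CCC([O-])=O", "C")) {
    v <- compute_descriptors(parse_smiles(smi))
    expect_length(v, 179L)
    expect_true(all(is.finite(v)))
    expect_true(all(v[33:179] %in% c(0, 1)), info = smi)
  }
})

test_that("drug-likeness slots match hand-computable molecules", {
  benzene <- compute_descriptors(parse_smiles("c1ccccc1"))
  expect_equal(unname(benzene["DL_HBD"]), 0)
  expect_equal(unname(benzene["DL_HBA"]), 0)
  expect_equal(unname(benzene["DL_Rings"]), 1)
  expect_equal(unname(benzene["DL_HeavyAtoms"]), 6)
  expect_equal(unname(benzene["DL_MW"]), 6 * 12.011 + 6 * 1.008,
               tolerance = 1e-12)

  ethanol <- compute_descriptors(parse_smiles("CCO"))
  expect_equal(unname(ethanol["DL_HBD"]), 1)  # the hydroxyl
  expect_equal(unname(ethanol["DL_HBA"]), 1)
  expect_equal(unname(ethanol["DL_Rings"]), 0)
  expect_equal(unname(ethanol["DL_MW"]), 2 * 12.011 + 15.999 + 6 * 1.008,
               tolerance = 1e-12)
  # C-C and C-O are terminal-atom bonds, hence not rotatable
  expect_equal(unname(ethanol["DL_RotB"]), 0)
})

test_that("featurization is deterministic and permutation-equivariant", {
  smis <- c("CCO", "c1ccccc1O", "CC(=O)N", "CN1CCCC1", "OC(=O)C(N)C")
  mols <- lapply(smis, parse_smiles)
  t1 <- featurize(mols)
  t2 <- featurize(mols)
  expect_identical(t1$matrix, t2$matrix)
  perm <- c(3L, 1L, 5L, 2L, 4L)
  t3 <- featurize(mols[perm])
  expect_identical(unname(t3$matrix), unname(t1$matrix[perm, ]))
  expect_identical(t3$ids, t1$ids[perm])
})

test_that("the same structure from SDF and SMILES yields identical vectors", {
  smis <- c("c1cnc2[nH]ccc2c1",  # pyrrole-type NH: hardest H-count case
            "CC(=O)Oc1ccccc1C(=O)O", "[NH3+]CCC([O-])=O",
            "c1ccccc1S(=O)(=O)N", "Clc1ccccc1Br")
  mols <- lapply(seq_along(smis), function(i) {
    parse_smiles(smis[i], id = sprintf("M%d", i))
  })
  sdf <- tempfile(fileext = ".sdf")
  write_sdf(mols, sdf)
  back <- read_sdf(sdf)
  expect_length(back, length(mols))
  for (i in seq_along(mols)) {
    expect_equal(compute_descriptors(back[[i]]),
                 compute_descriptors(mols[[i]]), info = smis[i])
  }
})

test_that("SDF reading counts, skips corrupt blocks, and maps activity", {
  mols <- lapply(c("CCO", "c1ccccc1"), parse_smiles)
  mols[[1]]$activity <- "active"
  mols[[2]]$activity <- "inactive"
  sdf <- tempfile(fileext = ".sdf")
  write_sdf(mols, sdf, activity_tag = "PUBCHEM_ACTIVITY_OUTCOME")

  got <- read_sdf(sdf, activity_tag = "PUBCHEM_ACTIVITY_OUTCOME")
  expect_length(got, 2L)
  expect_identical(vapply(got, function(m) m$activity, character(1)),
                   c("active", "inactive"))
  # without the tag argument, records come back unlabelled
  plain <- read_sdf(sdf)
  expect_true(all(is.na(vapply(plain, function(m) m$activity, character(1)))))

  # corrupt middle block: skipped with a warning, others survive
  lines <- readLines(sdf)
  corrupt <- c("garbage", "", "", "not a counts line", "$$$$")
  end1 <- grep("^\\$\\$\\$\\$", lines)[1]
  writeLines(c(lines[1:end1], corrupt, lines[(end1 + 1):length(lines)]),
             sdf)
  expect_warning(got2 <- read_sdf(sdf), "skipping SDF block")
  expect_length(got2, 2L)
  expect_identical(attr(got2, "n_skipped"), 1L)

  # unmappable outcome values drop the record (corrupt block also skipped)
  lines <- readLines(sdf)
  lines[lines == "Active"] <- "Inconclusive"
  writeLines(lines, sdf)
  got3 <- suppressWarnings(
    read_sdf(sdf, activity_tag = "PUBCHEM_ACTIVITY_OUTCOME"))
  expect_length(got3, 1L)
  expect_identical(got3[[1]]$activity, "inactive")
  expect_identical(attr(got3, "n_skipped"), 2L)
})

test_that("SMILES files parse line by line, skipping bad entries", {
  smi <- tempfile(fileext = ".smi")
  writeLines(c("CCO mol1", "not_a_smiles((", "c1ccccc1 mol3"), smi)
  expect_warning(mols <- read_smiles(smi), "skipping SMILES line")
  expect_length(mols, 2L)
  expect_identical(mols[[1]]$id, "mol1")
  expect_identical(mols[[2]]$id, "mol3")
  expect_identical(attr(mols, "n_skipped"), 1L)
  expect_error(read_smiles(tempfile()), "cannot read")
})

test_that("featurize labels only fully-labelled inputs and rejects empties", {
  a <- parse_smiles("CCO"); a$activity <- "active"
  b <- parse_smiles("CCN")
  expect_warning(t1 <- featurize(list(a, b)), "mixed")
  expect_null(t1$labels)
  b$activity <- "inactive"
  t2 <- featurize(list(a, b))
  expect_identical(t2$labels, c(1L, 0L))
  expect_error(featurize(list()), "empty")
})

test_that("feature tables round-trip through CSV", {
  set.seed(55)
  m <- matrix(rnorm(3 * 179), nrow = 3, ncol = 179)
  m[1, 1] <- -3.5e-7  # awkward magnitudes must survive the text round trip
  m[2, 2] <- 1e12
  m[, 33:179] <- (m[, 33:179] > 0) + 0
  colnames(m) <- descriptor_names()
  t0 <- feature_table(m, ids = c("a", "b", "c"), labels = c(1L, 0L, 1L))
  csv <- tempfile(fileext = ".csv")
  write_feature_table(t0, csv)
  t1 <- read_feature_table(csv)
  expect_equal(t1$matrix, t0$matrix)
  expect_identical(t1$ids, t0$ids)
  expect_identical(t1$labels, t0$labels)

  # wrong width is fatal and names the actual count
  bad <- feature_table(m[, 1:178])
  csv2 <- tempfile(fileext = ".csv")
  write_feature_table(bad, csv2)
  expect_error(read_feature_table(csv2), "178")
})
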