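test_that("SMILES parsing builds the heavy-atom graph with implicit hydrogens", {
  lig <- parseLigand("C=CC(=O)N", "acrylamide")
  expect_equal(sort(atoms(lig)$element), c("C", "C", "C", "N", "O"))
  expect_equal(formatFormula(lig@formula), "C3H5NO")
  expect_equal(sum(atoms(lig)$implicit_h), 5L)

  benzene <- parseLigand("c1ccccc1")
  expect_equal(atoms(benzene)$element, rep("C", 6))
  expect_equal(formatFormula(benzene@formula), "C6H6")

  expect_error(parseLigand("C(", "bad"), class = "cyslock_parse_error")
  expect_error(parseLigand("CC.CC", "salt"), class = "cyslock_parse_error")
})

test_that("implicit-hydrogen completion agrees with the OpenBabel formula", {
  for (smi in c("C=CC(=O)N", "c1ccccc1", "C=CS(C)(=O)=O", "CC(C)O",
                "C=CC(=O)Oc1ccccc1", "CCS(=O)(=O)OC")) {
    mine <- formatFormula(parseLigand(smi)@formula)
    ref <- ChemmineR::propOB(ChemmineR::smiles2sdf(smi))$formula
    expect_identical(mine, ref)
  }
})

test_that("SDF blocks parse to the same molecule as their SMILES", {
  sdfset <- ChemmineR::smiles2sdf("C=CS(C)(=O)=O")
  tmp <- tempfile(fileext = ".sdf")
  ChemmineR::write.SDF(sdfset, tmp)
  lig <- parseLigand(readLines(tmp), "sulfone")
  expect_equal(formatFormula(lig@formula), "C3H6O2S")
  expect_equal(nrow(detectWarheads(lig)), 1L)
})

test_that("partial charges conserve total charge and are deterministic", {
  for (smi in c("C=CC(=O)N", "CCO", "C=CC(=O)Oc1ccccc1")) {
    lig <- parseLigand(smi)
    expect_equal(sum(atoms(lig)$charge), sum(atoms(lig)$formal_charge),
                 tolerance = 1e-9)
  }
  a <- parseLigand("C=CC(=O)NCC")
  b <- parseLigand("C=CC(=O)NCC")
  expect_identical(atoms(a)$charge, atoms(b)$charge)
  # carbonyl oxygen is the most negative atom of acrylamide
  lig <- parseLigand("C=CC(=O)N")
  expect_equal(which.min(atoms(lig)$charge), which(atoms(lig)$element == "O"))
})

test_that("the five packaged warhead classes are detected and benzene is not", {
  cases <- list(acrylamide = "C=CC(=O)N",
                enone = "C=CC(=O)C",
                acrylate_ester = "C=CC(=O)OCC",
                vinyl_sulfone = "C=CS(C)(=O)=O",
                vinyl_sulfonate = "C=CS(=O)(=O)OC")
  for (nm in names(cases)) {
    lig <- parseLigand(cases[[nm]], nm)
    m <- detectWarheads(lig)
    expect_equal(nrow(m), 1L, info = nm)
    expect_identical(m$pattern_id, nm)
    # thiol attacks the terminal CH2 carbon
    expect_equal(atoms(lig)$implicit_h[m$beta_c], 2L, info = nm)
    expect_identical(atoms(lig)$element[m$ewg_atom],
                     if (grepl("sulf", nm)) "S" else "C")
  }
  expect_equal(nrow(detectWarheads(parseLigand("c1ccccc1"))), 0L)
  # saturated analog and ring-internal double bonds do not match
  expect_equal(nrow(detectWarheads(parseLigand("CCC(=O)N"))), 0L)
  expect_equal(nrow(detectWarheads(parseLigand("O=C1C=CC(=O)C=C1"))), 0L)
})

test_that("warhead detection is invariant under atom re-indexing", {
  a <- detectWarheads(parseLigand("C=CC(=O)N"))
  b <- detectWarheads(parseLigand("NC(=O)C=C"))
  expect_identical(sort(a$pattern_id), sort(b$pattern_id))
  c1 <- detectWarheads(parseLigand("C=CS(=O)(=O)OC"))
  c2 <- detectWarheads(parseLigand("COS(=O)(=O)C=C"))
  expect_identical(sort(c1$pattern_id), sort(c2$pattern_id))
})

test_that("Michael addition reduces the double bond and adds the parent mass", {
  lig <- parseLigand("C=CC(=O)N")
  m <- detectWarheads(lig)[1, ]
  an <- applyMichaelAddition(lig, m)
  expect_equal(massDelta(an), 71.0371, tolerance = 1e-3)
  b <- an@ligand@bonds
  row <- which((b$from == m$alpha_c & b$to == m$beta_c) |
               (b$from == m$beta_c & b$to == m$alpha_c))
  expect_equal(b$order[row], 1L)
  expect_equal(an@ligand@atoms$implicit_h[m$alpha_c],
               atoms(lig)$implicit_h[m$alpha_c] + 1L)
  # beta keeps its hydrogens; the freed valence is the S link
  expect_equal(an@ligand@atoms$implicit_h[m$beta_c],
               atoms(lig)$implicit_h[m$beta_c])

  # applying the same match to the already-reacted ligand is stale
  expect_error(applyMichaelAddition(an@ligand, m),
               class = "cyslock_consistency_error")
  expect_error(applyMichaelAddition(lig, list(alpha_c = 50, beta_c = 51,
                                              ewg_atom = 3,
                                              pattern_id = "acrylamide")),
               class = "cyslock_consistency_error")
})

test_that("adduct mass equals the formula mass of the parent", {
  for (smi in c("C=CC(=O)N", "C=CS(=O)(=O)OC", "C=CC(=O)Oc1ccccc1")) {
    lig <- parseLigand(smi)
    an <- applyMichaelAddition(lig, detectWarheads(lig)[1, ])
    expect_equal(massDelta(an), formulaMass(formatFormula(lig@formula)),
                 tolerance = 1e-6, info = smi)
  }
})

test_that("rotatable bonds follow the single/acyclic/non-terminal rule", {
  # anchored butyl chain S-C-C-C-C: anchor bond + two interior C-C bonds
  lig <- parseLigand("C=CCC", "butene")
  an <- applyMichaelAddition(lig, list(alpha_c = 2, beta_c = 1, ewg_atom = 3,
                                       pattern_id = "enone"))
  rb <- findRotatableBonds(an)
  expect_equal(nrow(rb), 3L)
  expect_equal(rb$from[1], 0L)
  expect_equal(rb$to[1], an@betaC)
  # terminal methyl bond 3-4 is absent
  expect_false(any(rb$from == 3 & rb$to == 4))

  # acrylamide: amide C-N is excluded, ester and ring bonds likewise
  am <- anchoredIn(stdPocket(1))$anchored
  rbA <- findRotatableBonds(am)
  expect_equal(nrow(rbA), 3L)
  ar <- anchoredIn(stdPocket(1), "C=CC(=O)Nc1ccccc1", "anilide")$anchored
  rbAr <- findRotatableBonds(ar)
  ring <- which(ar@ligand@bonds$order == 2L | ar@ligand@bonds$order == 4L)
  for (r in ring)
    expect_false(any(rbAr$from == ar@ligand@bonds$from[r] &
                     rbAr$to == ar@ligand@bonds$to[r]))
  # N-phenyl bond is rotatable, the amide C-N is not
  nIdx <- which(ar@ligand@atoms$element == "N")
  expect_equal(sum(rbAr$from == nIdx | rbAr$to == nIdx), 1L)
})

test_that("ligand libraries read and write round-trip", {
  lib <- makeLigandLibrary(1, 10, 0.5)
  tmp <- tempfile(fileext = ".smi")
  writeLigandLibrary(lib, tmp)
  back <- readLigandLibrary(tmp)
  expect_identical(back$id, lib$id)
  expect_identical(back$smiles, lib$smiles)
  expect_error(readLigandLibrary(character(0)), class = "cyslock_value_error")
})
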