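test_that("even frame extraction keeps the index-formula models, CA only", {
  tr <- makeTrajectory(1, nFrames = 10, nResidues = 12)
  s <- readStructure(tr$pdb)
  all10 <- extractEvenFrames(s, 10)
  expect_equal(nFrames(all10), 10L)
  expect_equal(cyslock:::frameCoords(all10, 3), modelCoords(s, 3),
               tolerance = 1e-12)

  tr9 <- makeTrajectory(2, nFrames = 9, nResidues = 12)
  s9 <- readStructure(tr9$pdb)
  three <- extractEvenFrames(s9, 3)
  expect_equal(nFrames(three), 3L)
  for (k in 1:3)
    expect_equal(cyslock:::frameCoords(three, k),
                 modelCoords(s9, c(1, 5, 9)[k]), tolerance = 1e-12)

  one <- extractEvenFrames(s9, 1)
  expect_equal(cyslock:::frameCoords(one, 1), modelCoords(s9, 1),
               tolerance = 1e-12)
  expect_error(extractEvenFrames(s9, 10), class = "cyslock_value_error")
})

test_that("superposed RMSD has its metric properties and known values", {
  expect_equal(caRMSD(matrix(1:12, 4, 3), matrix(1:12, 4, 3)), 0)

  set.seed(1)
  a <- matrix(rnorm(30), 10, 3)
  shifted <- a + rep(c(4, -2, 7), each = 10)
  expect_lt(caRMSD(a, shifted), 1e-9)
  th <- 1.1
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  expect_lt(caRMSD(a, a %*% R + 3), 1e-9)

  # two-point frames: centering leaves deviations of exactly 1 per point
  p <- matrix(c(0, 0, 0, 2, 0, 0), 2, 3, byrow = TRUE)
  q <- matrix(c(0, 0, 0, 4, 0, 0), 2, 3, byrow = TRUE)
  expect_equal(caRMSD(p, q), 1.0, tolerance = 1e-12)

  b <- matrix(rnorm(30), 10, 3)
  expect_equal(caRMSD(a, b), caRMSD(b, a), tolerance = 1e-12)
  expect_lte(caRMSD(a, b), caRMSD(a, b, superpose = FALSE) + 1e-12)
  expect_error(caRMSD(a, b[1:5, ]), class = "cyslock_value_error")
})

test_that("superposed RMSD agrees with bio3d's fitted rmsd", {
  set.seed(3)
  for (rep in 1:5) {
    a <- matrix(rnorm(36), 12, 3)
    b <- a + matrix(rnorm(36, sd = 0.7), 12, 3)
    ref <- bio3d::rmsd(as.vector(t(a)), as.vector(t(b)), fit = TRUE)
    expect_equal(caRMSD(a, b), ref, tolerance = 1e-3)   # bio3d rounds to 3 dp
  }
})

test_that("shared-residue RMSD matches structures by chain and number", {
  s <- readStructure(makeToyPocket(6))
  # rigidly moved copy with one residue dropped: shared-CA RMSD is 0
  th <- 0.6
  R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3)
  s2 <- s
  s2@coords[, , 1] <- s@coords[, , 1] %*% R + 2
  drop <- which(s2@atoms$resno != s2@atoms$resno[nrow(s2@atoms)])
  s2@atoms <- s2@atoms[drop, ]
  s2@coords <- s2@coords[drop, , , drop = FALSE]
  r <- sharedCaRMSD(s, s2)
  expect_lt(as.numeric(r), 1e-9)
  expect_equal(attr(r, "n_shared"),
               length(unique(s2@atoms$resno[s2@atoms$name == "CA"])))
})

test_that("clustering recovers synthetic states and reports exact occupancies", {
  # as many clusters as frames: singletons
  tr <- makeTrajectory(5, nFrames = 6, stateFractions = c(0.5, 0.5),
                       nResidues = 10)
  fs6 <- extractEvenFrames(tr$pdb, 6)
  cr6 <- clusterFrames(fs6, k = 6)
  expect_equal(occupancies(cr6), rep(1 / 6, 6))
  expect_equal(sort(medoids(cr6)), 1:6)

  # two well-separated states, 60/40
  tr2 <- makeTrajectory(7, nFrames = 100, stateFractions = c(0.6, 0.4))
  fs <- extractEvenFrames(tr2$pdb, 100)
  cr <- clusterFrames(fs, k = 2)
  expect_equal(occupancies(cr), c(0.6, 0.4), tolerance = 1e-12)
  expect_equal(sum(occupancies(cr)), 1, tolerance = 1e-9)
  agree <- max(mean(clusterLabels(cr) == tr2$labels$state),
               mean(clusterLabels(cr) == 3 - tr2$labels$state))
  expect_equal(agree, 1)
  # medoids carry their own label
  expect_equal(clusterLabels(cr)[medoids(cr)], 1:2)

  expect_error(clusterFrames(fs, k = 101), class = "cyslock_value_error")
})

test_that("cluster occupancies are invariant under frame permutation", {
  tr <- makeTrajectory(9, nFrames = 60, stateFractions = c(0.7, 0.3),
                       nResidues = 20)
  fs <- extractEvenFrames(tr$pdb, 60)
  cr <- clusterFrames(fs, k = 2)
  perm <- rev(seq_len(60))
  fsP <- fs
  fsP@coords <- fs@coords[, , perm]
  crP <- clusterFrames(fsP, k = 2)
  expect_equal(occupancies(crP), occupancies(cr), tolerance = 1e-12)
  # same partition up to relabeling
  tab <- table(clusterLabels(cr)[perm], clusterLabels(crP))
  expect_equal(sum(tab > 0), 2L)
})

test_that("cluster reports export in the table shape of an occupancy listing", {
  tr <- makeTrajectory(3, nFrames = 20, stateFractions = c(0.5, 0.5),
                       nResidues = 10)
  fs <- extractEvenFrames(tr$pdb, 20)
  cr <- clusterFrames(fs, k = 2)
  tmp <- tempfile()
  writeClusterReport(cr, tmp)
  tab <- read.delim(tmp)
  expect_identical(names(tab), c("cluster", "occupancy", "medoid_model"))
  expect_equal(sum(tab$occupancy), 1, tolerance = 1e-6)
  pdbLines <- writeFramePDB(fs, medoids(cr)[1])
  expect_equal(sum(grepl("^ATOM", pdbLines)), 10L)
})

test_that("the conservation screen finds the reference column", {
  aln <- c(">REF some protein", "AC-DEF",
           ">OTH1 synthetic", "AA-DEF",
           ">OTH2 synthetic", "AC-DEF")
  out <- conservationScreen(aln, "REF", 2, targetSymbol = "C")
  expect_equal(out$column, 2L)
  expect_equal(sum(out$table$is_target), 2L)
  # gap handling: residue 3 of REF sits past the gap column
  out3 <- conservationScreen(aln, "REF", 3)
  expect_equal(out3$column, 4L)
  expect_error(conservationScreen(aln, "REF", 0),
               class = "cyslock_value_error")
  expect_error(conservationScreen(aln, "REF", 99),
               class = "cyslock_value_error")
  expect_error(conservationScreen(aln, "NOPE", 1),
               class = "cyslock_value_error")
})

test_that("only Rho-family rows carry the anchor cysteine in the packaged alignment", {
  f <- system.file("extdata", "synthetic_gtpase_alignment.fasta",
                   package = "cyslock")
  out <- conservationScreen(f, "RHOA_HUMAN", 13)
  tab <- out$table
  rho <- grepl("^RHO", tab$id)
  expect_true(all(tab$is_target[rho]))
  expect_false(any(tab$is_target[!rho]))
})
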