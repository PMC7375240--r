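test_that("Coulomb term reproduces the closed form on single pairs", {
  lig <- bareLigand(q = 1)
  cfg <- openConfig(dielectric = 1)
  pk <- barePocket(matrix(c(1, 0, 0), 1, 3), q = -1)
  e <- coulombEnergy(matrix(0, 1, 3), pk, cfg, ligand = lig)
  expect_equal(e, -332.0637, tolerance = 1e-9)

  # dielectric scales inversely
  e4 <- coulombEnergy(matrix(0, 1, 3), pk, openConfig(dielectric = 4),
                      ligand = lig)
  expect_equal(e4, -332.0637 / 4, tolerance = 1e-9)

  zero <- barePocket(matrix(rnorm(15), 5, 3), q = 0)
  expect_equal(coulombEnergy(matrix(0, 1, 3), zero, cfg, ligand = lig), 0)

  far <- barePocket(matrix(c(20, 0, 0), 1, 3), q = -1)
  cut <- scoringConfig(dielectric = 1, cutoff = 12, excluded = integer(0))
  expect_equal(coulombEnergy(matrix(0, 1, 3), far, cut, ligand = lig), 0)
})

test_that("Lennard-Jones term reproduces its closed forms", {
  sig <- 3.4; eps <- 0.25
  lig <- bareLigand(q = 0, sigma = sig, epsilon = eps)
  cfg <- openConfig()
  at <- function(r) barePocket(matrix(c(r, 0, 0), 1, 3), q = 0,
                               sigma = sig, epsilon = eps)
  expect_equal(ljEnergy(matrix(0, 1, 3), at(sig), cfg, ligand = lig), 0,
               tolerance = 1e-9)
  expect_equal(ljEnergy(matrix(0, 1, 3), at(2^(1 / 6) * sig), cfg,
                        ligand = lig), -eps, tolerance = 1e-9)
  lig1 <- bareLigand(q = 0, sigma = sig, epsilon = 1)
  pk1 <- barePocket(matrix(c(2 * sig, 0, 0), 1, 3), q = 0, sigma = sig,
                    epsilon = 1)
  expect_equal(ljEnergy(matrix(0, 1, 3), pk1, cfg, ligand = lig1),
               4 * (2^-12 - 2^-6), tolerance = 1e-12)

  expect_error(ljEnergy(matrix(0, 1, 3), at(0), cfg, ligand = lig),
               class = "cyslock_singular_error")
})

test_that("both terms match a naive double-loop reference on random systems", {
  set.seed(42)
  for (rep in 1:20) {
    nl <- sample(2:8, 1); np <- sample(3:20, 1)
    lxyz <- matrix(runif(nl * 3, -4, 4), nl, 3)
    pxyz <- matrix(runif(np * 3, -8, 8) + 6, np, 3)
    lq <- runif(nl, -0.5, 0.5); pq <- runif(np, -0.5, 0.5)
    ls <- runif(nl, 3, 4); ps <- runif(np, 3, 4)
    le <- runif(nl, 0.05, 0.3); pe <- runif(np, 0.05, 0.3)
    cutoff <- sample(c(8, 12, 1e6), 1)
    lig <- bareLigand(q = lq, sigma = ls, epsilon = le)
    pk <- barePocket(pxyz, q = pq, sigma = ps, epsilon = pe)
    cfg <- scoringConfig(dielectric = 2, cutoff = cutoff,
                         excluded = integer(0))
    expect_equal(coulombEnergy(lxyz, pk, cfg, ligand = lig),
                 naiveCoulomb(lxyz, lq, pxyz, pq, 2, cutoff),
                 tolerance = 1e-8)
    expect_equal(ljEnergy(lxyz, pk, cfg, ligand = lig),
                 naiveLJ(lxyz, ls, le, pxyz, ps, pe, cutoff),
                 tolerance = 1e-8)
  }
})

test_that("clashed poses score positive, favorable poses negative", {
  cfg <- openConfig()
  lig <- bareLigand(q = 0)
  clash <- barePocket(matrix(c(1, 0, 0), 1, 3), q = 0)
  expect_gt(ljEnergy(matrix(0, 1, 3), clash, cfg, ligand = lig), 100)
  good <- barePocket(matrix(c(2^(1 / 6) * 3.4, 0, 0), 1, 3), q = 0)
  expect_lt(ljEnergy(matrix(0, 1, 3), good, cfg, ligand = lig), 0)
})

test_that("weights combine the terms exactly", {
  pk <- stdPocket(1)
  set <- enumerateConformers(anchoredIn(pk)$start, 120)
  cf <- new("Conformer", coords = set@coords[, , 1],
            torsions = set@torsions[1, ], rotatable = set@rotatable,
            anchored = set@anchored, sg = set@sg, cb = set@cb)
  es <- coulombEnergy(cf, pk, scoringConfig(pk))
  lj <- ljEnergy(cf, pk, scoringConfig(pk))
  onlyVdw <- scoringConfig(pk, wEs = 0, wVdw = 1)
  expect_equal(scoreConformer(cf, pk, onlyVdw)$total, lj, tolerance = 1e-12)
  both <- scoringConfig(pk, wEs = 2, wVdw = 0.5)
  expect_equal(scoreConformer(cf, pk, both)$total, 2 * es + 0.5 * lj,
               tolerance = 1e-9)
})

test_that("vectorized set scoring agrees with per-conformer scoring", {
  pk <- stdPocket(2)
  set <- enumerateConformers(anchoredIn(pk)$start, 120)
  sc <- scoreConformerSet(set, pk)
  for (k in c(1L, 7L, 20L, conformerCount(set))) {
    cf <- new("Conformer", coords = set@coords[, , k],
              torsions = set@torsions[k, ], rotatable = set@rotatable,
              anchored = set@anchored, sg = set@sg, cb = set@cb)
    one <- scoreConformer(cf, pk, scoringConfig(pk))
    expect_equal(sc$electrostatic[k], one$electrostatic, tolerance = 1e-8)
    expect_equal(sc$vdw[k], one$vdw, tolerance = 1e-8)
  }
})

test_that("energies are invariant under rigid motion of the whole system", {
  set.seed(7)
  lxyz <- matrix(runif(12, -3, 3), 4, 3)
  pxyz <- matrix(runif(18, 4, 9), 6, 3)
  lig <- bareLigand(q = runif(4, -0.3, 0.3))
  cfg <- openConfig(dielectric = 2)
  pk1 <- barePocket(pxyz, q = runif(6, -0.3, 0.3))
  e1 <- coulombEnergy(lxyz, pk1, cfg, ligand = lig)
  v1 <- ljEnergy(lxyz, pk1, cfg, ligand = lig)
  th <- 0.9
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  shift <- c(5, -3, 2)
  move <- function(m) m %*% R + rep(shift, each = nrow(m))
  pk2 <- barePocket(move(pxyz), q = atoms(pk1)$charge)
  expect_equal(coulombEnergy(move(lxyz), pk2, cfg, ligand = lig), e1,
               tolerance = 1e-8)
  expect_equal(ljEnergy(move(lxyz), pk2, cfg, ligand = lig), v1,
               tolerance = 1e-8)
})

test_that("Coulomb term is antisymmetric in the ligand charges", {
  set.seed(8)
  lxyz <- matrix(runif(9, -2, 2), 3, 3)
  pxyz <- matrix(runif(15, 3, 8), 5, 3)
  lq <- runif(3, -0.4, 0.4); pq <- runif(5, -0.4, 0.4)
  cfg <- openConfig(dielectric = 3)
  e <- coulombEnergy(lxyz, barePocket(pxyz, q = pq), cfg,
                     ligand = bareLigand(q = lq))
  eNegAll <- coulombEnergy(lxyz, barePocket(pxyz, q = -pq), cfg,
                           ligand = bareLigand(q = -lq))
  eNegLig <- coulombEnergy(lxyz, barePocket(pxyz, q = pq), cfg,
                           ligand = bareLigand(q = -lq))
  expect_equal(eNegAll, e, tolerance = 1e-10)
  expect_equal(eNegLig, -e, tolerance = 1e-10)
})

test_that("bestScore takes the minimum total with first-index tie break", {
  pk <- stdPocket(1)
  set <- enumerateConformers(anchoredIn(pk)$start, 120)
  sc <- scoreConformerSet(set, pk)
  best <- bestScore(set, pk)
  expect_equal(best$total, min(sc$total))
  expect_equal(best$conformer_index, which.min(sc$total))

  dup <- set
  dup@coords <- set@coords[, , c(1, 1), drop = FALSE]
  dup@torsions <- set@torsions[c(1, 1), , drop = FALSE]
  expect_equal(bestScore(dup, pk)$conformer_index, 1L)

  empty <- set
  empty@coords <- set@coords[, , 0, drop = FALSE]
  empty@torsions <- set@torsions[0, , drop = FALSE]
  expect_error(bestScore(empty, pk), class = "cyslock_value_error")
})

test_that("unparameterized inputs are scoring errors", {
  s <- readStructure(makeToyPocket(1))
  raw <- extractPocket(s, findAnchor(s, "A", 107), 10)
  lig <- bareLigand(q = 0)
  expect_error(coulombEnergy(matrix(0, 1, 3), raw, openConfig(),
                             ligand = lig),
               class = "cyslock_scoring_error")
})
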