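test_that("formula parsing and masses follow IUPAC values", {
  expect_equal(formulaMass("H2O"), 18.010565, tolerance = 1e-3)
  expect_equal(formulaMass(""), 0.0)
  expect_equal(formulaMass("CH4", "average"), 12.011 + 4 * 1.008,
               tolerance = 1e-6)
  expect_error(formulaMass("Qq2"), class = "cyslock_value_error")
  expect_error(parseFormula("12C"), class = "cyslock_value_error")
  expect_identical(formatFormula(parseFormula("C12H10SO4")), "C12H10O4S")

  # additivity over merged counts
  set.seed(11)
  els <- c("C", "H", "N", "O", "S")
  for (rep in 1:10) {
    fa <- setNames(sample(1:9, 3), sample(els, 3))
    fb <- setNames(sample(1:9, 3), sample(els, 3))
    merged <- tapply(c(fa, fb), c(names(fa), names(fb)), sum)
    expect_equal(formulaMass(fa) + formulaMass(fb),
                 formulaMass(setNames(as.integer(merged), names(merged))),
                 tolerance = 1e-9)
  }
})

test_that("tryptic digestion cleaves after K/R except before P", {
  d <- trypticDigest("AAKRCC")
  expect_identical(d$sequence, c("AAK", "R", "CC"))
  expect_equal(d$start, c(1L, 4L, 5L))
  expect_equal(d$end, c(3L, 4L, 6L))

  expect_identical(trypticDigest("AKPR")$sequence, "AKPR")

  d1 <- trypticDigest("AAKRCC", maxMissed = 1)
  expect_true(all(c("AAKR", "RCC") %in% d1$sequence))
  expect_equal(d1$missed_cleavages[d1$sequence == "AAKR"], 1L)

  expect_error(trypticDigest("AAB"), class = "cyslock_value_error")

  # zero-missed peptides concatenate back to the parent
  set.seed(12)
  for (rep in 1:10) {
    s <- paste(sample(names(cyslock:::RESIDUE_FORMULA), 60, replace = TRUE),
               collapse = "")
    d0 <- trypticDigest(s)
    expect_identical(paste(d0$sequence[d0$missed_cleavages == 0],
                           collapse = ""), s)
  }
})

test_that("peptide masses are residue-additive plus water", {
  expect_equal(peptideMass("G"), formulaMass("C2H5NO2"), tolerance = 1e-9)
  expect_equal(peptideMass("GG"),
               2 * formulaMass("C2H3NO") + formulaMass("H2O"),
               tolerance = 1e-9)
  expect_error(peptideMass("GZ"), class = "cyslock_value_error")
})

test_that("adduct matching resolves candidates at ppm tolerance", {
  base <- peptideMass("HFCPNVPIILVGNK")
  hits <- matchAdduct(250.0299, c("C12H10SO4", "C12H12SO4"), 10, base)
  expect_equal(nrow(hits), 1L)
  expect_identical(hits$formula, "C12H10SO4")

  expect_equal(nrow(matchAdduct(0.0, c("C12H10SO4", "H2O"), 10, base)), 0L)

  two <- matchAdduct(250.0299, c("C12H10SO4", "C12H10SO4"), 10, base)
  expect_equal(nrow(two), 2L)
  expect_identical(two$formula, c("C12H10SO4", "C12H10SO4"))

  expect_error(matchAdduct(1, "H2O", -5, base), class = "cyslock_value_error")
  expect_error(matchAdduct(1, "H2O", 10, 0), class = "cyslock_value_error")
})

test_that("CSP combines proton and weighted nitrogen shifts", {
  apo <- data.frame(residue = 1:3, h_ppm = c(8.0, 8.5, 7.9),
                    n_ppm = c(120, 118, 125), intensity = 1)
  same <- computeCSP(apo, apo)
  expect_equal(same$csp, rep(0, 3))
  expect_false(any(same$attenuated))

  bound <- apo
  bound$h_ppm[2] <- apo$h_ppm[2] + 0.03
  bound$n_ppm[2] <- apo$n_ppm[2] - 0.2
  rec <- computeCSP(apo, bound)
  expect_equal(rec$csp[2], 0.05, tolerance = 1e-12)

  # swapping apo and bound leaves magnitudes unchanged
  expect_equal(computeCSP(bound, apo)$csp, rec$csp, tolerance = 1e-12)

  # disappeared peak: attenuated with undefined CSP
  gone <- bound[-3, ]
  rec2 <- computeCSP(apo, gone)
  expect_true(rec2$attenuated[rec2$residue == 3])
  expect_true(is.na(rec2$csp[rec2$residue == 3]))

  weak <- apo
  weak$intensity[1] <- 0.1
  expect_true(computeCSP(apo, weak)$attenuated[1])

  dup <- rbind(apo, apo[1, ])
  expect_error(computeCSP(dup, bound), class = "cyslock_value_error")
  expect_error(computeCSP(apo[0, ], bound[0, ]),
               class = "cyslock_value_error")
})

test_that("perturbation classification is strict at the threshold", {
  rec <- data.frame(residue = c(5L, 6L, 7L, 10L, 12L, 13L, 20L),
                    csp = c(0.2, 0.1, 0.06, 0.050, 0.051, 0.2, 0.01),
                    attenuated = c(rep(FALSE, 6), TRUE))
  out <- classifyPerturbations(rec, threshold = 0.05)
  # residue 10 at exactly 0.050 is NOT perturbed; attenuated residue 20 is
  expect_false(10 %in% out$perturbed)
  expect_true(20 %in% out$perturbed)
  expect_equal(out$perturbed, c(5L, 6L, 7L, 12L, 13L, 20L))
  expect_equal(out$segments$start, c(5L, 12L, 20L))
  expect_equal(out$segments$end, c(7L, 13L, 20L))

  none <- classifyPerturbations(
    data.frame(residue = 1:3, csp = 0, attenuated = FALSE))
  expect_equal(length(none$perturbed), 0L)
  expect_equal(nrow(none$segments), 0L)
})

test_that("peak lists round-trip through TSV", {
  pl <- makePeakLists(5, nResidues = 30, perturbedRanges = list(c(5L, 9L)))
  tmp <- tempfile()
  writePeakList(pl$apo, tmp)
  back <- readPeakList(tmp)
  expect_equal(back$h_ppm, pl$apo$h_ppm, tolerance = 1e-4)
  expect_equal(back$residue, pl$apo$residue)
})

test_that("the packaged RhoA digest contains the anchor-spanning peptide", {
  f <- system.file("extdata", "rhoa_human.fasta", package = "cyslock")
  seqc <- paste(readLines(f)[-1], collapse = "")
  expect_equal(nchar(seqc), 193L)
  expect_identical(substr(seqc, 107, 107), "C")
  d <- trypticDigest(seqc)
  hit <- d[d$sequence == "HFCPNVPIILVGNK", ]
  expect_equal(nrow(hit), 1L)
  expect_true(hit$start <= 107 && 107 <= hit$end)
})
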