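test_that("backbone contacts involve both flanking residues", {
  ann <- tinyAnnotations("GAFGAGAGFG",
    rbind(tinyContactRow(3, 7, catA = "backbone", catB = "backbone",
                         typeA = "FG", typeB = "GF")))
  inv <- involvementFrequency(ann)
  hit <- PiPiContacts:::involvedResidues(annotationContacts(ann))
  expect_setequal(hit$resIndex, c(3, 4, 7, 8))
  expect_equal(attr(inv, "overall"), 4 / 10)
})

test_that("a fully stacked fixture has involvement frequency 1 everywhere", {
  ann <- tinyAnnotations("FYFY",
    rbind(tinyContactRow(1, 3, typeA = "F", typeB = "F"),
          tinyContactRow(2, 4, typeA = "Y", typeB = "Y")))
  inv <- involvementFrequency(ann)
  expect_true(all(inv$frequency[inv$total > 0] == 1))
  expect_equal(attr(inv, "overall"), 1)
})

test_that("involvement survives an annotation file round trip", {
  shared <- sharedPredictor()
  ann <- shared$ann
  fc <- tempfile(fileext = ".tsv")
  fch <- tempfile(fileext = ".tsv")
  writeContactAnnotations(ann, fc, fch)
  ann2 <- readContactAnnotations(fc, fch)
  expect_equal(involvementFrequency(ann2), involvementFrequency(ann),
               ignore_attr = FALSE)
  expect_equal(contactsPer100(ann2), contactsPer100(ann))
})

test_that("per-100 rates are participations over residues and partition", {
  # 50 residues, 5 group participations in 'all'
  seq50 <- paste(rep("A", 50), collapse = "")
  ann <- tinyAnnotations(seq50,
    rbind(tinyContactRow(1, 10, typeA = "F", typeB = "Y"),
          tinyContactRow(20, 30, typeA = "R", typeB = "Q"),
          tinyContactRow(40, 45, typeA = "F", typeB = "N")))
  expect_equal(contactsPer100(ann, "all"), 100 * 6 / 50)
  # partition identity: the three aromaticity classes sum to 'all'
  classes <- c("aromatic_aromatic", "aromatic_nonaromatic",
               "nonaromatic_nonaromatic")
  expect_equal(sum(vapply(classes, function(cl) contactsPer100(ann, cl),
                          numeric(1))),
               contactsPer100(ann, "all"))
  shared <- sharedPredictor()
  expect_equal(sum(vapply(classes, function(cl)
    contactsPer100(shared$ann, cl), numeric(1))),
    contactsPer100(shared$ann, "all"))
  # hand count on the 3-contact fixture
  expect_equal(contactsPer100(ann, "aromatic_aromatic"), 100 * 2 / 50)
  expect_equal(contactsPer100(ann, "aromatic_nonaromatic"), 100 * 2 / 50)
  expect_equal(contactsPer100(ann, "nonaromatic_nonaromatic"), 100 * 2 / 50)
})

resolutionFixture <- function(resolutions) {
  chains <- data.frame(
    chainKey = sprintf("P%04d_A", seq_along(resolutions)),
    sequence = "GGGG", resolution = resolutions, rFactor = NA_real_,
    pdbId = sprintf("P%04d", seq_along(resolutions)),
    stringsAsFactors = FALSE)
  chainAnnotations(chains)
}

test_that("resolution binning follows the roll-small-bins rule", {
  two <- resolutionBins(resolutionFixture(c(rep(1.5, 200), rep(2.0, 150))))
  expect_equal(nrow(two), 2L)
  expect_equal(two$n, c(200L, 150L))
  expect_equal(two$resolution, c(1.5, 2.0))
  merged <- resolutionBins(resolutionFixture(c(rep(1.5, 99), rep(1.6, 99))))
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$n, 198L)
  expect_equal(merged$resolution, stats::weighted.mean(c(1.5, 1.6),
                                                       c(99, 99)))
  # bins conserve the input count
  set.seed(8)
  res <- round(runif(700, 1.0, 3.0), 2)
  bins <- resolutionBins(resolutionFixture(res))
  expect_equal(sum(bins$n), 700L)
  expect_true(all(diff(bins$resolution) > 0))
})

test_that("weighted fits reproduce closed-form solutions", {
  exact <- weightedLinearFit(data.frame(resolution = c(1, 2, 3),
                                        rate = 2 - 0.5 * c(1, 2, 3),
                                        n = c(50, 100, 25)))
  expect_equal(exact$slope, -0.5, tolerance = 1e-12)
  expect_equal(exact$intercept, 2, tolerance = 1e-12)
  expect_equal(abs(exact$r), 1, tolerance = 1e-9)
  # equal weights reduce to ordinary least squares
  b <- data.frame(resolution = c(1, 1.5, 2.2, 3), rate = c(5, 4, 4.5, 2),
                  n = rep(10, 4))
  wf <- weightedLinearFit(b)
  ols <- stats::coef(lm(rate ~ resolution, data = b))
  expect_equal(wf$slope, unname(ols[2]))
  expect_equal(wf$intercept, unname(ols[1]))
  # 3-bin weighted case against hand-solved normal equations
  b3 <- data.frame(resolution = c(1.2, 1.8, 2.6), rate = c(6.1, 5.0, 3.2),
                   n = c(120, 300, 80))
  w <- b3$n; x <- b3$resolution; y <- b3$rate
  sw <- sum(w); sx <- sum(w * x); sy <- sum(w * y)
  sxx <- sum(w * x^2); sxy <- sum(w * x * y)
  slope <- (sw * sxy - sx * sy) / (sw * sxx - sx^2)
  intercept <- (sy - slope * sx) / sw
  wf3 <- weightedLinearFit(b3)
  expect_equal(wf3$slope, slope, tolerance = 1e-12)
  expect_equal(wf3$intercept, intercept, tolerance = 1e-12)
  expect_error(weightedLinearFit(b3[1, ]), "at least 2")
})

test_that("block bootstrap SEM matches the analytic SEM of a mean", {
  set.seed(9)
  vals <- rnorm(30, mean = 2, sd = 0.6)
  chains <- data.frame(chainKey = sprintf("B%02d_A", 1:30), sequence = "G",
                       resolution = vals, rFactor = NA_real_,
                       pdbId = sprintf("B%02d", 1:30),
                       stringsAsFactors = FALSE)
  ann <- chainAnnotations(chains)
  statistic <- function(a) mean(annotationChains(a)$resolution)
  sem <- blockBootstrapSEM(statistic, ann, nIter = 10000, seed = 5)
  analytic <- sd(vals) / sqrt(30)
  expect_lt(abs(sem - analytic) / analytic, 0.05)
  # constant statistic has zero SEM; fixed seed reproduces bitwise
  expect_equal(blockBootstrapSEM(function(a) 1, ann, nIter = 50, seed = 1), 0)
  expect_identical(blockBootstrapSEM(statistic, ann, nIter = 200, seed = 7),
                   blockBootstrapSEM(statistic, ann, nIter = 200, seed = 7))
  one <- chainAnnotations(chains[1, ])
  expect_warning(s1 <- blockBootstrapSEM(statistic, one, nIter = 10),
                 "single-PDB")
  expect_equal(s1, 0)
})

test_that("solvation profiles recover the generating slope", {
  sim <- makeStatsAnnotations(nChains = 25, chainLength = 250, seed = 31,
                              base = 0.05, waterSlope = 0.012, waterMean = 4)
  prof <- solvationProfile(sim$annotations)
  fit <- lm(anyFreq ~ waterCount, data = prof, weights = prof$n)
  slope <- unname(coef(fit)[2])
  se <- summary(fit)$coefficients[2, 2]
  expect_gt(slope, 0)
  expect_lt(abs(slope - 0.012), 4 * se + 0.004)
  # chains below the >1 water-per-residue threshold are excluded
  dry <- sim$annotations
  res <- annotationResidues(dry)
  res$waterCount[res$chainKey == "SIM0001_A"] <- 0L
  dry@residues <- res
  profDry <- solvationProfile(dry)
  expect_equal(sum(profDry$n), sum(prof$n) - 250)
})

test_that("all-water-zero annotations land in the zero bin", {
  ann <- tinyAnnotations("GGGGG")
  res <- annotationResidues(ann)
  res$waterCount <- 0L
  ann@residues <- res
  # direct residue binning (threshold disabled)
  prof <- solvationProfile(ann, minWaterPerResidue = -1)
  expect_equal(prof$waterCount, 0L)
  expect_equal(prof$n, 5L)
})

test_that("secondary-structure distances match a brute-force scan", {
  set.seed(13)
  for (k in 1:20) {
    ss <- sample(c("H", "G", "E", "-", "T", "S"), 40, replace = TRUE)
    pos <- PiPiContacts:::ssSignedPositions(ss, cap = 7L)
    ordered <- ss %in% c("H", "G", "E")
    for (i in seq_along(ss)) {
      dOrd <- if (any(ordered)) min(abs(i - which(ordered))) else Inf
      dLoop <- if (any(!ordered)) min(abs(i - which(!ordered))) else Inf
      want <- if (ordered[i]) -min(dLoop, 8) else min(dOrd, 8)
      expect_equal(pos[i], want)
    }
  }
})

test_that("an all-helix chain occupies a single profile bin", {
  ann <- tinyAnnotations("GGGGGGGG")
  res <- annotationResidues(ann)
  res$ss <- "H"
  ann@residues <- res
  prof <- ssDistanceProfile(ann)
  expect_equal(nrow(prof), 1L)
  expect_equal(prof$position, -8)
  expect_equal(prof$n, 8L)
})

test_that("the order-disorder sigmoid endpoints are recovered", {
  sim <- makeStatsAnnotations(nChains = 50, chainLength = 250, seed = 17,
                              ssEndpoints = c(0.095, 0.16))
  prof <- ssDistanceProfile(sim$annotations)
  deepSS <- prof[prof$position == -8, ]
  deepLoop <- prof[prof$position == 8, ]
  ciSS <- 3 * sqrt(0.095 * 0.905 / deepSS$n)
  ciLoop <- 3 * sqrt(0.16 * 0.84 / deepLoop$n)
  expect_lt(abs(deepSS$frequency - 0.095), ciSS)
  expect_lt(abs(deepLoop$frequency - 0.16), ciLoop)
  expect_gt(deepLoop$frequency, deepSS$frequency)
})

test_that("interface breakdowns partition and detect intra-inter exchange", {
  ann <- tinyAnnotations("AYAAAAAAAA",
    rbind(tinyContactRow(2, 5, typeA = "Y", typeB = "Y",
                         chainClass = "inter_asu", keyB = "T2_A")))
  res <- annotationResidues(ann)
  res$interfaceClass[2] <- "inter_asu"
  ann@residues <- res
  bd <- interfaceBreakdown(ann)
  yline <- bd[bd$identity == "Y" & bd$interfaceClass == "inter_asu", ]
  expect_equal(yline$inter, 1)
  expect_equal(yline$total, yline$local + yline$nonlocalIntra + yline$inter)
  sim <- makeStatsAnnotations(nChains = 30, chainLength = 250, seed = 23,
                              base = 0.2, interfaceExchange = 0.6)
  bd2 <- interfaceBreakdown(sim$annotations)
  ok <- !is.na(bd2$total) & bd2$n > 30
  expect_equal(bd2$total[ok],
               (bd2$local + bd2$nonlocalIntra + bd2$inter)[ok])
  # exchange: inter fraction rises at interfaces, totals stay comparable
  agg <- function(cls, col) {
    sel <- bd2$interfaceClass == cls & !is.na(bd2$total)
    stats::weighted.mean(bd2[[col]][sel], bd2$n[sel])
  }
  expect_gt(agg("inter_asu", "inter") + agg("symmetry", "inter"),
            2 * agg("none", "inter"))
  expect_lt(abs(agg("inter_asu", "total") - agg("none", "total")),
            0.35 * agg("none", "total"))
})

test_that("sp3 control fractions match hand enumeration", {
  # a Gly-Gly peptide unit in the z = 0 plane plus a Leu terminal plane
  # parallel to it 3.4 A above: the only Leu-backbone VDW contact is planar
  gg <- makeIdealPeptide("GG", withOXT = FALSE)
  a <- gg@atoms
  over <- colMeans(as.matrix(a[a$elety %in% c("C", "O", "N"),
                               c("x", "y", "z")]))
  leu <- data.frame(
    elety = c("CG", "CD1", "CD2"), alt = "", resid = "LEU", chain = "A",
    resno = 10L, insert = "",
    x = over[1] + c(0, 1.3, -0.6), y = over[2] + c(0, 0, 1.1),
    z = 3.4, o = 1, elesy = "C", isWater = FALSE, isH = FALSE,
    resIndex = 10L, stringsAsFactors = FALSE)
  gg@atoms <- rbind(a, leu)
  fr <- backbonePlanarFractions(gg)
  enr <- sp3ControlEnrichment(fr)
  leuRow <- enr[enr$identity == "L" & enr$class == "sp3", ]
  expect_equal(leuRow$nVdw, 1L)
  expect_equal(leuRow$fraction, 1.0)
  expect_true(all(enr$fraction >= 0 & enr$fraction <= 1))
  # tilting the Leu plane far past the alignment threshold drops the
  # planar fraction to 0 while the VDW denominator stays
  tilted <- gg
  sel <- tilted@atoms$resid == "LEU"
  tilted@atoms$z[sel] <- 3.4 + c(0, 1.3, -1.1)  # ~45 degree plane
  enr2 <- sp3ControlEnrichment(backbonePlanarFractions(tilted))
  leu2 <- enr2[enr2$identity == "L" & enr2$class == "sp3", ]
  expect_equal(leu2$nVdw, 1L)
  expect_equal(leu2$fraction, 0)
  # identities with zero denominators are omitted with a warning
  expect_warning(
    sp3ControlEnrichment(data.frame(identity = c("F", "L"),
                                    class = c("sp2", "sp3"),
                                    nVdw = c(3L, 0L),
                                    nPlanar = c(2L, 0L))),
    "zero VDW")
})
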