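ringPair <- function(gap, offset = 0, tilt = 0) {
  gs <- extractSp2Groups(makeStackedPair(gap = gap, offset = offset,
                                         tilt = tilt))
  list(a = groupCoords(gs)[[1]], na = groupNormals(gs)[1, ],
       b = groupCoords(gs)[[2]], nb = groupNormals(gs)[2, ])
}

test_that("VDW pair counting matches brute force on stacked rings", {
  p <- ringPair(3.6)
  expect_equal(countVdwPairs(p$a, p$b), 36L)  # all 36 pairs within 4.9 A
  # independent brute force over the 36 distances
  brute <- sum(as.matrix(dist(rbind(p$a, p$b)))[1:6, 7:12] <= 4.9)
  expect_equal(countVdwPairs(p$a, p$b), brute)
  expect_equal(countVdwPairs(ringPair(10)$a, ringPair(10)$b), 0L)
})

test_that("groups sharing an atom return the shared-atom sentinel", {
  gs <- extractSp2Groups(makeIdealPeptide("GGG", withOXT = FALSE))
  g <- groupTable(gs)
  expect_equal(nrow(g), 2L)  # two adjacent peptide units sharing CA(2)
  k1 <- PiPiContacts:::groupAtomKeys(rownames(groupCoords(gs)[[1]]),
                                     g$chain[1], g$resIndex[1])
  k2 <- PiPiContacts:::groupAtomKeys(rownames(groupCoords(gs)[[2]]),
                                     g$chain[2], g$resIndex[2])
  expect_true(is.na(countVdwPairs(groupCoords(gs)[[1]], groupCoords(gs)[[2]],
                                  keysA = k1, keysB = k2)))
  expect_equal(nrow(contactTable(detectContacts(gs))), 0L)
})

test_that("elevated-surface distances match the defining arithmetic", {
  p34 <- ringPair(3.4)
  expect_equal(surfaceDistance(p34$a, p34$na, p34$b, p34$nb), 0,
               tolerance = 1e-9)
  p49 <- ringPair(4.9)
  expect_equal(surfaceDistance(p49$a, p49$na, p49$b, p49$nb), 1.5,
               tolerance = 1e-9)
  # coplanar side-by-side rings, nearest-atom gap 4.0: in-plane distances
  # are unchanged by elevation
  side <- ringPair(0, offset = 2 * 1.39 + 4.0)
  expect_equal(surfaceDistance(side$a, side$na, side$b, side$nb), 4.0,
               tolerance = 1e-9)
  # brute force over the four elevation sign combinations
  brute <- min(vapply(list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1)),
                      function(s) {
    ea <- sweep(side$a, 2, s[1] * 1.7 * side$na, "+")
    eb <- sweep(side$b, 2, s[2] * 1.7 * side$nb, "+")
    min(as.matrix(dist(rbind(ea, eb)))[1:6, 7:12])
  }, numeric(1)))
  expect_equal(surfaceDistance(side$a, side$na, side$b, side$nb), brute)
})

test_that("the contact decision applies all three criteria inclusively", {
  p <- ringPair(3.5)
  expect_true(isPlanarPiContact(p$a, p$na, p$b, p$nb)$contact)
  tilted <- ringPair(3.5, tilt = 40)
  res <- isPlanarPiContact(tilted$a, tilted$na, tilted$b, tilted$nb)
  expect_false(res$contact)
  expect_equal(res$absDot, cos(40 * pi / 180), tolerance = 1e-9)
  # |dot| exactly at the 0.8 boundary is accepted (other criteria met)
  atBoundary <- isPlanarPiContact(p$a, c(0, 0, 1), p$b, c(0, 0.6, 0.8))
  expect_equal(atBoundary$absDot, 0.8)
  expect_true(atBoundary$contact)
  justUnder <- isPlanarPiContact(p$a, c(0, 0, 1), p$b,
                                 c(0, sqrt(1 - 0.799^2), 0.799))
  expect_false(justUnder$contact)
  # inclusive VDW boundary with exactly representable distances (3-4-5)
  a <- matrix(c(0, 0, 0, 1, 0, 0), 2, 3, byrow = TRUE,
              dimnames = list(c("C1", "C2"), NULL))
  b <- matrix(c(3, 4, 0, 4, 4, 0), 2, 3, byrow = TRUE,
              dimnames = list(c("C3", "C4"), NULL))
  expect_equal(countVdwPairs(a, b, cutoff = 5), 3L)  # pairs at 5, 5, sqrt(20), sqrt(32)
})

test_that("detection equals the brute-force all-pairs oracle on random fields", {
  for (seed in 1:25) {
    gs <- makeRandomGroupField(nGroups = 30, box = 28, seed = seed)
    expect_equal(detectedContactPairs(detectContacts(gs)),
                 bruteForceContactPairs(gs))
  }
  # a denser field exercises the neighbor prefilter harder
  gs <- makeRandomGroupField(nGroups = 120, box = 35, seed = 99)
  expect_equal(detectedContactPairs(detectContacts(gs)),
               bruteForceContactPairs(gs))
})

test_that("contact decisions are invariant under rigid motion", {
  gs <- makeRandomGroupField(nGroups = 50, box = 30, seed = 3)
  ref <- detectedContactPairs(detectContacts(gs))
  set.seed(21)
  for (k in 1:10) {
    R <- PiPiContacts:::randomRotation()
    t <- runif(3, -50, 50)
    expect_equal(detectedContactPairs(detectContacts(applyRigidMotion(gs, R, t))),
                 ref)
  }
})

test_that("loosening any threshold never removes a contact", {
  gs <- makeRandomGroupField(nGroups = 60, box = 26, seed = 5)
  base <- contactCriteria()
  ref <- detectedContactPairs(detectContacts(gs, base))
  looser <- list(
    contactCriteria(vdwCutoff = 5.4),
    contactCriteria(minAtomPairs = 1),
    contactCriteria(surfaceCutoff = 2.0),
    contactCriteria(minAbsDot = 0.6))
  for (cr in looser)
    expect_true(all(ref %in% detectedContactPairs(detectContacts(gs, cr))))
})

test_that("contacts classify by chain and sequence separation", {
  intra <- contactTable(detectContacts(makeStackedPair(gap = 3.5)))
  expect_equal(nrow(intra), 1L)
  expect_equal(intra$chainClass, "intra")
  expect_equal(intra$rangeClass, "long")
  expect_equal(intra$seqSeparation, 20)
  inter <- contactTable(detectContacts(makeStackedPair(gap = 3.5,
                                                       sameChain = FALSE)))
  expect_equal(inter$chainClass, "inter_asu")
  expect_equal(inter$seqSeparation, Inf)
  expect_equal(inter$rangeClass, "long")
  short <- makeStackedPair(gap = 3.5)
  short@atoms$resno[short@atoms$resno == 30] <- 13
  short@atoms$resIndex <- NULL
  short@atoms$resIndex <- ave(short@atoms$resno, short@atoms$chain,
                              FUN = function(r) r - min(r) + 1)
  expect_equal(contactTable(detectContacts(short))$rangeClass, "short")
})

test_that("symmetry contacts are flagged separately and clashes counted", {
  # operator -X,Y,-Z maps a ring in the z = -1.75 plane onto a stacked image
  # 3.5 A above it
  m <- makeIdealPeptide("F", withOXT = FALSE)
  m@atoms <- m@atoms[m@atoms$elety %in%
                       c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"), ]
  ring <- extractSp2Groups(m)
  ctr <- colMeans(groupCoords(ring)[[1]])
  m@atoms$x <- m@atoms$x - ctr[1]
  m@atoms$y <- m@atoms$y - ctr[2]
  m@atoms$z <- m@atoms$z - ctr[3] - 1.75
  m@unitCell <- c(50, 50, 50, 90, 90, 90)
  M <- PiPiContacts:::cellOrthMatrix(m@unitCell)
  m@symmetryOps <- list(list(R = diag(3), t = numeric(3)),
                        list(R = diag(c(-1, 1, -1)), t = numeric(3)))
  ct <- detectContacts(m)
  tab <- contactTable(ct)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$chainClass, "symmetry")
  # same ring centered on the rotation axis clashes with its own image
  m2 <- m
  m2@atoms$z <- m2@atoms$z + 1.75
  ct2 <- detectContacts(m2)
  expect_gt(ct2@clashes, 0L)
})

test_that("water contact counting is inclusive and symmetry-aware", {
  base <- makeIdealPeptide("Y")
  expect_equal(waterContactCount(base, "A", 1L), 0L)
  wet <- addWaterShell(base, 11, rmin = 3, rmax = 4, seed = 4)
  expect_equal(waterContactCount(wet, "A", 1L), 11L)
  # boundary water: 3-4-5 right triangle from a single-atom residue is
  # counted at cutoff 5 (inclusive) and dropped just under it
  one <- PiPiContacts:::structureFromAtoms(
    elety = "CA", resid = "GLY", chain = "A", resno = 1L,
    xyz = matrix(c(0, 0, 0), 1, 3))
  wat <- one@atoms[1, ]
  wat$elety <- "O"; wat$elesy <- "O"; wat$resid <- "HOH"
  wat$chain <- "W"; wat$resno <- 1000; wat$isWater <- TRUE
  wat$resIndex <- NA_integer_
  wat$x <- 3; wat$y <- 4; wat$z <- 0
  one@atoms <- rbind(one@atoms, wat)
  expect_equal(waterContactCount(one, "A", 1L, cutoff = 5), 1L)
  expect_equal(waterContactCount(one, "A", 1L, cutoff = 4.99), 0L)
})
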