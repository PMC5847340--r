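# Hand-built 5-residue profile for attachment tests: one sidechain group at
# position 3, backbone units at 1..4.
toyProfile <- function() {
  prof <- data.frame(
    position = c(3L, 1L, 2L, 3L, 4L),
    identity = c("F", "GF", "FG", "GF", "FG"),
    category = c("sidechain", rep("backbone", 4)),
    carbonCount = c(6L, rep(3L, 4)),
    stringsAsFactors = FALSE)
  for (ch in PiPiContacts:::PSCORE_CHANNELS) prof[[ch]] <- 0
  prof$long_bb_abs <- c(10, 1, 2, 3, 4)
  new("ContactProfile", sequence = "GFGFG", profile = prof)
}

test_that("attachment of group values to residues matches hand assignment", {
  v <- componentValues(toyProfile(), "long_bb_abs")
  # residue 1: unit 1 only; residue 2: units 1 and 2; residue 3: units 2, 3
  # and the sidechain group; residue 4: units 3, 4; residue 5: unit 4
  expect_equal(v, c(1, (1 + 2) / 2, (2 + 3 + 10) / 3, (3 + 4) / 2, 4))
  # carbon modulation multiplies each group value by its carbon count
  vc <- componentValues(toyProfile(), "long_bb_abs", carbon = TRUE)
  expect_equal(vc, c(3, (3 + 6) / 2, (6 + 9 + 60) / 3, (9 + 12) / 2, 12))
  # a channel with all-zero values stays zero
  expect_equal(componentValues(toyProfile(), "short_sc_abs"), rep(0, 5))
})

test_that("window aggregation matches enumeration", {
  expect_equal(windowAggregate(rep(2.5, 30), window = 7), 2.5)
  expect_equal(windowAggregate(rep(2.5, 30), window = 7, mode = "topk"), 2.5)
  spike <- c(rep(0, 50), 6, rep(0, 49))
  expect_equal(windowAggregate(spike, window = 10), 6 / 10)
  expect_error(windowAggregate(rep(1, 5), window = 10), "shorter")
  # top-k expansion equals brute-force enumeration on a random track
  set.seed(3)
  x <- rnorm(200)
  got <- windowAggregate(x, mode = "topk", k = 60, expand = 5)
  top <- order(x, decreasing = TRUE)[1:60]
  sel <- sort(unique(unlist(lapply(top, function(i)
    max(1, i - 5):min(200, i + 5)))))
  expect_equal(got, mean(x[sel]))
})

test_that("the background set z-scores to mean 0 and sd 1 under its model", {
  shared <- sharedPredictor()
  sets <- makeSequenceSets(nPositive = 6, nBackground = 40,
                           lengthRange = c(150, 220), seed = 12)
  model <- pscoreModel(weights = c(0, 0, 0, 1, 0, 0, 0, 0.5))
  raw <- scoreSequences(sets$background, model, shared$table,
                        shared$calibration)
  m2 <- pscoreModel(weights = c(0, 0, 0, 1, 0, 0, 0, 0.5),
                    bgMean = mean(raw$raw), bgSd = sd(raw$raw))
  z <- scoreSequences(sets$background, m2, shared$table,
                      shared$calibration)
  expect_equal(mean(z$pscore), 0, tolerance = 1e-12)
  expect_equal(sd(z$pscore), 1, tolerance = 1e-12)
})

test_that("sequences under 140 residues are refused, never scored silently", {
  shared <- sharedPredictor()
  model <- pscoreModel(weights = 1)
  expect_error(pscore(strrep("G", 139), model, shared$table,
                      shared$calibration),
               "too short")
  out <- scoreSequences(c(a = strrep("GA", 80), b = strrep("G", 100)),
                        model, shared$table, shared$calibration)
  expect_equal(out$id, "a")
  expect_equal(attr(out, "skipped"), "b")
  expect_error(scoreSequences(c(a = strrep("G", 100)), model, shared$table,
                              shared$calibration, skipShort = FALSE),
               "140")
})

trainedFixture <- function() {
  if (is.null(.shared$trained)) {
    shared <- sharedPredictor()
    sets <- makeSequenceSets(nPositive = 11, nBackground = 120,
                             lengthRange = c(150, 260), seed = 77)
    .shared$trained <- list(
      sets = sets,
      model = trainPScore(sets$positive, sets$background, shared$table,
                          shared$calibration, seed = 101L, plateau = 250L,
                          maxProposals = 2500L))
  }
  .shared$trained
}

test_that("training separates generator positives from background", {
  shared <- sharedPredictor()
  tr <- trainedFixture()
  model <- tr$model
  expect_true(all(diff(trainingTrace(model)) > 0))
  expect_gt(trainingTrace(model)[length(trainingTrace(model))],
            trainingTrace(model)[1])
  # positives sit above the background top-1% mean (objective > 0)
  expect_gt(trainingTrace(model)[length(trainingTrace(model))], 0)
  fresh <- makeSequenceSets(nPositive = 15, nBackground = 60,
                            lengthRange = c(150, 260), seed = 202)
  sp <- scoreSequences(fresh$positive, model, shared$table,
                       shared$calibration)
  sb <- scoreSequences(fresh$background, model, shared$table,
                       shared$calibration)
  expect_gt(rocAuc(sp$pscore, sb$pscore)$auc, 0.9)
})

test_that("training is deterministic under a fixed seed", {
  shared <- sharedPredictor()
  sets <- makeSequenceSets(nPositive = 5, nBackground = 100,
                           lengthRange = c(150, 200), seed = 9)
  m1 <- trainPScore(sets$positive, sets$background, shared$table,
                    shared$calibration, seed = 31L, plateau = 60L,
                    maxProposals = 400L)
  m2 <- trainPScore(sets$positive, sets$background, shared$table,
                    shared$calibration, seed = 31L, plateau = 60L,
                    maxProposals = 400L)
  expect_identical(modelComponents(m1), modelComponents(m2))
  expect_identical(trainingTrace(m1), trainingTrace(m2))
  expect_identical(backgroundMoments(m1), backgroundMoments(m2))
})

test_that("null positives drawn from the background yield no separation", {
  shared <- sharedPredictor()
  sets <- makeSequenceSets(nPositive = 1, nBackground = 140,
                           lengthRange = c(150, 200), seed = 55)
  bg <- as.character(sets$background)
  model <- trainPScore(bg[1:8], bg[9:140], shared$table,
                       shared$calibration, seed = 19L, plateau = 80L,
                       maxProposals = 600L)
  final <- trainingTrace(model)[length(trainingTrace(model))]
  expect_lt(final, 1)  # the minimum positive cannot clear the top 1%
})

test_that("degenerate inputs are refused", {
  shared <- sharedPredictor()
  expect_error(trainPScore(character(0), rep(strrep("GA", 80), 100),
                           shared$table, shared$calibration),
               "at least one")
  expect_error(trainPScore(strrep("GA", 80), rep(strrep("GA", 80), 10),
                           shared$table, shared$calibration),
               "at least 100")
})

test_that("threshold capture counts boundary scores as captured", {
  expect_equal(thresholdCapture(rep(5, 4)), 1)
  expect_equal(thresholdCapture(c(3.9, 4.0, 4.1)), 2 / 3)
  expect_equal(thresholdCapture(c(3.9, 4.0, 4.1)),
               sum(c(3.9, 4.0, 4.1) >= 4) / 3)
  expect_error(thresholdCapture(numeric(0)), "empty")
})

test_that("raising a positively weighted channel never lowers the score", {
  comps <- modelComponents(pscoreModel(weights = c(0, 0.2, 0, 1, 0, 0, 0,
                                                   0.5)))
  rawOf <- function(prof) sum(vapply(seq_len(nrow(comps)), function(k)
    comps$weight[k] * windowAggregate(
      componentValues(prof, comps$channel[k], comps$carbon[k]),
      window = 5, mode = "max"), numeric(1)))
  prof <- toyProfile()
  set.seed(2)
  for (i in which(comps$weight > 0)) {
    prof2 <- prof
    bump <- runif(nrow(prof2@profile), 0, 0.5)
    prof2@profile[[comps$channel[i]]] <-
      prof2@profile[[comps$channel[i]]] + bump
    expect_gte(rawOf(prof2), rawOf(prof))
  }
})

test_that("models survive text serialization", {
  tr <- trainedFixture()
  f <- tempfile(fileext = ".yaml")
  writePScoreModel(tr$model, f)
  m2 <- readPScoreModel(f)
  expect_equal(modelComponents(m2), modelComponents(tr$model))
  expect_equal(backgroundMoments(m2), backgroundMoments(tr$model))
  expect_equal(trainingTrace(m2), trainingTrace(tr$model))
})
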