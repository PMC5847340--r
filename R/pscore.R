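# Stage-2 predictor: weighted sequence-window averages over the pi-contact
# profile channels, z-normalized against a background reference set
# (PScore), and the stochastic training procedure.

PSCORE_CHANNELS <- c("short_sc_abs", "short_bb_abs", "long_sc_abs",
                     "long_bb_abs", "short_sc_rel", "short_bb_rel",
                     "long_sc_rel", "long_bb_rel")
WINDOW_SET <- c(10L, 20L, 30L, 40L, 60L, 80L, 100L, 120L, 140L)
MIN_SCORE_LENGTH <- 140L

#' Construct a PScore model
#'
#' One component per profile channel; each component carries a weight, a
#' window length, an aggregation mode ("max": best contiguous-window mean;
#' "topk": mean over the top-60 residues expanded by +/- 5 positions) and a
#' flag multiplying channel values by the sp2 group's carbon count.
#'
#' @param channels profile channels to score.
#' @param weights,windows,modes,carbon per-component settings, recycled.
#' @param bgMean,bgSd background raw-score moments (PScore z-normalization).
#' @param seed,trace,meta training metadata.
#' @return a \linkS4class{PScoreModel}.
#' @export
pscoreModel <- function(channels = PSCORE_CHANNELS, weights = 0,
                        windows = 60L, modes = "max", carbon = FALSE,
                        bgMean = 0, bgSd = 1, seed = NA_integer_,
                        trace = numeric(0), meta = list()) {
  n <- length(channels)
  new("PScoreModel",
      components = data.frame(
        channel = channels,
        weight = rep_len(weights, n),
        window = as.integer(rep_len(windows, n)),
        mode = rep_len(modes, n),
        carbon = rep_len(carbon, n),
        stringsAsFactors = FALSE),
      bgMean = bgMean, bgSd = bgSd, trace = trace,
      seed = as.integer(seed), meta = meta)
}

#' Per-residue component value tracks
#'
#' Converts a group-level \linkS4class{ContactProfile} into per-residue value
#' vectors for one channel: sidechain groups attach their channel value to
#' their own residue, backbone peptide units attach theirs to both flanking
#' residues, and overlapping attachments at a residue are averaged. With
#' \code{carbon = TRUE}, group values are multiplied by the group's carbon
#' count before attachment.
#'
#' @param profile a \linkS4class{ContactProfile}.
#' @param channel one of the eight profile channels.
#' @param carbon apply carbon-count modulation.
#' @return numeric vector, one value per residue (0 where no group
#'   contributes).
#' @export
componentValues <- function(profile, channel, carbon = FALSE) {
  stopifnot(channel %in% PSCORE_CHANNELS)
  p <- profile@profile
  L <- nchar(profile@sequence)
  v <- p[[channel]]
  v[is.na(v)] <- 0
  if (carbon) v <- v * p$carbonCount
  acc <- numeric(L); nacc <- numeric(L)
  sc <- p$category == "sidechain"
  at <- p$position[sc]
  acc[at] <- acc[at] + v[sc]
  nacc[at] <- nacc[at] + 1
  bb <- which(!sc)
  for (ofs in 0:1) {
    at <- p$position[bb] + ofs
    ok <- at >= 1 & at <= L
    acc[at[ok]] <- acc[at[ok]] + v[bb][ok]
    nacc[at[ok]] <- nacc[at[ok]] + 1
  }
  out <- numeric(L)
  sel <- nacc > 0
  out[sel] <- acc[sel] / nacc[sel]
  out
}

#' Aggregate a per-residue track into a scalar
#'
#' \code{mode = "max"}: the maximum over all contiguous windows of length
#' \code{window} of the window mean. \code{mode = "topk"}: the mean over the
#' union of the top-60 residues by value expanded by five positions on each
#' side.
#'
#' @param values per-residue numeric track.
#' @param window window length (mode "max").
#' @param mode "max" or "topk".
#' @param k,expand top-k parameters (mode "topk").
#' @return scalar aggregate.
#' @export
windowAggregate <- function(values, window = 60L, mode = c("max", "topk"),
                            k = 60L, expand = 5L) {
  mode <- match.arg(mode)
  n <- length(values)
  if (mode == "max") {
    if (n < window) stop("sequence shorter than the aggregation window")
    cs <- c(0, cumsum(values))
    max((cs[(window + 1):(n + 1)] - cs[1:(n - window + 1)]) / window)
  } else {
    k <- min(k, n)
    top <- order(values, decreasing = TRUE)[seq_len(k)]
    sel <- unique(unlist(lapply(top, function(i)
      max(1L, i - expand):min(n, i + expand))))
    mean(values[sel])
  }
}

# All component tracks of one sequence (matrix L x nComponents), given the
# component table. Track computation is the expensive step; aggregates are
# cheap and cached by the trainer.
componentTracks <- function(profile, components) {
  L <- nchar(profile@sequence)
  m <- matrix(0, L, nrow(components))
  for (i in seq_len(nrow(components)))
    m[, i] <- componentValues(profile, components$channel[i],
                              components$carbon[i])
  m
}

componentAggregates <- function(tracks, components) {
  vapply(seq_len(nrow(components)), function(i)
    windowAggregate(tracks[, i], components$window[i], components$mode[i]),
    numeric(1))
}

#' Raw score and PScore of a sequence
#'
#' The raw score is the weighted sum of per-component window aggregates of
#' the sequence's contact profile; the PScore is its distance from the
#' background reference mean in background standard deviations. Sequences
#' shorter than 140 residues are refused.
#'
#' @param sequence amino-acid sequence (single string).
#' @param model a \linkS4class{PScoreModel}.
#' @param table a \linkS4class{ContactFrequencyTable}.
#' @param calibration a \linkS4class{ContactCalibration}.
#' @param id sequence identifier carried into the result.
#' @return list with \code{id}, \code{length}, \code{raw}, \code{pscore} and
#'   \code{track} (the per-residue weighted component sum).
#' @export
pscore <- function(sequence, model, table, calibration, id = "seq") {
  L <- nchar(sequence)
  if (L < MIN_SCORE_LENGTH)
    stop("sequence too short to score: ", L, " residues (minimum ",
         MIN_SCORE_LENGTH, ")")
  prof <- predictProfile(sequence, table, calibration)
  tracks <- componentTracks(prof, model@components)
  agg <- componentAggregates(tracks, model@components)
  raw <- sum(model@components$weight * agg)
  list(id = id, length = L, raw = raw,
       pscore = (raw - model@bgMean) / model@bgSd,
       track = as.numeric(tracks %*% model@components$weight))
}

#' Score a set of sequences
#'
#' @param sequences character vector or \code{Biostrings::AAStringSet}.
#' @param model,table,calibration as in \code{\link{pscore}}.
#' @param skipShort drop sequences under 140 residues (recorded in the
#'   \code{skipped} attribute) instead of erroring.
#' @return data.frame (id, length, raw, pscore), attribute \code{skipped}.
#' @export
scoreSequences <- function(sequences, model, table, calibration,
                           skipShort = TRUE) {
  nm <- names(sequences)
  seqs <- as.character(sequences)
  names(seqs) <- if (is.null(nm))
    sprintf("seq%04d", seq_along(seqs)) else nm
  short <- nchar(seqs) < MIN_SCORE_LENGTH
  if (any(short) && !skipShort)
    stop("sequences shorter than 140 residues: ",
         paste(names(seqs)[short], collapse = ", "))
  out <- do.call(rbind, lapply(which(!short), function(i) {
    s <- quietCalibrationFallback(
      pscore(seqs[i], model, table, calibration, id = names(seqs)[i]))
    data.frame(id = s$id, length = s$length, raw = s$raw,
               pscore = s$pscore, stringsAsFactors = FALSE)
  }))
  if (is.null(out))
    out <- data.frame(id = character(), length = integer(), raw = numeric(),
                      pscore = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "skipped") <- names(seqs)[short]
  out
}

#' Fraction of scores at or above the confidence threshold
#'
#' @param scores numeric PScores.
#' @param threshold confidence threshold (ties included).
#' @return fraction in [0, 1].
#' @export
thresholdCapture <- function(scores, threshold = 4.0) {
  if (!length(scores)) stop("empty score set")
  mean(scores >= threshold)
}

#' Train a PScore model
#'
#' Seeded random-restart hill climbing over component weights, window
#' lengths, aggregation modes and carbon flags, maximizing the
#' background-normalized z-score difference between the lowest-scoring
#' training positive and the mean of the highest-scoring 1 percent of the
#' background set. Background normalization is recomputed at every step so
#' the objective is always in current z units; the accepted-step objective
#' trace is non-decreasing by construction.
#'
#' @param positives character vector / AAStringSet of training positives
#'   (each at least 140 residues).
#' @param background background sequences (at least 100).
#' @param table,calibration the stage-1 predictor.
#' @param seed RNG seed.
#' @param plateau stop after this many consecutive rejected proposals.
#' @param maxProposals hard proposal cap.
#' @param weightSd standard deviation of weight perturbations.
#' @return a trained \linkS4class{PScoreModel}.
#' @export
trainPScore <- function(positives, background, table, calibration,
                        seed = 1L, plateau = 2000L, maxProposals = 20000L,
                        weightSd = 0.3) {
  pos <- as.character(positives)
  bg <- as.character(background)
  if (length(pos) < 1) stop("need at least one training positive")
  if (length(bg) < 100) stop("need at least 100 background sequences")
  if (any(nchar(c(pos, bg)) < MIN_SCORE_LENGTH))
    stop("all training sequences must have >= 140 residues")

  comps <- pscoreModel()@components
  comps$weight <- 0
  comps$weight[comps$channel == "long_bb_abs"] <- 1  # unoptimized start

  profs <- quietCalibrationFallback(lapply(c(pos, bg), function(s)
    predictProfile(s, table, calibration)))
  nPos <- length(pos)
  isPos <- seq_along(profs) <= nPos
  trackCache <- new.env(parent = emptyenv())
  getTracks <- function(ci, channel, carbon) {
    key <- paste(channel, carbon)
    hit <- trackCache[[key]]
    if (is.null(hit)) {
      hit <- lapply(profs, function(p) componentValues(p, channel, carbon))
      trackCache[[key]] <- hit
    }
    hit
  }
  aggCache <- new.env(parent = emptyenv())
  getAgg <- function(channel, carbon, window, mode) {
    key <- paste(channel, carbon, window, mode)
    hit <- aggCache[[key]]
    if (is.null(hit)) {
      tr <- getTracks(NULL, channel, carbon)
      hit <- vapply(tr, windowAggregate, numeric(1), window = window,
                    mode = mode)
      aggCache[[key]] <- hit
    }
    hit
  }
  aggMatrix <- function(cc) {
    vapply(seq_len(nrow(cc)), function(i)
      getAgg(cc$channel[i], cc$carbon[i], cc$window[i], cc$mode[i]),
      numeric(length(profs)))
  }
  objective <- function(cc) {
    raw <- as.numeric(aggMatrix(cc) %*% cc$weight)
    mu <- mean(raw[!isPos]); sg <- stats::sd(raw[!isPos])
    if (!is.finite(sg) || sg < 1e-12) return(-Inf)
    kTop <- max(1L, ceiling(sum(!isPos) * 0.01))
    top <- mean(sort(raw[!isPos], decreasing = TRUE)[seq_len(kTop)])
    (min(raw[isPos]) - top) / sg
  }

  best <- comps
  bestObj <- objective(best)
  trace <- bestObj
  withSeed(seed, {
    stale <- 0L
    for (it in seq_len(maxProposals)) {
      if (stale >= plateau) break
      cand <- best
      i <- sample.int(nrow(cand), 1)
      u <- stats::runif(1)
      if (u < 0.7) {
        cand$weight[i] <- cand$weight[i] + stats::rnorm(1, sd = weightSd)
      } else if (u < 0.85) {
        cand$window[i] <- sample(WINDOW_SET, 1)
      } else if (u < 0.95) {
        cand$mode[i] <- if (cand$mode[i] == "max") "topk" else "max"
      } else {
        cand$carbon[i] <- !cand$carbon[i]
      }
      obj <- objective(cand)
      if (obj > bestObj) {
        best <- cand
        bestObj <- obj
        trace <- c(trace, obj)
        stale <- 0L
      } else {
        stale <- stale + 1L
      }
    }
  })
  rawBg <- as.numeric(aggMatrix(best) %*% best$weight)[!isPos]
  new("PScoreModel", components = best, bgMean = mean(rawBg),
      bgSd = stats::sd(rawBg), trace = trace, seed = as.integer(seed),
      meta = list(nPositives = nPos, nBackground = length(bg),
                  plateau = plateau))
}

#' Write / read a PScore model as structured text
#'
#' @param model a \linkS4class{PScoreModel}.
#' @param path YAML file path.
#' @return the path (write) or a \linkS4class{PScoreModel} (read).
#' @export
writePScoreModel <- function(model, path) {
  yaml::write_yaml(list(
    format = "pipi-pscore-model-1",
    components = lapply(seq_len(nrow(model@components)), function(i)
      as.list(model@components[i, ])),
    bgMean = model@bgMean, bgSd = model@bgSd,
    seed = model@seed, trace = model@trace, meta = model@meta),
    path, precision = 17)
  invisible(path)
}

#' @rdname writePScoreModel
#' @export
readPScoreModel <- function(path) {
  y <- yaml::read_yaml(path)
  comps <- do.call(rbind, lapply(y$components, function(cp)
    data.frame(channel = cp$channel, weight = cp$weight,
               window = as.integer(cp$window), mode = cp$mode,
               carbon = as.logical(cp$carbon), stringsAsFactors = FALSE)))
  new("PScoreModel", components = comps, bgMean = y$bgMean, bgSd = y$bgSd,
      trace = as.numeric(unlist(y$trace)),
      seed = as.integer(y$seed %||% NA_integer_),
      meta = y$meta %||% list())
}
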