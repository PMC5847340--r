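# Synthetic annotation corpora and sequence sets with known statistical
# structure, used to exercise the survey statistics, the frequency predictor
# and the propensity-score trainer without any structure downloads.

#' Background amino-acid composition
#'
#' Average amino-acid frequencies of the UniProt protein universe, used as
#' the folded-protein-like background composition for generated sequences.
#'
#' @return named numeric(20) summing to 1.
#' @export
backgroundComposition <- function() {
  f <- c(A = 8.25, R = 5.53, N = 4.06, D = 5.45, C = 1.38, Q = 3.93,
         E = 6.75, G = 7.07, H = 2.27, I = 5.96, L = 9.66, K = 5.84,
         M = 2.42, F = 3.86, P = 4.70, S = 6.56, T = 5.34, W = 1.08,
         Y = 2.92, V = 6.87)
  f <- f[STANDARD_AA]
  f / sum(f)
}

FLEX_AA <- c("G", "S", "T", "P")

#' True contact-rate function of the synthetic corpus
#'
#' Per-opportunity contact probability for an unordered pair of sp2 groups:
#' \deqn{p = base[sep] f_cat(a) f_cat(b) m(type_a) m(type_b)
#'       (1 + gamma (flex_a + flex_b) / 2)}
#' where flex is the Gly/Ser/Thr/Pro fraction in the context window around
#' each group, clipped to \code{clip}. Aromatic partners, the sp2 amides /
#' carboxyls / guanidinium and backbone-exposing small residues carry
#' elevated multipliers; the gamma term ties long-range backbone contact
#' rates to local backbone flexibility.
#'
#' @param baseShort,baseLong per-opportunity base rates; the defaults place
#'   realized per-residue involvement near the folded-protein survey regime
#'   (roughly a quarter of residues involved, backbone unit contact rates of
#'   a few percent).
#' @param gamma flexibility coefficient (applied to long-range
#'   opportunities).
#' @param clip maximum probability.
#' @return a list of coefficients consumed by
#'   \code{\link{makeAnnotationCorpus}}.
#' @export
corpusRates <- function(baseShort = 0.002, baseLong = 0.0002, gamma = 2,
                        clip = 0.5) {
  typeMult <- stats::setNames(rep(1, 20), STANDARD_AA)
  typeMult[AROMATIC_AA] <- 1.8
  typeMult[c("R", "Q", "N", "E", "D")] <- 1.3
  typeMult[FLEX_AA] <- 1.5
  list(base = c(short = baseShort, long = baseLong),
       catFactor = c(sidechain = 1.5, backbone = 1.0),
       typeMult = typeMult, gamma = gamma, clip = clip)
}

# GSTP fraction in the +/- window context of every position.
flexFractions <- function(seqChars, window = CONTEXT_WINDOW) {
  L <- length(seqChars)
  flex <- as.numeric(seqChars %in% FLEX_AA)
  cs <- c(0, cumsum(flex))
  lo <- pmax(seq_len(L) - window, 1L)
  hi <- pmin(seq_len(L) + window, L)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Generate a synthetic contact-annotation corpus
#'
#' Draws planar-contact events over the canonical opportunity enumeration of
#' each chain, with the stated per-opportunity probability function of group
#' identities, separation class and local composition. Realized rates
#' converge to the stated function as the corpus grows, so parameter
#' recovery by the survey statistics and the frequency predictor is
#' testable.
#'
#' @param nChains number of chains (ignored when \code{sequences} given).
#' @param lengthRange chain length range, residues.
#' @param sequences optional explicit character vector of sequences.
#' @param rates coefficient list from \code{\link{corpusRates}}.
#' @param seed RNG seed.
#' @param composition per-letter sampling weights for generated sequences.
#' @return list with \code{annotations} (a \linkS4class{ChainAnnotations})
#'   and \code{truth} (the rate coefficients).
#' @export
makeAnnotationCorpus <- function(nChains = 50, lengthRange = c(150, 300),
                                 sequences = NULL, rates = corpusRates(),
                                 seed = 1L,
                                 composition = backgroundComposition()) {
  withSeed(seed, {
    if (is.null(sequences)) {
      lens <- sample(seq(lengthRange[1], lengthRange[2]), nChains,
                     replace = TRUE)
      sequences <- vapply(lens, function(L)
        paste(sample(STANDARD_AA, L, replace = TRUE, prob = composition),
              collapse = ""), character(1))
    }
    nChains <- length(sequences)
    keys <- sprintf("SYN%04d_A", seq_len(nChains))
    ctL <- vector("list", nChains)
    for (i in seq_len(nChains)) {
      seqChars <- strsplit(sequences[i], "")[[1]]
      L <- length(seqChars)
      groups <- enumerateGroups(seqChars)
      if (!nrow(groups)) next
      opp <- enumerateOpportunities(groups, L)
      if (!nrow(opp)) next
      flex <- flexFractions(seqChars)
      fa <- flex[groups$pos[opp$a]]
      fb <- flex[groups$pos[opp$b]]
      ta <- rates$typeMult[groups$typeIdx[opp$a]]
      tb <- rates$typeMult[groups$typeIdx[opp$b]]
      ca <- rates$catFactor[groups$cat[opp$a]]
      cb <- rates$catFactor[groups$cat[opp$b]]
      p <- rates$base[opp$sep] * ca * cb * ta * tb *
        ifelse(opp$sep == "long", 1 + rates$gamma * (fa + fb) / 2, 1)
      p <- pmin(p, rates$clip)
      hit <- stats::runif(nrow(opp)) < p
      if (!any(hit)) next
      oh <- opp[hit, , drop = FALSE]
      ga <- groups[oh$a, ]; gb <- groups[oh$b, ]
      ctL[[i]] <- data.frame(
        chainKeyA = keys[i], chainKeyB = keys[i],
        typeA = ga$identity, typeB = gb$identity,
        categoryA = ga$cat, categoryB = gb$cat,
        aromaticA = ga$aromatic, aromaticB = gb$aromatic,
        resIndexA = ga$pos, resIndexB = gb$pos,
        seqSeparation = oh$offset,
        rangeClass = oh$sep, chainClass = "intra",
        stringsAsFactors = FALSE)
    }
  })
  chains <- data.frame(chainKey = keys, sequence = sequences,
                       resolution = NA_real_, rFactor = NA_real_,
                       pdbId = sub("_A$", "", keys),
                       stringsAsFactors = FALSE)
  contacts <- if (any(!vapply(ctL, is.null, logical(1))))
    do.call(rbind, ctL) else emptyAnnotationContacts()
  list(annotations = chainAnnotations(chains, contacts), truth = rates)
}

#' Generate residue-level annotations with stated involvement structure
#'
#' A direct simulation of per-residue planar-contact involvement used to
#' test the survey statistics: each residue's involvement probability is a
#' stated function of its water-contact count, its signed distance from
#' regular secondary structure, and (optionally) its interface class.
#' Involved residues are paired into sidechain-type contact records within or
#' across chains, so involvement frequencies, solvation slopes,
#' secondary-structure profiles and interface breakdowns are recoverable
#' against the stated coefficients.
#'
#' @param nChains,chainLength corpus dimensions.
#' @param seed RNG seed.
#' @param base baseline involvement probability.
#' @param waterSlope added involvement probability per water contact
#'   (waters drawn Poisson(\code{waterMean}) when non-NULL).
#' @param waterMean mean water-contact count.
#' @param ssEndpoints involvement deep inside secondary structure and deep
#'   inside loops (sigmoid between them, replacing \code{base}); NULL
#'   disables SS simulation.
#' @param interfaceExchange fraction of an interface residue's contacts
#'   exchanged from intra- to inter-chain; NULL disables interface
#'   simulation.
#' @param resolutionRate when non-NULL, \code{c(intercept, slope)}: chains
#'   get resolutions uniform on 1.0-3.0 angstrom and involvement
#'   \code{intercept + slope * resolution}.
#' @return list with \code{annotations} and \code{truth}.
#' @export
makeStatsAnnotations <- function(nChains = 40, chainLength = 250, seed = 1L,
                                 base = 0.12, waterSlope = NULL,
                                 waterMean = 3, ssEndpoints = NULL,
                                 interfaceExchange = NULL,
                                 resolutionRate = NULL) {
  comp <- backgroundComposition()
  withSeed(seed, {
    keys <- sprintf("SIM%04d_A", seq_len(nChains))
    resolution <- if (is.null(resolutionRate)) rep(NA_real_, nChains)
    else stats::runif(nChains, 1.0, 3.0)
    chL <- list(); resL <- list(); ctL <- list()
    for (i in seq_len(nChains)) {
      L <- chainLength
      aa <- sample(STANDARD_AA, L, replace = TRUE, prob = comp)
      wc <- if (is.null(waterSlope)) rep(NA_integer_, L)
      else stats::rpois(L, waterMean)
      ss <- rep("-", L)
      if (!is.null(ssEndpoints)) {
        # alternating secondary-structure and loop runs, geometric lengths
        pos <- 1L; inSS <- stats::runif(1) < 0.5
        while (pos <= L) {
          len <- min(3L + stats::rgeom(1, 0.08), L - pos + 1L)
          ss[pos:(pos + len - 1L)] <- if (inSS) "H" else "-"
          pos <- pos + len
          inSS <- !inSS
        }
      }
      q <- rep(base, L)
      if (!is.null(resolutionRate))
        q <- rep(resolutionRate[1] + resolutionRate[2] * resolution[i], L)
      if (!is.null(ssEndpoints)) {
        sp <- ssSignedPositions(ss, cap = 7L)
        # linear interpolation between the deep-SS and deep-loop endpoints
        frac <- (sp + 8) / 16
        q <- ssEndpoints[1] + frac * (ssEndpoints[2] - ssEndpoints[1])
      }
      if (!is.null(waterSlope)) q <- q + waterSlope * wc
      q <- pmin(pmax(q, 0.005), 0.95)
      inv <- stats::runif(L) < q
      iface <- rep("none", L)
      if (!is.null(interfaceExchange)) {
        # interface residues in contiguous blocks covering ~30% of the chain
        nBlocks <- max(1L, round(L / 60))
        starts <- sample(seq_len(L - 19L), nBlocks)
        for (s in starts)
          iface[s:(s + 19L)] <- sample(c("inter_asu", "symmetry"), 1)
      }
      invIdx <- which(inv)
      if (length(invIdx) %% 2L == 1L)
        invIdx <- invIdx[-length(invIdx)]
      cts <- NULL
      if (length(invIdx)) {
        pairIdx <- matrix(sample(invIdx), ncol = 2)
        inter <- if (is.null(interfaceExchange)) rep(FALSE, nrow(pairIdx))
        else (iface[pairIdx[, 1]] != "none" |
                iface[pairIdx[, 2]] != "none") &
          stats::runif(nrow(pairIdx)) < interfaceExchange
        sep <- abs(pairIdx[, 1] - pairIdx[, 2])
        cts <- data.frame(
          chainKeyA = keys[i],
          chainKeyB = ifelse(inter, paste0(keys[i], "p"), keys[i]),
          typeA = aa[pairIdx[, 1]], typeB = aa[pairIdx[, 2]],
          categoryA = "sidechain", categoryB = "sidechain",
          aromaticA = aa[pairIdx[, 1]] %in% AROMATIC_AA,
          aromaticB = aa[pairIdx[, 2]] %in% AROMATIC_AA,
          resIndexA = pairIdx[, 1], resIndexB = pairIdx[, 2],
          seqSeparation = ifelse(inter, Inf, sep),
          rangeClass = ifelse(!inter & sep <= 4, "short", "long"),
          chainClass = ifelse(inter, "inter_asu", "intra"),
          stringsAsFactors = FALSE)
      }
      chL[[i]] <- data.frame(chainKey = keys[i],
                             sequence = paste(aa, collapse = ""),
                             resolution = resolution[i], rFactor = NA_real_,
                             pdbId = sub("_A$", "", keys[i]),
                             stringsAsFactors = FALSE)
      resL[[i]] <- data.frame(chainKey = keys[i], resIndex = seq_len(L),
                              aa = aa, waterCount = wc, ss = ss,
                              interfaceClass = iface,
                              stringsAsFactors = FALSE)
      ctL[[i]] <- cts
    }
  })
  contacts <- if (any(!vapply(ctL, is.null, logical(1))))
    do.call(rbind, ctL) else emptyAnnotationContacts()
  ann <- chainAnnotations(do.call(rbind, chL), contacts,
                          do.call(rbind, resL))
  list(annotations = ann,
       truth = list(base = base, waterSlope = waterSlope,
                    ssEndpoints = ssEndpoints,
                    interfaceExchange = interfaceExchange,
                    resolutionRate = resolutionRate))
}

#' Generate positive-like and background sequence sets
#'
#' Positive-like sequences are built from dipeptide repeats associated with
#' high planar pi-contact frequencies (Pro-Gly, Phe-Gly, Ser-Arg, Tyr-Gly,
#' Arg-Gly) with a fraction of positions replaced by background-composition
#' noise; background sequences are sampled from the folded-protein-like
#' composition. All sequences meet the 140-residue scoring minimum.
#'
#' @param nPositive,nBackground set sizes.
#' @param lengthRange sequence length range (minimum 140).
#' @param noise fraction of positive-sequence positions replaced by
#'   background letters.
#' @param seed RNG seed.
#' @return list of two \code{Biostrings::AAStringSet}s: \code{positive} and
#'   \code{background}.
#' @export
makeSequenceSets <- function(nPositive = 30, nBackground = 150,
                             lengthRange = c(150, 350), noise = 0.1,
                             seed = 1L) {
  if (lengthRange[1] < 140) stop("lengthRange must start at >= 140")
  motifs <- c("PG", "FG", "SR", "YG", "RG")
  comp <- backgroundComposition()
  withSeed(seed, {
    lens <- sample(seq(lengthRange[1], lengthRange[2]), nPositive + nBackground,
                   replace = TRUE)
    pos <- vapply(seq_len(nPositive), function(i) {
      L <- lens[i]
      motif <- sample(motifs, 1)
      s <- strsplit(strrep(motif, ceiling(L / 2)), "")[[1]][seq_len(L)]
      flip <- stats::runif(L) < noise
      s[flip] <- sample(STANDARD_AA, sum(flip), replace = TRUE, prob = comp)
      paste(s, collapse = "")
    }, character(1))
    bg <- vapply(seq_len(nBackground), function(i) {
      L <- lens[nPositive + i]
      paste(sample(STANDARD_AA, L, replace = TRUE, prob = comp),
            collapse = "")
    }, character(1))
  })
  list(positive = Biostrings::AAStringSet(
         stats::setNames(pos, sprintf("POS%03d", seq_len(nPositive)))),
       background = Biostrings::AAStringSet(
         stats::setNames(bg, sprintf("BG%03d", seq_len(nBackground)))))
}
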