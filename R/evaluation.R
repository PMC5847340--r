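# Benchmark machinery: empirical ROC/AUC, bootstrap errors, dipeptide-profile
# distances and sequence complexity.

#' Empirical ROC curve and AUC
#'
#' Non-parametric step-function ROC from the empirical cumulative
#' distributions of the two score sets; the AUC is measured directly without
#' smoothing and handles ties with the Mann-Whitney 1/2 convention.
#'
#' @param positive,negative numeric score vectors (higher = more positive).
#' @return list with \code{auc} and \code{curve} (data.frame fpr, tpr).
#' @examples
#' rocAuc(c(3, 4), c(1, 2))$auc  # 1
#' rocAuc(c(3, 1), c(2, 0))$auc  # 0.75
#' @export
rocAuc <- function(positive, negative) {
  if (!length(positive) || !length(negative))
    stop("both score sets must be nonempty")
  np <- length(positive); nn <- length(negative)
  # pairwise concordance with half-weight ties (Mann-Whitney equivalence)
  r <- rank(c(positive, negative), ties.method = "average")
  u <- sum(r[seq_len(np)]) - np * (np + 1) / 2
  auc <- u / (np * nn)
  thr <- sort(unique(c(positive, negative, Inf)), decreasing = TRUE)
  curve <- data.frame(
    fpr = vapply(thr, function(t) mean(negative >= t), numeric(1)),
    tpr = vapply(thr, function(t) mean(positive >= t), numeric(1)))
  curve <- rbind(data.frame(fpr = 0, tpr = 0), curve)
  list(auc = auc, curve = curve)
}

#' Bootstrap SEM of an AUC
#'
#' Standard deviation of the AUC over resamples drawing both score sets with
#' replacement.
#'
#' @param positive,negative numeric score vectors.
#' @param nIter bootstrap iterations.
#' @param seed RNG seed.
#' @return bootstrap SEM.
#' @export
bootstrapAucSem <- function(positive, negative, nIter = 10000, seed = 1L) {
  if (!length(positive) || !length(negative))
    stop("both score sets must be nonempty")
  vals <- withSeed(seed, vapply(seq_len(nIter), function(i) {
    rocAuc(sample(positive, replace = TRUE),
           sample(negative, replace = TRUE))$auc
  }, numeric(1)))
  stats::sd(vals)
}

# Normalized dipeptide (i, i+1) frequency profile over the 400 ordered pairs.
dipeptideProfile <- function(sequence) {
  s <- strsplit(sequence, "")[[1]]
  if (length(s) < 2) stop("sequence must have length >= 2")
  a <- match(s[-length(s)], STANDARD_AA)
  b <- match(s[-1], STANDARD_AA)
  ok <- !is.na(a) & !is.na(b)
  prof <- tabulate((a[ok] - 1L) * 20L + b[ok], 400L)
  prof / sum(prof)
}

#' Minimum dipeptide-profile L1 distance to a reference set
#'
#' Computes the 400-cell dipeptide frequency profile of the query and of each
#' reference sequence (profiles normalized to sum 1), takes block L1
#' distances, and returns the smallest.
#'
#' @param query a sequence string.
#' @param references character vector / AAStringSet of reference sequences.
#' @return minimum L1 distance in [0, 2].
#' @examples
#' dipeptideDistance("GGGG", c("GSGS"))  # 2
#' dipeptideDistance("GGGS", c("GGGG"))  # 4/3
#' @export
dipeptideDistance <- function(query, references) {
  references <- as.character(references)
  if (!length(references)) stop("empty reference set")
  q <- dipeptideProfile(query)
  min(vapply(references, function(r) sum(abs(q - dipeptideProfile(r))),
             numeric(1)))
}

#' Shannon entropy of a sequence's amino-acid profile
#'
#' @param sequence a sequence string.
#' @return entropy in bits.
#' @examples
#' shannonEntropy("AAAA")  # 0
#' shannonEntropy("AABB")  # 1
#' @export
shannonEntropy <- function(sequence) {
  s <- strsplit(sequence, "")[[1]]
  if (!length(s)) stop("empty sequence")
  p <- table(s) / length(s)
  -sum(p * log2(p))
}

#' Load a benchmark sequence set
#'
#' Reads a TSV with columns \code{id}, \code{class} (one of
#' "in_vitro_sufficient", "in_vitro_insufficient", "in_cellulo_associated",
#' "synthetic_designed", "background") and \code{sequence}. Sequences
#' shorter than 140 residues are removed and logged.
#'
#' @param path TSV path.
#' @return data.frame (id, class, sequence), attribute \code{removed}.
#' @export
loadBenchmarkSet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "class", "sequence")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("benchmark file lacks columns: ", paste(miss, collapse = ", "))
  short <- nchar(df$sequence) < 140
  if (any(short))
    message("removing ", sum(short), " sequence(s) under 140 residues: ",
            paste(df$id[short], collapse = ", "))
  out <- df[!short, need]
  rownames(out) <- NULL
  attr(out, "removed") <- df$id[short]
  out
}
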