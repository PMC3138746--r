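# Benchmark metrics comparing a predicted PWM with an experimentally
# measured profile, plus the naive similarity-group baseline.

.matchedProfiles <- function(pred, exp) {
  if (length(pred@positions) != length(exp@positions)) {
    stop("PWMs cover different numbers of positions")
  }
  list(p = pred@profile, e = exp@profile)
}

#' Fraction Top 5
#'
#' Per position, the fraction of experimentally preferred letters
#' (frequency >= `freqThreshold`) found among the top `k` predicted
#' letters, averaged over positions with at least one qualifying letter,
#' times 100. Predicted ranking ties are broken alphabetically.
#'
#' @param pred,exp predicted and experimental \linkS4class{PWM}s over
#'   matched positions.
#' @param freqThreshold experimental frequency defining a preferred
#'   letter (default 0.10).
#' @param k size of the predicted top list (default 5).
#' @return percentage in [0, 100].
#' @export
fractionTop5 <- function(pred, exp, freqThreshold = 0.10, k = 5) {
  m <- .matchedProfiles(pred, exp)
  fracs <- c()
  for (j in seq_len(ncol(m$p))) {
    qual <- AA_ALPHABET[m$e[, j] >= freqThreshold]
    if (length(qual) == 0) next
    ord <- order(-m$p[, j], AA_ALPHABET)
    topk <- AA_ALPHABET[ord][seq_len(k)]
    fracs <- c(fracs, mean(qual %in% topk))
  }
  if (length(fracs) == 0) {
    stop("no position has an experimental letter above the threshold")
  }
  100 * mean(fracs)
}

#' Average absolute difference in amino-acid frequency
#'
#' Mean over all position x letter elements of |p_pred - p_exp|, times
#' 100. Ranges from 0 (identical) to 10 (disjoint one-hot columns).
#'
#' @inheritParams fractionTop5
#' @return percentage in [0, 10].
#' @export
aad <- function(pred, exp) {
  m <- .matchedProfiles(pred, exp)
  100 * mean(abs(m$p - m$e))
}

#' Area under the ROC curve of predicted frequencies
#'
#' Pools all position x letter elements, labels an element positive when
#' its experimental frequency is at least `freqThreshold`, scores it by
#' the predicted frequency, and computes the AUC by the rank-sum
#' (Mann-Whitney) formulation with ties counted half. 0.5 is the random
#' baseline.
#'
#' @inheritParams fractionTop5
#' @param perPosition average a separate AUC per position instead of
#'   pooling elements (default FALSE).
#' @return AUC in [0, 1].
#' @export
rocAUC <- function(pred, exp, freqThreshold = 0.10, perPosition = FALSE) {
  m <- .matchedProfiles(pred, exp)
  auc1 <- function(scores, labels) {
    npos <- sum(labels)
    nneg <- sum(!labels)
    if (npos == 0 || nneg == 0) {
      stop("AUC undefined: all elements in one class")
    }
    r <- rank(scores)
    (sum(r[labels]) - npos * (npos + 1) / 2) / (npos * nneg)
  }
  if (perPosition) {
    mean(vapply(seq_len(ncol(m$p)), function(j) {
      auc1(m$p[, j], m$e[, j] >= freqThreshold)
    }, 0))
  } else {
    auc1(as.numeric(m$p), as.numeric(m$e) >= freqThreshold)
  }
}

#' Average predicted rank of the experimental best letter
#'
#' Per position, the 1-based rank of the experimentally most frequent
#' letter within the predicted descending frequency order (ties broken
#' alphabetically), averaged over positions. 1 is perfect; 20 is the
#' worst possible.
#'
#' @inheritParams fractionTop5
#' @return average rank in [1, 20].
#' @export
rankTop <- function(pred, exp) {
  m <- .matchedProfiles(pred, exp)
  ranks <- vapply(seq_len(ncol(m$p)), function(j) {
    topExp <- AA_ALPHABET[which.max(m$e[, j])]
    ord <- AA_ALPHABET[order(-m$p[, j], AA_ALPHABET)]
    which(ord == topExp)
  }, 0L)
  mean(ranks)
}

#' Naive similarity-group baseline PWM
#'
#' For each position, gives equal weight to the wild-type letter's
#' chemical-similarity group (DENQ, RKH, LIVM, FYW, PAG, ST, C) and zero
#' elsewhere.
#'
#' @param wt named character vector: position label -> wild-type
#'   one-letter code.
#' @return a \linkS4class{PWM}.
#' @export
naivePWM <- function(wt) {
  stopifnot(all(wt %in% AA_ALPHABET))
  pos <- names(wt)
  if (is.null(pos)) pos <- paste0("P", seq_along(wt))
  prof <- matrix(0, 20, length(wt), dimnames = list(AA_ALPHABET, pos))
  for (j in seq_along(wt)) {
    grp <- SIMILARITY_GROUPS[[which(vapply(SIMILARITY_GROUPS,
                                           function(g) wt[j] %in% g,
                                           TRUE))]]
    prof[grp, j] <- 1 / length(grp)
  }
  methods::new("PWM", profile = prof, positions = pos,
               metadata = list(source = "naive-similarity-groups"))
}

#' Full metric report for a predicted profile
#'
#' @inheritParams fractionTop5
#' @return list: predictedBits, fractionTop5, aad, auc, rankTop.
#' @export
metricReport <- function(pred, exp, freqThreshold = 0.10, k = 5) {
  list(predictedBits = informationBits(pred)$average,
       fractionTop5 = fractionTop5(pred, exp, freqThreshold, k),
       aad = aad(pred, exp),
       auc = rocAUC(pred, exp, freqThreshold),
       rankTop = rankTop(pred, exp))
}
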