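#' Per-class ROC AUC against a prescribed-drug gold standard
#'
#' Within each repositioning class, the AUC is the Mann-Whitney probability
#' that a prescribed (gold-standard) drug's score exceeds a non-prescribed
#' drug's score, with tied pairs counted 0.5. A class lacking either a
#' positive or a negative drug has no defined AUC and yields `NA`. A
#' `global` row over all scored drugs is appended for convenience.
#'
#' @param scores Classified `drug_score_table` (see [classify_drpc()]).
#' @param gold A [gold_standard()].
#' @return `data.frame` with columns `class`, `n_pos`, `n_neg`, `auc`.
#' @export
auc_per_class <- function(scores, gold) {
  stopifnot(is.data.frame(scores), all(c("cid", "drps") %in% names(scores)),
            inherits(gold, "gold_standard"))
  if (nrow(scores) == 0L) stop("empty score table")
  if (!"drpc" %in% names(scores)) stop("scores must be classified first")
  groups <- c(levels(factor(scores$drpc)), "global")
  rows <- lapply(groups, function(cl) {
    sub <- if (cl == "global") scores else scores[scores$drpc == cl, , drop = FALSE]
    pos <- sub$cid %in% gold$cids
    data.frame(class = cl, n_pos = sum(pos), n_neg = sum(!pos),
               auc = mann_whitney_auc(sub$drps, pos),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Mann-Whitney AUC of a score vector against binary labels
#'
#' Midrank formulation: `AUC = (R_pos - n_pos (n_pos + 1) / 2) /
#' (n_pos n_neg)` where `R_pos` is the rank sum of positives, so each tied
#' positive-negative pair contributes 0.5. Returns `NA` when either group
#' is empty.
#'
#' @param score Numeric scores (higher = more drug-like candidate).
#' @param positive Logical labels, same length.
#' @return AUC in \[0, 1\], or `NA` when undefined.
#' @export
mann_whitney_auc <- function(score, positive) {
  stopifnot(length(score) == length(positive), is.logical(positive))
  n_pos <- sum(positive)
  n_neg <- sum(!positive)
  if (n_pos == 0L || n_neg == 0L) return(NA_real_)
  r <- rank(score, ties.method = "average")
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Rate of shared strongly-perturbed genes across two signatures
#'
#' For each fold-change threshold `t`, the rate is the fraction of the
#' reference signature's genes with `|F_A| >= t` that also satisfy
#' `|F_B| >= t` in the second signature:
#' `|{g: |F_A| >= t & |F_B| >= t}| / |{g: |F_A| >= t}|`. With
#' `jaccard = TRUE` the denominator is instead the union of the two
#' above-threshold sets. An empty denominator yields rate 0 with a
#' warning.
#'
#' @param sig_a Reference signature (its above-threshold set is the
#'   default denominator).
#' @param sig_b Comparison signature.
#' @param fc_grid Ascending positive fold-change thresholds.
#' @param jaccard Use the Jaccard denominator instead.
#' @return `data.frame` with columns `fc`, `n_ref`, `n_shared`, `rate`.
#' @export
shared_deg_rate <- function(sig_a, sig_b, fc_grid = c(0.5, 1, 1.5, 2),
                            jaccard = FALSE) {
  stopifnot(inherits(sig_a, "perturbation_signature"),
            inherits(sig_b, "perturbation_signature"))
  if (length(sig_a) == 0L || length(sig_b) == 0L) {
    stop("both signatures must be non-empty")
  }
  if (any(fc_grid <= 0) || is.unsorted(fc_grid, strictly = TRUE)) {
    stop("'fc_grid' must be strictly ascending positive thresholds")
  }
  rows <- lapply(fc_grid, function(t) {
    a <- names(sig_a)[abs(as.numeric(sig_a)) >= t]
    b <- names(sig_b)[abs(as.numeric(sig_b)) >= t]
    shared <- intersect(a, b)
    denom <- if (jaccard) length(union(a, b)) else length(a)
    rate <- if (denom == 0L) {
      warning(sprintf("no gene above |log2FC| >= %g in the reference; rate 0", t))
      0
    } else length(shared) / denom
    data.frame(fc = t, n_ref = length(a), n_shared = length(shared),
               rate = rate)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fraction of shared genes perturbed in the same direction
#'
#' Over the gene intersection of two signatures, the fraction whose fold
#' changes have the same strict sign; genes with a zero fold change in
#' either signature are excluded from both numerator and denominator.
#'
#' @param sig_a,sig_b [perturbation_signature()] objects with a non-empty
#'   gene intersection.
#' @return A proportion in \[0, 1\] (`NA` with a warning when every shared
#'   gene has a zero fold change).
#' @export
direction_similarity <- function(sig_a, sig_b) {
  stopifnot(inherits(sig_a, "perturbation_signature"),
            inherits(sig_b, "perturbation_signature"))
  common <- intersect(names(sig_a), names(sig_b))
  if (length(common) == 0L) stop("signatures share no genes")
  fa <- as.numeric(sig_a[common])
  fb <- as.numeric(sig_b[common])
  nonzero <- fa != 0 & fb != 0
  if (!any(nonzero)) {
    warning("all shared genes have a zero fold change; similarity undefined")
    return(NA_real_)
  }
  mean(sign(fa[nonzero]) == sign(fb[nonzero]))
}
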