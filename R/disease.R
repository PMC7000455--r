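#' Per-gene two-group differential test
#'
#' Welch's unequal-variance t-test applied gene-by-gene to case versus
#' normal intensity matrices, with Benjamini-Hochberg control of the false
#' discovery rate across genes. With `method = "log_welch_t"` the test is
#' run on `log2(x + pseudocount)` values, which is the appropriate scale
#' for count-like or right-skewed intensities; the reported fold change is
#' always `log2((mean_case + pc) / (mean_normal + pc))` on the intensity
#' scale.
#'
#' A gene whose intensities have zero variance in both groups carries no
#' within-group evidence, so its p-value is 1 by convention (its fold
#' change is still reported).
#'
#' @param case,normal [expression_profile()] objects (or plain matrices
#'   with gene rownames) with identical gene sets and at least two samples
#'   each.
#' @param method `"welch_t"` (test on the intensity scale) or
#'   `"log_welch_t"` (test on log2-transformed intensities).
#' @param pseudocount Non-negative offset used in the fold change and, for
#'   `log_welch_t`, in the transform.
#' @param normalize `"none"` or `"median_center"`: the latter median-centres
#'   each sample's log2 intensities before testing (a light-weight
#'   alternative to variance-stabilising normalisation for proteomics).
#' @return `data.frame` with columns `gene_id`, `log2fc`, `p_value`,
#'   `q_value` (BH-adjusted), one row per gene, in input gene order.
#' @seealso [make_disease_signature()]
#' @export
differential_test <- function(case, normal,
                              method = c("welch_t", "log_welch_t"),
                              pseudocount = 0,
                              normalize = c("none", "median_center")) {
  method <- match.arg(method)
  normalize <- match.arg(normalize)
  x <- if (inherits(case, "expression_profile")) case$values else as.matrix(case)
  y <- if (inherits(normal, "expression_profile")) normal$values else as.matrix(normal)
  if (is.null(rownames(x)) || is.null(rownames(y))) {
    stop("matrices must carry gene rownames")
  }
  if (!identical(rownames(x), rownames(y))) {
    common <- intersect(rownames(x), rownames(y))
    if (length(common) == 0L) stop("case and normal share no genes")
    x <- x[common, , drop = FALSE]
    y <- y[common, , drop = FALSE]
  }
  if (ncol(x) < 2L || ncol(y) < 2L) {
    stop("need at least 2 samples per group")
  }
  stopifnot(pseudocount >= 0)

  mean_case <- rowMeans(x)
  mean_normal <- rowMeans(y)
  log2fc <- log2((mean_case + pseudocount) / (mean_normal + pseudocount))

  if (normalize == "median_center") {
    center <- function(m) {
      lm2 <- log2(m + pseudocount)
      sweep(lm2, 2L, apply(lm2, 2L, stats::median))
    }
    x <- 2^center(x)
    y <- 2^center(y)
  }
  if (method == "log_welch_t") {
    x <- log2(x + pseudocount)
    y <- log2(y + pseudocount)
    if (any(!is.finite(x)) || any(!is.finite(y))) {
      stop("log transform produced non-finite values; increase 'pseudocount'")
    }
  }
  p <- row_welch_p(x, y)
  data.frame(gene_id = rownames(x), log2fc = log2fc, p_value = p,
             q_value = stats::p.adjust(p, method = "BH"),
             stringsAsFactors = FALSE, row.names = NULL)
}

# Vectorised two-sided Welch t-test across rows; p = 1 where both group
# variances are zero (no within-group evidence).
row_welch_p <- function(x, y) {
  nx <- ncol(x); ny <- ncol(y)
  mx <- rowMeans(x); my <- rowMeans(y)
  vx <- rowSums((x - mx)^2) / (nx - 1)
  vy <- rowSums((y - my)^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  degenerate <- se2 == 0
  tstat <- ifelse(degenerate, 0, (mx - my) / sqrt(se2))
  df <- ifelse(degenerate, 1,
               se2^2 / (vx^2 / (nx^2 * (nx - 1)) + vy^2 / (ny^2 * (ny - 1))))
  p <- 2 * stats::pt(-abs(tstat), df)
  p[degenerate] <- 1
  p
}

#' Filter a differential-test table into a disease signature
#'
#' Retains the genes passing the significance cut and returns their log2
#' fold changes as a disease perturbation signature (CGPS/AGPS for
#' transcripts, APPS for proteins). By default the cut is a strict
#' inequality on the BH q-value (`q < threshold`); set `use_fdr = FALSE`
#' to cut on the raw p-value non-strictly (`p <= threshold`), the
#' convention sometimes used for small proteomics designs.
#'
#' @param results `data.frame` from [differential_test()].
#' @param q_threshold Significance threshold in (0, 1].
#' @param origin `"CGPS"`, `"AGPS"` or `"APPS"`.
#' @param disease Disease label carried on the signature.
#' @param use_fdr Cut on BH q-values (default) or raw p-values.
#' @return A [perturbation_signature()]; empty (with a warning) when no
#'   gene passes.
#' @export
make_disease_signature <- function(results, q_threshold = 0.05,
                                   origin = c("CGPS", "AGPS", "APPS"),
                                   disease = "disease", use_fdr = TRUE) {
  origin <- match.arg(origin)
  stopifnot(is.data.frame(results),
            all(c("gene_id", "log2fc", "p_value", "q_value") %in% names(results)),
            length(q_threshold) == 1L, q_threshold > 0, q_threshold <= 1)
  keep <- if (use_fdr) results$q_value < q_threshold
          else results$p_value <= q_threshold
  if (!any(keep)) {
    warning("no gene passes the significance threshold; empty signature")
  }
  entries <- stats::setNames(results$log2fc[keep], results$gene_id[keep])
  perturbation_signature(entries, origin = origin, disease = disease)
}
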