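#' Genes inversely perturbed by a drug and a disease
#'
#' A gene is *inversely* perturbed when its drug and disease log2 fold
#' changes have strictly opposite signs (a zero fold change is never
#' inverse). `n` is the size of the full gene intersection between the two
#' signatures, not only its inverse subset: it is the denominator of the
#' mean perturbation score, so non-inverse genes dilute the score rather
#' than being ignored.
#'
#' @param dgps Drug signature ([perturbation_signature()]).
#' @param dsig Disease signature.
#' @return List with `genes` (character vector of inverse genes) and `n`
#'   (integer, size of the full intersection).
#' @export
inverse_gene_set <- function(dgps, dsig) {
  stopifnot(inherits(dgps, "perturbation_signature"),
            inherits(dsig, "perturbation_signature"))
  if (length(dgps) == 0L || length(dsig) == 0L) {
    stop("both signatures must be non-empty")
  }
  common <- intersect(names(dgps), names(dsig))
  if (length(common) == 0L) return(list(genes = character(), n = 0L))
  fdr <- as.numeric(dgps[common])
  fd <- as.numeric(dsig[common])
  inverse <- (fdr > 0 & fd < 0) | (fdr < 0 & fd > 0)
  list(genes = common[inverse], n = length(common))
}

#' Perturbation score of one inversely perturbed gene
#'
#' `PS = |F_disease| - |F_drug|` for a gene whose disease and drug fold
#' changes have strictly opposite signs. The score is positive when the
#' drug opposes the disease at a smaller magnitude and negative when the
#' drug overshoots; callers guarantee the sign precondition via
#' [inverse_gene_set()].
#'
#' @param f_d Disease log2 fold change(s).
#' @param f_dr Drug log2 fold change(s), sign-opposed to `f_d` elementwise.
#' @return Numeric vector of perturbation scores.
#' @examples
#' perturbation_score(2, -1)    # 1
#' perturbation_score(-0.5, 3)  # -2.5
#' @export
perturbation_score <- function(f_d, f_dr) {
  stopifnot(length(f_d) == length(f_dr))
  if (any(f_d * f_dr >= 0)) {
    stop("perturbation score requires strictly opposite signs")
  }
  abs(f_d) - abs(f_dr)
}

#' Score one drug condition against a disease signature
#'
#' Over the gene intersection of the drug and disease signatures, the mean
#' gene perturbation score is `sum(PS over inverse genes) / n` with `n` the
#' full intersection size (non-inverse genes contribute zero). The mean
#' pharmacogene score is computed identically restricted to pharmacogenes
#' (`m` of them in the intersection; defined as 0 when `m = 0`: without
#' pharmacogene overlap the drug receives no weighted evidence). The
#' condition's score is the product of the two means; with
#' `floor_negative_means = TRUE` (default) each mean is floored at zero
#' first, so that two negative means cannot multiply into a spuriously
#' positive score.
#'
#' @inheritParams inverse_gene_set
#' @param pgl A [pharmacogene_list()].
#' @param floor_negative_means Floor each component mean at zero before the
#'   product (default `TRUE`).
#' @return List of class `condition_score`: `key`, `gene_mean`, `pg_mean`,
#'   `n`, `m`, `product`.
#' @examples
#' dgps <- perturbation_signature(c(g1 = -1, g2 = 1), "DGPS",
#'                                key = condition_key(1, "cl", "d", "t"))
#' dsig <- perturbation_signature(c(g1 = 3, g2 = 2), "CGPS", disease = "x")
#' condition_score(dgps, dsig, pharmacogene_list("g1"))
#' # gene_mean 1, pg_mean 2, product 2
#' @export
condition_score <- function(dgps, dsig, pgl, floor_negative_means = TRUE) {
  inv <- inverse_gene_set(dgps, dsig)
  key <- sig_key(dgps)
  if (inv$n == 0L) {
    warning("signatures share no genes; condition scores 0")
    return(structure(list(key = key, gene_mean = 0, pg_mean = 0,
                          n = 0L, m = 0L, product = 0),
                     class = "condition_score"))
  }
  common <- intersect(names(dgps), names(dsig))
  ps <- if (length(inv$genes)) {
    perturbation_score(as.numeric(dsig[inv$genes]), as.numeric(dgps[inv$genes]))
  } else numeric()
  gene_mean <- sum(ps) / inv$n

  pg_common <- intersect(common, as.character(pgl))
  m <- length(pg_common)
  pg_mean <- if (m == 0L) 0 else {
    pg_inv <- intersect(inv$genes, pg_common)
    ps_pg <- if (length(pg_inv)) {
      perturbation_score(as.numeric(dsig[pg_inv]), as.numeric(dgps[pg_inv]))
    } else numeric()
    sum(ps_pg) / m
  }
  product <- if (floor_negative_means) {
    max(gene_mean, 0) * max(pg_mean, 0)
  } else {
    gene_mean * pg_mean
  }
  structure(list(key = key, gene_mean = gene_mean, pg_mean = pg_mean,
                 n = inv$n, m = m, product = product),
            class = "condition_score")
}

#' @export
print.condition_score <- function(x, ...) {
  cat(sprintf("<condition_score %s> product %.4g (gene_mean %.4g over n=%d, pg_mean %.4g over m=%d)\n",
              if (is.null(x$key)) "" else format(x$key),
              x$product, x$gene_mean, x$n, x$pg_mean, x$m))
  invisible(x)
}

#' Drug repositioning perturbation score (DRPS) of one drug
#'
#' A drug measured under several experimental conditions receives the
#' maximum condition score; ties are broken by the lexicographically
#' smallest condition key so the reported best condition is deterministic.
#'
#' @param drug_signatures List of the drug's DGPS
#'   [perturbation_signature()] objects (one per condition).
#' @inheritParams condition_score
#' @return List with `drps` (the maximum product) and `best` (the achieving
#'   `condition_score`).
#' @export
drps <- function(drug_signatures, dsig, pgl, floor_negative_means = TRUE) {
  stopifnot(is.list(drug_signatures), length(drug_signatures) >= 1L)
  scores <- lapply(drug_signatures, condition_score, dsig = dsig, pgl = pgl,
                   floor_negative_means = floor_negative_means)
  products <- vapply(scores, `[[`, numeric(1), "product")
  keys <- vapply(scores, function(s)
    if (is.null(s$key)) "" else format(s$key), character(1))
  best <- order(-products, keys)[1L]
  list(drps = products[best], best = scores[[best]])
}

#' Score every drug in a signature database
#'
#' Computes the DRPS of each compound in the database against a disease
#' signature and reports the condition achieving it.
#'
#' @param db A `signature_db`.
#' @inheritParams condition_score
#' @return A `data.frame` (class `drug_score_table`) with one row per
#'   compound: `cid`, `drps`, `gene_mean`, `pg_mean`, `n`, `m`,
#'   `cell_line`, `dose`, `time`, ordered by decreasing `drps` (ties by
#'   ascending `cid`). Pass through [classify_drpc()] to add the class
#'   column.
#' @export
score_drugs <- function(db, dsig, pgl, floor_negative_means = TRUE) {
  stopifnot(inherits(db, "signature_db"))
  if (length(db) == 0L) stop("empty signature database")
  cids <- sort(unique(db$index$cid))
  rows <- lapply(cids, function(cid) {
    keys <- db$index$key[db$index$cid == cid]
    res <- drps(db$signatures[keys], dsig, pgl,
                floor_negative_means = floor_negative_means)
    b <- res$best
    data.frame(cid = cid, drps = res$drps, gene_mean = b$gene_mean,
               pg_mean = b$pg_mean, n = b$n, m = b$m,
               cell_line = b$key$cell_line, dose = b$key$dose,
               time = b$key$time, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$drps, out$cid), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("drug_score_table", "data.frame")
  out
}

#' Classify scored drugs into repositioning tertiles (DRPC)
#'
#' Drugs ranked by score are split into three contiguous blocks — `high`,
#' `intermediate`, `low` — whose sizes differ by at most one; when the
#' count is not divisible by three the extra members go to the higher
#' classes first. Ties in score are broken by ascending CID, so the
#' partition is deterministic across reruns.
#'
#' @param scores A `drug_score_table` from [score_drugs()] with at least
#'   three drugs.
#' @return The table with a `drpc` factor column
#'   (`high`/`intermediate`/`low`) added, rows ordered by decreasing score.
#' @export
classify_drpc <- function(scores) {
  stopifnot(is.data.frame(scores), all(c("cid", "drps") %in% names(scores)))
  n <- nrow(scores)
  if (n < 3L) stop("need at least 3 drugs to form tertile classes")
  scores <- scores[order(-scores$drps, scores$cid), , drop = FALSE]
  base <- n %/% 3L
  rem <- n %% 3L
  sizes <- c(high = base + (rem >= 1L), intermediate = base + (rem >= 2L),
             low = base)
  scores$drpc <- factor(rep(c("high", "intermediate", "low"), times = sizes),
                        levels = c("high", "intermediate", "low"))
  rownames(scores) <- NULL
  class(scores) <- c("drug_score_table", "data.frame")
  scores
}

#' Select multi-omics repositioning candidates
#'
#' A candidate must (a) be classed `high` against at least one
#' transcriptomic disease signature *and* at least one proteomic signature
#' (set `transcriptomic_quantifier = "all"` to require high class in every
#' transcriptomic table), and (b) never be classed `low` in any supplied
#' table.
#'
#' @param class_tables Named list of classified `drug_score_table`s (one
#'   per disease signature).
#' @param transcriptomic_labels,proteomic_labels Names of `class_tables`
#'   entries derived from transcriptomic / proteomic signatures.
#' @param transcriptomic_quantifier `"any"` (default) or `"all"`: how many
#'   transcriptomic tables must rank the drug high.
#' @return Sorted integer vector of candidate CIDs.
#' @export
select_candidates <- function(class_tables, transcriptomic_labels,
                              proteomic_labels,
                              transcriptomic_quantifier = c("any", "all")) {
  transcriptomic_quantifier <- match.arg(transcriptomic_quantifier)
  stopifnot(is.list(class_tables), length(class_tables) >= 1L)
  if (!length(transcriptomic_labels) || !length(proteomic_labels)) {
    stop("need at least one transcriptomic and one proteomic table")
  }
  missing <- setdiff(c(transcriptomic_labels, proteomic_labels),
                     names(class_tables))
  if (length(missing)) {
    stop("unknown table label(s): ", paste(missing, collapse = ", "))
  }
  for (lab in names(class_tables)) {
    if (!"drpc" %in% names(class_tables[[lab]])) {
      stop("table '", lab, "' is not classified; run classify_drpc() first")
    }
  }
  class_of <- function(lab, cids) {
    tab <- class_tables[[lab]]
    as.character(tab$drpc[match(cids, tab$cid)])
  }
  all_cids <- sort(unique(unlist(lapply(class_tables, `[[`, "cid"))))
  high_t <- sapply(transcriptomic_labels, function(lab)
    class_of(lab, all_cids) == "high")
  high_t <- matrix(high_t, nrow = length(all_cids))
  ok_t <- if (transcriptomic_quantifier == "any") {
    apply(high_t, 1L, any, na.rm = TRUE)
  } else {
    apply(high_t, 1L, function(z) all(!is.na(z)) && all(z))
  }
  high_p <- matrix(sapply(proteomic_labels, function(lab)
    class_of(lab, all_cids) == "high"), nrow = length(all_cids))
  ok_p <- apply(high_p, 1L, any, na.rm = TRUE)
  any_low <- apply(matrix(sapply(names(class_tables), function(lab)
    class_of(lab, all_cids) == "low"), nrow = length(all_cids)),
    1L, any, na.rm = TRUE)
  all_cids[ok_t & ok_p & !any_low]
}
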