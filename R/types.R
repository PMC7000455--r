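#' Experimental condition key
#'
#' Identifies one drug-perturbation experiment by the tuple
#' (compound CID, cell line, dose, time). Replicates sharing a full key are
#' collapsed before a signature is built, and the repositioning score is
#' maximised over a drug's distinct keys.
#'
#' @param cid PubChem compound identifier, a single positive integer.
#' @param cell_line,dose,time Single non-empty strings (numerics are
#'   accepted and converted). Fields are whitespace-trimmed and case-folded
#'   so that keys compare reliably across sources.
#' @return An object of class `condition_key`: a list with fields `cid`,
#'   `cell_line`, `dose`, `time`.
#' @examples
#' condition_key(26757, "MCF7", "10uM", "6h")
#' @export
condition_key <- function(cid, cell_line, dose, time) {
  cid <- as.integer(cid)
  if (length(cid) != 1L || is.na(cid) || cid <= 0L) {
    stop("'cid' must be a single positive integer")
  }
  norm <- function(x, what) {
    x <- tolower(trimws(as.character(x)))
    if (length(x) != 1L || is.na(x) || !nzchar(x)) {
      stop(sprintf("condition key field '%s' must be a single non-empty value", what))
    }
    x
  }
  structure(
    list(cid = cid, cell_line = norm(cell_line, "cell_line"),
         dose = norm(dose, "dose"), time = norm(time, "time")),
    class = "condition_key"
  )
}

#' @export
format.condition_key <- function(x, ...) {
  paste(x$cid, x$cell_line, x$dose, x$time, sep = "|")
}

#' @export
print.condition_key <- function(x, ...) {
  cat("<condition_key> ", format(x), "\n", sep = "")
  invisible(x)
}

key_string <- function(key) format(key)

#' Gene-by-sample expression profile
#'
#' The raw material for perturbation signatures: a non-negative intensity
#' matrix (genes in rows) together with per-sample metadata. Treated samples
#' must carry the full experimental condition (cid, cell line, dose, time);
#' case/normal samples are used for disease signatures.
#'
#' @param values Numeric matrix of non-negative intensities, rownames = gene
#'   identifiers (unique, non-empty).
#' @param sample_meta `data.frame` with one row per column of `values`,
#'   containing at least `sample_id` and `role` (one of `treated`,
#'   `control`, `case`, `normal`); treated rows additionally need
#'   `cid`, `cell_line`, `dose`, `time` (`compound_name` is optional and
#'   carried through untouched).
#' @return An object of class `expression_profile` (list with `values` and
#'   `sample_meta`).
#' @export
expression_profile <- function(values, sample_meta) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)) ||
      any(!nzchar(rownames(values)))) {
    stop("'values' must have unique, non-empty rownames (gene identifiers)")
  }
  if (!is.numeric(values)) stop("'values' must be numeric")
  if (any(is.na(values)) || any(values < 0)) {
    stop("expression intensities must be non-negative and non-missing")
  }
  sample_meta <- as.data.frame(sample_meta, stringsAsFactors = FALSE)
  required <- c("sample_id", "role")
  if (!all(required %in% names(sample_meta))) {
    stop("'sample_meta' needs columns: ", paste(required, collapse = ", "))
  }
  if (nrow(sample_meta) != ncol(values)) {
    stop("one metadata row per sample column required")
  }
  roles <- c("treated", "control", "case", "normal")
  if (!all(sample_meta$role %in% roles)) {
    stop("sample roles must be one of: ", paste(roles, collapse = ", "))
  }
  if (is.null(colnames(values))) colnames(values) <- sample_meta$sample_id
  if (!identical(colnames(values), as.character(sample_meta$sample_id))) {
    stop("column names of 'values' must match sample_meta$sample_id (in order)")
  }
  treated <- sample_meta$role == "treated"
  if (any(treated)) {
    cond_cols <- c("cid", "cell_line", "dose", "time")
    if (!all(cond_cols %in% names(sample_meta))) {
      stop("treated samples require metadata columns: ",
           paste(cond_cols, collapse = ", "))
    }
    has_name <- if ("compound_name" %in% names(sample_meta)) {
      !is.na(sample_meta$compound_name) &
        nzchar(trimws(as.character(sample_meta$compound_name)))
    } else rep(FALSE, nrow(sample_meta))
    blank <- function(x) is.na(x) | !nzchar(trimws(as.character(x)))
    # a treated sample needs the full condition; the compound may be given
    # as a CID or as a name resolved later through a mapping table
    bad <- treated & ((is.na(sample_meta$cid) & !has_name) |
                        blank(sample_meta$cell_line) |
                        blank(sample_meta$dose) |
                        blank(sample_meta$time))
    if (any(bad)) {
      stop("treated samples missing condition fields: ",
           paste(sample_meta$sample_id[bad], collapse = ", "))
    }
  }
  structure(list(values = values, sample_meta = sample_meta),
            class = "expression_profile")
}

#' @export
print.expression_profile <- function(x, ...) {
  cat(sprintf("<expression_profile> %d genes x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s:%d", names(table(x$sample_meta$role)),
                            as.integer(table(x$sample_meta$role))),
                    collapse = ", ")))
  invisible(x)
}

#' @export
dim.expression_profile <- function(x) dim(x$values)

#' Per-gene log2 fold-change perturbation signature
#'
#' A mapping gene identifier -> log2 fold change (F). Drug signatures
#' (origin `DGPS`) carry the [condition_key()] of the experiment; disease
#' signatures (`CGPS`, `AGPS` for transcripts, `APPS` for proteins) carry a
#' free-text disease label.
#'
#' @param entries Named numeric vector of finite log2 fold changes; names
#'   are unique gene identifiers.
#' @param origin One of `"DGPS"`, `"CGPS"`, `"AGPS"`, `"APPS"`.
#' @param key A [condition_key()] (required when `origin == "DGPS"`).
#' @param disease Disease label (disease origins only).
#' @return A named numeric vector of class `perturbation_signature` with
#'   attributes `origin`, `key`, `disease`.
#' @examples
#' perturbation_signature(c(g1 = -1, g2 = 0.5), "CGPS", disease = "demo")
#' @export
perturbation_signature <- function(entries,
                                   origin = c("DGPS", "CGPS", "AGPS", "APPS"),
                                   key = NULL, disease = NULL) {
  origin <- match.arg(origin)
  entries <- unlist(entries)
  if (length(entries) && (is.null(names(entries)) ||
                          anyDuplicated(names(entries)) ||
                          any(!nzchar(names(entries))))) {
    stop("signature entries must have unique, non-empty gene names")
  }
  storage.mode(entries) <- "double"
  if (any(!is.finite(entries))) stop("all fold changes must be finite")
  if (origin == "DGPS") {
    if (!inherits(key, "condition_key")) {
      stop("a DGPS signature requires a 'condition_key'")
    }
  } else if (!is.null(key)) {
    stop("'key' is only meaningful for DGPS signatures")
  }
  structure(entries, class = "perturbation_signature",
            origin = origin, key = key, disease = disease)
}

#' @export
print.perturbation_signature <- function(x, ...) {
  origin <- attr(x, "origin")
  tag <- if (origin == "DGPS") format(attr(x, "key")) else
    (attr(x, "disease") %||% "<unlabelled>")
  cat(sprintf("<perturbation_signature %s> %d genes [%s]\n",
              origin, length(x), tag))
  if (length(x)) {
    show <- utils::head(unclass(x), 5L)
    print(show)
    if (length(x) > 5L) cat("...\n")
  }
  invisible(x)
}

#' @export
as.data.frame.perturbation_signature <- function(x, ...) {
  data.frame(gene_id = names(x), log2fc = as.numeric(x),
             stringsAsFactors = FALSE, row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

sig_origin <- function(sig) attr(sig, "origin")
sig_key <- function(sig) attr(sig, "key")

#' Drug-induced signature database
#'
#' A collection of DGPS signatures, one per distinct experimental condition,
#' with an index mapping each compound to its conditions. Usually built by
#' [assemble_database()] or [build_signature_db()].
#'
#' @param signatures List of DGPS [perturbation_signature()] objects with
#'   pairwise-distinct condition keys.
#' @return An object of class `signature_db`: list with `signatures` (named
#'   by key string) and `index` (data.frame: cid, cell_line, dose, time, key).
#' @seealso [assemble_database()], [write_signature_db()]
#' @export
signature_db <- function(signatures = list()) {
  assemble_database(signatures)
}

#' @export
print.signature_db <- function(x, ...) {
  cat(sprintf("<signature_db> %d signatures, %d compounds, %d cell lines\n",
              length(x$signatures),
              length(unique(x$index$cid)),
              length(unique(x$index$cell_line))))
  invisible(x)
}

#' @export
length.signature_db <- function(x) length(x$signatures)

#' Pharmacogene list
#'
#' Genes annotated as drug targets, enzymes, transporters or carriers. The
#' repositioning score weights perturbation evidence restricted to this set.
#'
#' @param genes Character vector of gene identifiers (duplicates dropped).
#' @return Character vector of class `pharmacogene_list`.
#' @export
pharmacogene_list <- function(genes) {
  genes <- unique(as.character(genes))
  genes <- genes[nzchar(genes)]
  structure(genes, class = "pharmacogene_list")
}

#' @export
print.pharmacogene_list <- function(x, ...) {
  cat(sprintf("<pharmacogene_list> %d genes\n", length(x)))
  invisible(x)
}

#' Prescribed-drug gold standard
#'
#' The set of compounds actually prescribed for a disease, used as positive
#' labels when validating score rankings by ROC/AUC.
#'
#' @param cids Positive integer PubChem CIDs (duplicates dropped).
#' @param disease_label Free-text disease name.
#' @return List of class `gold_standard` with `disease_label` and `cids`.
#' @export
gold_standard <- function(cids, disease_label = "disease") {
  cids <- unique(as.integer(cids))
  if (length(cids) == 0L || any(is.na(cids)) || any(cids <= 0L)) {
    stop("gold standard requires a non-empty set of positive integer CIDs")
  }
  structure(list(disease_label = as.character(disease_label), cids = cids),
            class = "gold_standard")
}

#' @export
print.gold_standard <- function(x, ...) {
  cat(sprintf("<gold_standard %s> %d prescribed CIDs\n",
              x$disease_label, length(x$cids)))
  invisible(x)
}
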