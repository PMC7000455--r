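#' Normalize a compound name for offline CID lookup
#'
#' Deterministic, offline stand-in for name standardization: case-folds,
#' collapses internal whitespace, trims leading/trailing whitespace and
#' punctuation. The result is the lookup key into a [read_cid_map()] table.
#'
#' @param raw Character vector of raw compound names; every element must be
#'   non-empty (and remain non-empty after trimming).
#' @return Character vector of normalized names.
#' @examples
#' normalize_name(" Selegiline ")   # "selegiline"
#' @export
normalize_name <- function(raw) {
  if (!is.character(raw) || length(raw) == 0L) {
    stop("'raw' must be a non-empty character vector")
  }
  if (any(is.na(raw)) || any(!nzchar(trimws(raw)))) {
    stop("compound names must be non-empty")
  }
  x <- tolower(trimws(raw))
  x <- gsub("[[:space:]]+", " ", x)
  x <- gsub("^[[:punct:][:space:]]+|[[:punct:][:space:]]+$", "", x)
  if (any(!nzchar(x))) stop("compound name is empty after normalization")
  x
}

#' Map compound names to PubChem CIDs through an offline table
#'
#' Looks up [normalize_name()]-normalized names in a curated mapping table.
#' Unmapped names yield `NA` (a missing marker, not an error): profiles for
#' unmapped compounds are simply excluded downstream, so only CID-mapped
#' compounds enter the signature database.
#'
#' @param raw Character vector of compound names.
#' @param table Mapping table from [read_cid_map()] (data.frame with
#'   `raw_name` already normalized, `cid`).
#' @return Integer vector of CIDs, `NA` where unmapped.
#' @export
map_to_cid <- function(raw, table) {
  stopifnot(is.data.frame(table), all(c("raw_name", "cid") %in% names(table)))
  idx <- match(normalize_name(raw), table$raw_name)
  as.integer(table$cid[idx])
}

#' Collapse replicate samples of one experimental condition
#'
#' All treated samples sharing the full condition key (cid, cell line, dose,
#' time) are replaced by their per-gene arithmetic mean; control samples of
#' the same cell line are collapsed likewise. Controls are matched within
#' cell line only (vehicle controls are shared across doses and times).
#'
#' @param profile An [expression_profile()] holding treated and control
#'   samples.
#' @param key A [condition_key()].
#' @return An [expression_profile()] with exactly two samples: the collapsed
#'   treated profile and the collapsed cell-line control.
#' @export
collapse_replicates <- function(profile, key) {
  stopifnot(inherits(profile, "expression_profile"),
            inherits(key, "condition_key"))
  meta <- profile$sample_meta
  fold <- function(x) tolower(trimws(as.character(x)))
  is_treated <- meta$role == "treated" &
    !is.na(meta$cid) & as.integer(meta$cid) == key$cid &
    fold(meta$cell_line) == key$cell_line &
    fold(meta$dose) == key$dose &
    fold(meta$time) == key$time
  if (!any(is_treated)) {
    stop("no treated sample matches condition ", format(key))
  }
  is_control <- meta$role == "control" & fold(meta$cell_line) == key$cell_line
  if (!any(is_control)) {
    stop("no control sample in cell line '", key$cell_line, "'")
  }
  treated_mean <- rowMeans(profile$values[, is_treated, drop = FALSE])
  control_mean <- rowMeans(profile$values[, is_control, drop = FALSE])
  values <- cbind(treated = treated_mean, control = control_mean)
  first_treated <- which(is_treated)[1L]
  meta_out <- data.frame(
    sample_id = c("treated", "control"),
    role = c("treated", "control"),
    compound_name = c(
      if ("compound_name" %in% names(meta))
        as.character(meta$compound_name[first_treated]) else NA_character_,
      NA_character_),
    cid = c(key$cid, NA_integer_),
    cell_line = key$cell_line,
    dose = c(key$dose, NA_character_),
    time = c(key$time, NA_character_),
    stringsAsFactors = FALSE
  )
  expression_profile(values, meta_out)
}

#' Build a drug-induced gene perturbation signature (DGPS)
#'
#' For every gene k, the signature entry is
#' `F_k = log2((E_treated_k + pc) / (E_control_k + pc))` with pseudocount
#' `pc`. Genes whose fold change is not finite (both offset intensities
#' zero, or a zero denominator at `pc = 0`) are dropped with a warning
#' rather than raising an error.
#'
#' @param profile A replicate-collapsed [expression_profile()] (two samples:
#'   treated, control), e.g. from [collapse_replicates()].
#' @param key The [condition_key()] of the experiment.
#' @param pseudocount Non-negative offset added to both intensities before
#'   the ratio. Use 1 for count-like data; 0 for intensities already
#'   bounded away from zero.
#' @return A DGPS [perturbation_signature()].
#' @examples
#' prof <- expression_profile(
#'   matrix(c(8, 5, 2, 5), 2, 2,
#'          dimnames = list(c("g1", "g2"), c("treated", "control"))),
#'   data.frame(sample_id = c("treated", "control"),
#'              role = c("treated", "control"), cid = c(10L, NA),
#'              cell_line = "mcf7", dose = c("10um", NA), time = c("6h", NA)))
#' build_dgps(prof, condition_key(10, "mcf7", "10um", "6h"))  # g1: 2, g2: 0
#' @export
build_dgps <- function(profile, key, pseudocount = 0) {
  stopifnot(inherits(profile, "expression_profile"),
            inherits(key, "condition_key"),
            length(pseudocount) == 1L, pseudocount >= 0)
  meta <- profile$sample_meta
  t_col <- which(meta$role == "treated")
  c_col <- which(meta$role == "control")
  if (length(t_col) != 1L || length(c_col) != 1L) {
    stop("'profile' must be replicate-collapsed: exactly one treated and one control sample")
  }
  num <- profile$values[, t_col] + pseudocount
  den <- profile$values[, c_col] + pseudocount
  f <- stats::setNames(log2(num / den), rownames(profile$values))
  drop <- !is.finite(f)
  if (any(drop)) {
    warning(sprintf("%d gene(s) dropped: fold change undefined at pseudocount %g",
                    sum(drop), pseudocount))
    f <- f[!drop]
  }
  perturbation_signature(f, origin = "DGPS", key = key)
}

#' Assemble DGPS signatures into a signature database
#'
#' @param signatures List of DGPS [perturbation_signature()] objects; their
#'   condition keys must be pairwise distinct (collapse replicates first).
#' @return A `signature_db` whose `index` (cid, cell_line, dose, time, key)
#'   is consistent with the stored signatures.
#' @export
assemble_database <- function(signatures) {
  stopifnot(is.list(signatures))
  if (length(signatures)) {
    ok <- vapply(signatures, function(s)
      inherits(s, "perturbation_signature") && sig_origin(s) == "DGPS", logical(1))
    if (!all(ok)) stop("all signatures must be DGPS perturbation signatures")
  }
  keys <- vapply(signatures, function(s) key_string(sig_key(s)), character(1))
  if (anyDuplicated(keys)) {
    stop("duplicate condition key(s): ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "))
  }
  names(signatures) <- keys
  index <- if (length(signatures)) {
    do.call(rbind, lapply(signatures, function(s) {
      k <- sig_key(s)
      data.frame(cid = k$cid, cell_line = k$cell_line, dose = k$dose,
                 time = k$time, key = key_string(k), stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(cid = integer(), cell_line = character(), dose = character(),
               time = character(), key = character(), stringsAsFactors = FALSE)
  }
  rownames(index) <- NULL
  structure(list(signatures = signatures, index = index), class = "signature_db")
}

#' Build a signature database from expression data
#'
#' High-level constructor: normalizes compound names against a CID mapping
#' table, drops profiles of unmapped compounds, collapses replicates per
#' distinct (cid, cell line, dose, time) condition, computes log2
#' fold-change signatures against cell-line controls and assembles the
#' database.
#'
#' @param profile An [expression_profile()] containing treated and control
#'   samples. Treated rows may carry `cid` directly, or a `compound_name`
#'   to be resolved through `cid_map`.
#' @param cid_map Optional mapping table from [read_cid_map()].
#' @inheritParams build_dgps
#' @return A `signature_db`.
#' @export
build_signature_db <- function(profile, cid_map = NULL, pseudocount = 0) {
  stopifnot(inherits(profile, "expression_profile"))
  meta <- profile$sample_meta
  treated <- meta[meta$role == "treated", , drop = FALSE]
  if (nrow(treated) == 0L) stop("no treated samples in profile")
  cid <- suppressWarnings(as.integer(treated$cid))
  if (!is.null(cid_map) && "compound_name" %in% names(treated)) {
    unmapped <- is.na(cid) & !is.na(treated$compound_name)
    if (any(unmapped)) {
      cid[unmapped] <- map_to_cid(as.character(treated$compound_name[unmapped]),
                                  cid_map)
    }
  }
  keep <- !is.na(cid)
  if (!any(keep)) stop("no treated sample maps to a CID")
  if (any(!keep)) {
    message(sprintf("excluding %d treated sample(s) without CID mapping",
                    sum(!keep)))
  }
  # write resolved CIDs back so replicate matching sees them
  meta$cid <- suppressWarnings(as.integer(meta$cid))
  meta$cid[meta$role == "treated"] <- cid
  keep_sample <- meta$role != "treated" | !is.na(meta$cid)
  profile <- expression_profile(profile$values[, keep_sample, drop = FALSE],
                                meta[keep_sample, , drop = FALSE])
  treated <- treated[keep, , drop = FALSE]
  cid <- cid[keep]
  fold <- function(x) tolower(trimws(as.character(x)))
  cond <- unique(data.frame(cid = cid, cell_line = fold(treated$cell_line),
                            dose = fold(treated$dose), time = fold(treated$time),
                            stringsAsFactors = FALSE))
  sigs <- lapply(seq_len(nrow(cond)), function(i) {
    key <- condition_key(cond$cid[i], cond$cell_line[i], cond$dose[i],
                         cond$time[i])
    build_dgps(collapse_replicates(profile, key), key,
               pseudocount = pseudocount)
  })
  assemble_database(sigs)
}
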