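# All on-disk formats are plain tab-separated text. Fold changes are
# written with 17 significant digits so that write/read round-trips are
# bit-exact for IEEE doubles. Lines starting with '#' are header comments
# (version/seed/parameters) and are skipped on read.

fmt_dbl <- function(x) sprintf("%.17g", x)

write_tsv_commented <- function(df, path, header_lines = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_lines)) {
    writeLines(paste0("# ", header_lines), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
}

read_tsv_commented <- function(path, colClasses = NA) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    colClasses = colClasses, check.names = FALSE,
                    na.strings = c("NA", ""))
}

run_header <- function(seed = NULL, params = character()) {
  c(sprintf("drpsc %s", as.character(utils::packageVersion("drpsc"))),
    if (!is.null(seed)) sprintf("seed: %s", seed),
    params)
}

#' Read a wide gene-by-sample expression matrix
#'
#' Tab-separated text: first column gene identifiers, remaining columns
#' one sample each. `#`-prefixed lines are skipped.
#'
#' @param path File path.
#' @return Numeric matrix with gene rownames.
#' @export
read_expression_matrix <- function(path) {
  df <- read_tsv_commented(path)
  if (ncol(df) < 2L) stop("expression matrix needs a gene column and samples")
  genes <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  m
}

#' Read per-sample metadata
#'
#' Tab-separated text with columns `sample_id`, `role` and (for treated
#' samples) `compound_name`/`cid`, `cell_line`, `dose`, `time`.
#'
#' @param path File path.
#' @return `data.frame`.
#' @export
read_sample_meta <- function(path) {
  meta <- read_tsv_commented(path)
  if (!all(c("sample_id", "role") %in% names(meta))) {
    stop("sample metadata needs at least 'sample_id' and 'role'")
  }
  meta$sample_id <- as.character(meta$sample_id)
  if ("cid" %in% names(meta)) meta$cid <- suppressWarnings(as.integer(meta$cid))
  meta
}

#' Read an expression profile (matrix + metadata)
#'
#' @param expr_path Wide matrix TSV (see [read_expression_matrix()]), or a
#'   GCT 1.2/1.3 file when `gct = TRUE`.
#' @param meta_path Sample metadata TSV.
#' @param gct Treat `expr_path` as GCT.
#' @return An [expression_profile()].
#' @export
read_expression_profile <- function(expr_path, meta_path, gct = FALSE) {
  values <- if (gct) read_gct(expr_path) else read_expression_matrix(expr_path)
  meta <- read_sample_meta(meta_path)
  idx <- match(colnames(values), meta$sample_id)
  if (any(is.na(idx))) {
    stop("samples missing from metadata: ",
         paste(colnames(values)[is.na(idx)], collapse = ", "))
  }
  expression_profile(values, meta[idx, , drop = FALSE])
}

#' Read a GCT 1.2 / 1.3 expression matrix
#'
#' Minimal reader for the GCT dialect: a version line (`#1.2` or `#1.3`), a
#' dimension line, then a header row starting with the id and description
#' columns (GCT 1.3 row/column annotations are skipped using the dimension
#' line).
#'
#' @param path File path.
#' @return Numeric matrix with gene rownames.
#' @export
read_gct <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L) stop("not a GCT file: too short")
  version <- trimws(lines[1L])
  if (!version %in% c("#1.2", "#1.3")) {
    stop("unsupported GCT version line: ", version)
  }
  dims <- as.integer(strsplit(trimws(lines[2L]), "\t")[[1L]])
  n_row <- dims[1L]; n_col <- dims[2L]
  n_rmeta <- if (version == "#1.3" && length(dims) >= 4L) dims[3L] else 1L
  n_cmeta <- if (version == "#1.3" && length(dims) >= 4L) dims[4L] else 0L
  header <- strsplit(lines[3L], "\t")[[1L]]
  sample_ids <- utils::tail(header, n_col)
  data_lines <- lines[(3L + n_cmeta + 1L):(3L + n_cmeta + n_row)]
  fields <- strsplit(data_lines, "\t")
  ids <- vapply(fields, `[[`, character(1), 1L)
  m <- t(vapply(fields, function(f)
    as.numeric(utils::tail(f, n_col)), numeric(n_col)))
  dimnames(m) <- list(ids, sample_ids)
  m
}

#' Read a compound-name-to-CID mapping table
#'
#' Two-column TSV (`raw_name`, `cid`) with header. Names are normalized
#' with [normalize_name()] and must be unique afterwards; CIDs must be
#' positive.
#'
#' @param path File path.
#' @return `data.frame` with normalized `raw_name` and integer `cid`.
#' @export
read_cid_map <- function(path) {
  df <- read_tsv_commented(path)
  if (!all(c("raw_name", "cid") %in% names(df))) {
    stop("CID mapping table needs columns 'raw_name' and 'cid'")
  }
  df$raw_name <- normalize_name(as.character(df$raw_name))
  df$cid <- as.integer(df$cid)
  if (anyDuplicated(df$raw_name)) {
    stop("duplicate compound names after normalization: ",
         paste(unique(df$raw_name[duplicated(df$raw_name)]), collapse = ", "))
  }
  if (any(is.na(df$cid)) || any(df$cid <= 0L)) stop("CIDs must be positive")
  df[, c("raw_name", "cid")]
}

#' Read a pharmacogene list
#'
#' One gene identifier per line; blank and `#`-comment lines are skipped.
#'
#' @param path File path.
#' @return A [pharmacogene_list()].
#' @export
read_pgl <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  pharmacogene_list(lines)
}

#' Read a prescribed-drug gold standard
#'
#' One CID per line; blank and `#`-comment lines are skipped.
#'
#' @param path File path.
#' @param disease_label Label attached to the gold standard.
#' @return A [gold_standard()].
#' @export
read_gold_standard <- function(path, disease_label = "disease") {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  gold_standard(as.integer(lines), disease_label)
}

#' Write / read a perturbation signature
#'
#' Two-column TSV (`gene_id`, `log2fc`); fold changes round-trip
#' bit-exactly.
#'
#' @param sig A [perturbation_signature()].
#' @param path File path.
#' @param header_lines Extra `#` header comment lines.
#' @return `write_signature()` returns `path` invisibly; `read_signature()`
#'   the signature.
#' @export
write_signature <- function(sig, path, header_lines = character()) {
  stopifnot(inherits(sig, "perturbation_signature"))
  df <- data.frame(gene_id = names(sig), log2fc = fmt_dbl(as.numeric(sig)),
                   stringsAsFactors = FALSE)
  write_tsv_commented(df, path, header_lines)
  invisible(path)
}

#' @rdname write_signature
#' @param origin,key,disease Signature attributes to attach on read (see
#'   [perturbation_signature()]).
#' @export
read_signature <- function(path, origin = "CGPS", key = NULL, disease = NULL) {
  df <- read_tsv_commented(path, colClasses = c("character", "character"))
  if (!all(c("gene_id", "log2fc") %in% names(df))) {
    stop("signature file needs columns 'gene_id' and 'log2fc'")
  }
  perturbation_signature(stats::setNames(as.numeric(df$log2fc), df$gene_id),
                         origin = origin, key = key, disease = disease)
}

#' Write / read a drug signature database directory
#'
#' The database is laid out as one signature TSV per condition plus a
#' `manifest.tsv` (`cid`, `cell_line`, `dose`, `time`, `path`). Reloading
#' reproduces identical fold changes and index.
#'
#' @param db A `signature_db`.
#' @param dir Directory (created if needed).
#' @param header_lines Extra `#` header comment lines for the manifest.
#' @return `write_signature_db()` returns `dir` invisibly;
#'   `read_signature_db()` the database.
#' @export
write_signature_db <- function(db, dir, header_lines = character()) {
  stopifnot(inherits(db, "signature_db"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(db$signatures))
  for (i in seq_along(db$signatures)) {
    paths[i] <- sprintf("sig_%05d.tsv", i)
    write_signature(db$signatures[[i]], file.path(dir, paths[i]))
  }
  manifest <- cbind(db$index[, c("cid", "cell_line", "dose", "time")],
                    path = paths)
  write_tsv_commented(manifest, file.path(dir, "manifest.tsv"), header_lines)
  invisible(dir)
}

#' @rdname write_signature_db
#' @export
read_signature_db <- function(dir) {
  manifest_path <- file.path(dir, "manifest.tsv")
  if (!file.exists(manifest_path)) stop("no manifest.tsv in ", dir)
  manifest <- read_tsv_commented(manifest_path)
  sigs <- lapply(seq_len(nrow(manifest)), function(i) {
    key <- condition_key(manifest$cid[i], manifest$cell_line[i],
                         manifest$dose[i], manifest$time[i])
    read_signature(file.path(dir, manifest$path[i]), origin = "DGPS",
                   key = key)
  })
  assemble_database(sigs)
}

#' Write / read a drug score table
#'
#' Tab-separated, numeric columns bit-exact on round-trip.
#'
#' @param scores A `drug_score_table`.
#' @param path File path.
#' @param header_lines Extra `#` header comment lines.
#' @return `write_score_table()` returns `path` invisibly;
#'   `read_score_table()` the table.
#' @export
write_score_table <- function(scores, path, header_lines = character()) {
  stopifnot(is.data.frame(scores))
  out <- scores
  for (col in intersect(c("drps", "gene_mean", "pg_mean"), names(out))) {
    out[[col]] <- fmt_dbl(out[[col]])
  }
  write_tsv_commented(out, path, header_lines)
  invisible(path)
}

#' @rdname write_score_table
#' @export
read_score_table <- function(path) {
  df <- read_tsv_commented(path)
  for (col in intersect(c("drps", "gene_mean", "pg_mean"), names(df))) {
    df[[col]] <- as.numeric(df[[col]])
  }
  if ("drpc" %in% names(df)) {
    df$drpc <- factor(df$drpc, levels = c("high", "intermediate", "low"))
  }
  class(df) <- c("drug_score_table", "data.frame")
  df
}

write_expression_profile <- function(profile, expr_path, meta_path,
                                     header_lines = character()) {
  stopifnot(inherits(profile, "expression_profile"))
  df <- data.frame(gene_id = rownames(profile$values),
                   profile$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_commented(df, expr_path, header_lines)
  write_tsv_commented(profile$sample_meta, meta_path, header_lines)
  invisible(expr_path)
}
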