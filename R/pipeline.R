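#' Run configuration
#'
#' Validated bundle of pipeline-level settings. All randomness in a run
#' flows from the single `seed`.
#'
#' @param seed Integer seed.
#' @param q_threshold Disease-signature significance threshold in (0, 1].
#' @param pseudocount Non-negative pseudocount for fold changes.
#' @param floor_negative_means Floor negative component means at zero
#'   before the score product.
#' @param transcriptomic_quantifier `"any"` or `"all"`: candidate rule
#'   quantifier over transcriptomic tables.
#' @param fc_grid Ascending positive fold-change thresholds for the
#'   signature-similarity report.
#' @param sim A [sim_config()] describing the synthetic study (its seed is
#'   overridden by `seed`).
#' @return List of class `run_config`.
#' @export
run_config <- function(seed = 1L, q_threshold = 0.05, pseudocount = 0,
                       floor_negative_means = TRUE,
                       transcriptomic_quantifier = c("any", "all"),
                       fc_grid = c(0.5, 1, 1.5, 2),
                       sim = sim_config()) {
  transcriptomic_quantifier <- match.arg(transcriptomic_quantifier)
  if (!is.numeric(q_threshold) || length(q_threshold) != 1L ||
      q_threshold <= 0 || q_threshold > 1) {
    stop("'q_threshold' must lie in (0, 1]")
  }
  if (!is.numeric(pseudocount) || pseudocount < 0) {
    stop("'pseudocount' must be non-negative")
  }
  if (any(fc_grid <= 0) || is.unsorted(fc_grid, strictly = TRUE)) {
    stop("'fc_grid' must be strictly ascending positive thresholds")
  }
  stopifnot(inherits(sim, "sim_config"))
  sim$seed <- as.integer(seed)
  structure(list(seed = as.integer(seed), q_threshold = q_threshold,
                 pseudocount = pseudocount,
                 floor_negative_means = isTRUE(floor_negative_means),
                 transcriptomic_quantifier = transcriptomic_quantifier,
                 fc_grid = fc_grid, sim = sim),
            class = "run_config")
}

#' Read a flat key = value configuration file
#'
#' Plain text, one `key = value` per line; blank lines and `#` comments are
#' skipped. Keys matching [run_config()] arguments set those; keys matching
#' [sim_config()] arguments set the simulation block; `fc_grid` takes a
#' comma-separated list. Unknown keys are an error.
#'
#' @param path File path.
#' @param overrides Named list applied on top of the file (CLI flags).
#' @return A [run_config()].
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  kv <- list()
  if (!is.null(path)) {
    lines <- trimws(readLines(path))
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    for (line in lines) {
      parts <- strsplit(line, "=", fixed = TRUE)[[1L]]
      if (length(parts) < 2L) stop("malformed config line: ", line)
      kv[[trimws(parts[1L])]] <- trimws(paste(parts[-1L], collapse = "="))
    }
  }
  kv[names(overrides)] <- overrides
  run_keys <- setdiff(names(formals(run_config)), "sim")
  sim_keys <- names(formals(sim_config))
  unknown <- setdiff(names(kv), c(run_keys, sim_keys))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  parse_val <- function(key, val) {
    if (is.character(val)) {
      if (key == "fc_grid") {
        as.numeric(strsplit(val, ",")[[1L]])
      } else if (key %in% c("floor_negative_means")) {
        tolower(val) %in% c("true", "1", "yes")
      } else if (key == "transcriptomic_quantifier") {
        val
      } else {
        as.numeric(val)
      }
    } else val
  }
  sim_args <- lapply(stats::setNames(nm = intersect(names(kv), sim_keys)),
                     function(k) parse_val(k, kv[[k]]))
  run_args <- lapply(stats::setNames(nm = intersect(names(kv), run_keys)),
                     function(k) parse_val(k, kv[[k]]))
  run_args$sim <- do.call(sim_config, sim_args)
  if (!is.null(run_args$seed)) run_args$seed <- as.integer(run_args$seed)
  do.call(run_config, run_args)
}

#' Run the full synthetic repositioning pipeline
#'
#' Orchestrates simulate -> build-db -> disease-sig -> score -> classify ->
#' evaluate -> candidates through the on-disk formats: the synthetic study
#' is written out as expression matrices, metadata, CID mapping,
#' pharmacogene list and gold standard; the signature database is then
#' rebuilt from those files, disease signatures derived, drugs scored and
#' classified against both omics layers, per-class AUC computed, the
#' similarity report produced, and candidates selected. Every output file
#' carries a `#` header recording version, seed and parameters. On failure
#' the partially written output directory is removed.
#'
#' @param config A [run_config()] (or path to a key = value file).
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, the list of result objects (see [simulate_study()]),
#'   plus `paths` to the written artifacts.
#' @export
run_pipeline <- function(config = run_config(), out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  created <- !dir.exists(out_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ok <- FALSE
  on.exit(if (!ok && created) unlink(out_dir, recursive = TRUE), add = TRUE)

  hdr <- run_header(config$seed, c(
    sprintf("q_threshold: %g", config$q_threshold),
    sprintf("floor_negative_means: %s", config$floor_negative_means),
    sprintf("transcriptomic_quantifier: %s", config$transcriptomic_quantifier)))
  p <- function(...) file.path(out_dir, ...)

  # simulate the study and write every input the downstream steps consume
  disease <- simulate_disease(config$sim)
  de_rna <- differential_test(disease$case, disease$normal,
                              method = "log_welch_t",
                              pseudocount = config$pseudocount)
  dsig_rna <- make_disease_signature(de_rna, config$q_threshold,
                                     origin = "AGPS", disease = "synthetic")
  drugs <- simulate_drug_db(config$sim, dsig_rna)
  expr <- db_to_expression(drugs$db, config$sim$baseline_log2)

  write_expression_profile(disease$case, p("disease_case.tsv"),
                           p("disease_case_meta.tsv"), hdr)
  write_expression_profile(disease$normal, p("disease_normal.tsv"),
                           p("disease_normal_meta.tsv"), hdr)
  write_expression_profile(expr$profile, p("drug_expr.tsv"),
                           p("drug_meta.tsv"), hdr)
  write_tsv_commented(expr$cid_map, p("cid_map.tsv"), hdr)
  writeLines(c(paste0("# ", hdr), as.character(drugs$pgl)), p("pgl.txt"))
  writeLines(c(paste0("# ", hdr), as.character(drugs$gold$cids)),
             p("gold.txt"))

  # rebuild the database and signatures from the written files
  drug_profile <- read_expression_profile(p("drug_expr.tsv"),
                                          p("drug_meta.tsv"))
  db <- build_signature_db(drug_profile, read_cid_map(p("cid_map.tsv")),
                           pseudocount = config$pseudocount)
  write_signature_db(db, p("dgpsd"), hdr)
  pgl <- read_pgl(p("pgl.txt"))
  gold <- read_gold_standard(p("gold.txt"), "synthetic")

  case <- read_expression_profile(p("disease_case.tsv"),
                                  p("disease_case_meta.tsv"))
  normal <- read_expression_profile(p("disease_normal.tsv"),
                                    p("disease_normal_meta.tsv"))
  de_rna <- differential_test(case, normal, method = "log_welch_t",
                              pseudocount = config$pseudocount)
  dsig_rna <- make_disease_signature(de_rna, config$q_threshold,
                                     origin = "AGPS", disease = "synthetic")
  write_signature(dsig_rna, p("dsig_rna.tsv"), hdr)

  # protein layer (smaller study sharing the same disease perturbation)
  study <- simulate_study(config$sim, q_threshold = config$q_threshold)
  dsig_protein <- study$dsig_protein
  write_signature(dsig_protein, p("dsig_protein.tsv"), hdr)

  scores_rna <- classify_drpc(score_drugs(
    db, dsig_rna, pgl, floor_negative_means = config$floor_negative_means))
  scores_protein <- classify_drpc(score_drugs(
    db, dsig_protein, pgl,
    floor_negative_means = config$floor_negative_means))
  write_score_table(scores_rna, p("scores.tsv"), hdr)
  write_score_table(scores_protein, p("scores_protein.tsv"), hdr)

  auc <- auc_per_class(scores_rna, gold)
  write_tsv_commented(auc, p("auc.tsv"), hdr)

  sim_report <- shared_deg_rate(dsig_rna, dsig_protein, config$fc_grid)
  sim_report$direction_similarity <- direction_similarity(dsig_rna,
                                                          dsig_protein)
  write_tsv_commented(sim_report, p("similarity.tsv"), hdr)

  candidates <- select_candidates(
    list(rna = scores_rna, protein = scores_protein),
    transcriptomic_labels = "rna", proteomic_labels = "protein",
    transcriptomic_quantifier = config$transcriptomic_quantifier)
  writeLines(c(paste0("# ", hdr), as.character(candidates)),
             p("candidates.txt"))

  ok <- TRUE
  invisible(list(disease = disease, db = db, dsig_rna = dsig_rna,
                 dsig_protein = dsig_protein, scores_rna = scores_rna,
                 scores_protein = scores_protein, auc = auc,
                 similarity = sim_report, candidates = candidates,
                 gold = gold,
                 paths = list(out_dir = out_dir,
                              scores = p("scores.tsv"),
                              auc = p("auc.tsv"),
                              candidates = p("candidates.txt"))))
}
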