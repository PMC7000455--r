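#' Configuration for the synthetic study generator
#'
#' Bundles and validates the parameters of the planted-reversal simulation.
#' Defaults describe a desk-scale study: a 1,000-gene universe, 100 planted
#' disease genes shifted by two log2 units, measurement noise of 0.2 log2
#' units, 50 compounds of which 10 truly reverse 90% of the disease
#' signature, each assayed under 3 conditions.
#'
#' Reversing compounds oppose the disease fold changes at a fraction of
#' their magnitude: `reversal_magnitude` (default 0.25) at the designated
#' best condition and `offtarget_magnitude` (default 0.75, nearer full
#' negation and therefore lower-scoring) at the remaining conditions, which
#' makes the max-over-conditions rule observable. Pharmacogenes are drawn
#' with `pgl_enrichment_in_reversers` of the list taken from disease-
#' signature genes.
#'
#' @param n_genes Size of the gene universe.
#' @param n_degs Number of planted disease genes.
#' @param n_drugs,n_reversers Compounds in the database / true reversers.
#' @param reversal_fraction Fraction of disease-signature genes a reverser
#'   inverts.
#' @param effect_size Mean |log2 fold change| of planted disease genes.
#' @param noise_sd Gaussian noise SD on the log2 scale (both omics layers).
#' @param n_case,n_normal Disease-layer sample sizes.
#' @param pgl_fraction Pharmacogene-list size as a fraction of the universe.
#' @param pgl_enrichment_in_reversers Fraction of the pharmacogene list
#'   drawn from disease-signature genes.
#' @param n_conditions_per_drug Experimental conditions per compound.
#' @param reversal_magnitude,offtarget_magnitude Drug/disease fold-change
#'   magnitude ratios at the best / other conditions, in (0, 1].
#' @param protein_fraction Fraction of the universe measured on the protein
#'   layer (multi-omics studies only).
#' @param n_case_protein,n_normal_protein Protein-layer sample sizes.
#' @param baseline_log2 Baseline log2 intensity of unperturbed genes.
#' @param seed Integer seed; all generator randomness flows from it.
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 1000L, n_degs = 100L, n_drugs = 50L,
                       n_reversers = 10L, reversal_fraction = 0.9,
                       effect_size = 2, noise_sd = 0.2,
                       n_case = 10L, n_normal = 10L,
                       pgl_fraction = 0.1, pgl_enrichment_in_reversers = 0.3,
                       n_conditions_per_drug = 3L,
                       reversal_magnitude = 0.25, offtarget_magnitude = 0.75,
                       protein_fraction = 0.4,
                       n_case_protein = 9L, n_normal_protein = 8L,
                       baseline_log2 = 7, seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_degs = as.integer(n_degs),
              n_drugs = as.integer(n_drugs),
              n_reversers = as.integer(n_reversers),
              reversal_fraction = reversal_fraction,
              effect_size = effect_size, noise_sd = noise_sd,
              n_case = as.integer(n_case), n_normal = as.integer(n_normal),
              pgl_fraction = pgl_fraction,
              pgl_enrichment_in_reversers = pgl_enrichment_in_reversers,
              n_conditions_per_drug = as.integer(n_conditions_per_drug),
              reversal_magnitude = reversal_magnitude,
              offtarget_magnitude = offtarget_magnitude,
              protein_fraction = protein_fraction,
              n_case_protein = as.integer(n_case_protein),
              n_normal_protein = as.integer(n_normal_protein),
              baseline_log2 = baseline_log2, seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_genes >= 1L, n_degs >= 1L, n_degs <= n_genes,
              n_drugs >= 1L, n_reversers >= 0L, n_reversers <= n_drugs,
              reversal_fraction >= 0, reversal_fraction <= 1,
              effect_size >= 0, noise_sd >= 0,
              n_case >= 2L, n_normal >= 2L,
              pgl_fraction >= 0, pgl_fraction <= 1,
              pgl_enrichment_in_reversers >= 0,
              pgl_enrichment_in_reversers <= 1,
              n_conditions_per_drug >= 1L,
              reversal_magnitude > 0, reversal_magnitude <= 1,
              offtarget_magnitude > 0, offtarget_magnitude <= 1,
              protein_fraction > 0, protein_fraction <= 1,
              n_case_protein >= 2L, n_normal_protein >= 2L,
              !is.na(seed))
  })
  structure(cfg, class = "sim_config")
}

sim_gene_ids <- function(n) sprintf("g%05d", seq_len(n))

# one case/normal layer on a given gene set; deg_lfc is a named vector of
# true log2 shifts applied to case samples
simulate_layer <- function(genes, deg_lfc, n_case, n_normal, noise_sd,
                           baseline_log2, role_case = "case",
                           role_normal = "normal", prefix = "s") {
  n <- length(genes)
  shift <- stats::setNames(numeric(n), genes)
  shift[names(deg_lfc)] <- deg_lfc
  make <- function(k, role, shifted) {
    m <- matrix(baseline_log2, n, k, dimnames = list(
      genes, sprintf("%s_%s%02d", prefix, role, seq_len(k))))
    if (shifted) m <- m + shift
    m + matrix(stats::rnorm(n * k, 0, noise_sd), n, k)
  }
  case_m <- 2^make(n_case, role_case, TRUE)
  normal_m <- 2^make(n_normal, role_normal, FALSE)
  meta <- function(m, role) data.frame(sample_id = colnames(m), role = role,
                                       stringsAsFactors = FALSE)
  list(case = expression_profile(case_m, meta(case_m, role_case)),
       normal = expression_profile(normal_m, meta(normal_m, role_normal)))
}

#' Simulate a disease case/normal expression study
#'
#' Normal samples fluctuate around a common baseline; a planted subset of
#' genes is shifted by plus or minus `effect_size` log2 units in cases.
#' Gaussian noise of SD `noise_sd` is added on the log2 scale and
#' intensities are returned on the linear scale (always positive).
#' Deterministic under `config$seed`.
#'
#' @param config A [sim_config()].
#' @return List with `case` and `normal` [expression_profile()]s,
#'   `true_degs` (character vector) and `true_lfc` (named vector of planted
#'   log2 fold changes).
#' @export
simulate_disease <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  genes <- sim_gene_ids(config$n_genes)
  degs <- sample(genes, config$n_degs)
  signs <- sample(c(-1, 1), config$n_degs, replace = TRUE)
  true_lfc <- stats::setNames(signs * config$effect_size, degs)
  layer <- simulate_layer(genes, true_lfc, config$n_case, config$n_normal,
                          config$noise_sd, config$baseline_log2,
                          prefix = "rna")
  list(case = layer$case, normal = layer$normal, true_degs = degs,
       true_lfc = true_lfc)
}

#' Simulate a drug signature database with planted reversers
#'
#' Builds `n_drugs` compounds, each with `n_conditions_per_drug` condition
#' signatures over the gene universe. Reversing compounds invert a
#' `reversal_fraction` subset of the disease signature: at the designated
#' best condition the drug fold change is `-reversal_magnitude * F_disease`
#' (mild opposing perturbation, high perturbation score), at the remaining
#' conditions `-offtarget_magnitude * F_disease` (nearer full negation,
#' lower score). All other entries are Gaussian noise; non-reversers are
#' noise-only. Also returns a pharmacogene list enriched in disease genes
#' and a gold standard equal to the reverser set (or, when
#' `n_reversers = 0`, a random 20% of compounds, the null-calibration
#' convention).
#'
#' @param config A [sim_config()].
#' @param dsig Disease [perturbation_signature()] the reversers act
#'   against.
#' @return List: `db` (`signature_db`), `reversers` (CIDs), `pgl`
#'   ([pharmacogene_list()]), `gold` ([gold_standard()]).
#' @export
simulate_drug_db <- function(config, dsig) {
  stopifnot(inherits(config, "sim_config"),
            inherits(dsig, "perturbation_signature"))
  if (length(dsig) == 0L) stop("disease signature must be non-empty")
  set.seed(config$seed + 1L)
  genes <- sim_gene_ids(config$n_genes)
  if (!all(names(dsig) %in% genes)) {
    stop("disease signature genes outside the simulated universe")
  }
  cids <- 1000L + seq_len(config$n_drugs)
  reversers <- cids[seq_len(config$n_reversers)]

  n_pgl <- max(1L, round(config$pgl_fraction * config$n_genes))
  n_from_disease <- min(length(dsig),
                        round(config$pgl_enrichment_in_reversers * n_pgl))
  pgl_genes <- c(sample(names(dsig), n_from_disease),
                 sample(setdiff(genes, names(dsig)),
                        max(0L, n_pgl - n_from_disease)))
  pgl <- pharmacogene_list(pgl_genes)

  n_rev_genes <- round(config$reversal_fraction * length(dsig))
  sigs <- list()
  for (cid in cids) {
    reversed <- if (cid %in% reversers && n_rev_genes > 0L) {
      sample(names(dsig), n_rev_genes)
    } else character()
    for (e in seq_len(config$n_conditions_per_drug)) {
      f <- stats::setNames(stats::rnorm(config$n_genes, 0, config$noise_sd),
                           genes)
      if (length(reversed)) {
        rho <- if (e == 1L) config$reversal_magnitude else config$offtarget_magnitude
        f[reversed] <- -rho * as.numeric(dsig[reversed]) +
          stats::rnorm(length(reversed), 0, config$noise_sd)
      }
      key <- condition_key(cid, "cl1", "10um", sprintf("%dh", 6L * e))
      sigs[[length(sigs) + 1L]] <- perturbation_signature(f, "DGPS", key = key)
    }
  }
  gold_cids <- if (config$n_reversers > 0L) reversers else {
    sample(cids, max(1L, round(0.2 * config$n_drugs)))
  }
  list(db = assemble_database(sigs), reversers = reversers, pgl = pgl,
       gold = gold_standard(gold_cids, "synthetic"))
}

#' Back-convert a signature database to expression profiles
#'
#' Produces a treated/control expression matrix whose log2 fold changes
#' reproduce the database signatures exactly (one treated sample per
#' condition, one shared control per cell line at the baseline), together
#' with a compound-name-to-CID mapping table. Used to exercise the
#' database-construction path end to end on synthetic data.
#'
#' @param db A `signature_db`.
#' @param baseline_log2 Baseline log2 intensity of the control samples.
#' @return List: `profile` ([expression_profile()]) and `cid_map`
#'   (data.frame `raw_name`, `cid`).
#' @export
db_to_expression <- function(db, baseline_log2 = 7) {
  stopifnot(inherits(db, "signature_db"), length(db) > 0L)
  genes <- Reduce(union, lapply(db$signatures, names))
  cols <- list(); meta <- list()
  for (i in seq_along(db$signatures)) {
    sig <- db$signatures[[i]]
    key <- sig_key(sig)
    f <- stats::setNames(numeric(length(genes)), genes)
    f[names(sig)] <- as.numeric(sig)
    cols[[i]] <- 2^(baseline_log2 + f)
    meta[[i]] <- data.frame(sample_id = sprintf("trt_%04d", i),
                            role = "treated",
                            compound_name = sprintf("drug%d", key$cid),
                            cid = NA_integer_, cell_line = key$cell_line,
                            dose = key$dose, time = key$time,
                            stringsAsFactors = FALSE)
  }
  for (cl in unique(db$index$cell_line)) {
    cols[[length(cols) + 1L]] <- rep(2^baseline_log2, length(genes))
    meta[[length(meta) + 1L]] <- data.frame(
      sample_id = paste0("ctl_", cl), role = "control",
      compound_name = NA_character_, cid = NA_integer_, cell_line = cl,
      dose = NA_character_, time = NA_character_, stringsAsFactors = FALSE)
  }
  values <- do.call(cbind, cols)
  rownames(values) <- genes
  meta <- do.call(rbind, meta)
  colnames(values) <- meta$sample_id
  cid_map <- unique(data.frame(
    raw_name = sprintf("drug%d", db$index$cid), cid = db$index$cid,
    stringsAsFactors = FALSE))
  list(profile = expression_profile(values, meta), cid_map = cid_map)
}

#' Simulate a complete multi-omics repositioning study
#'
#' End-to-end convenience wrapper: simulates a transcriptomic case/normal
#' study and a smaller proteomic study sharing the same underlying disease
#' perturbation (the protein layer measures `protein_fraction` of the
#' universe, biased to include most disease genes), derives both disease
#' signatures by differential testing, plants a drug database reversing the
#' transcriptomic signature, scores and classifies every compound against
#' both signatures, evaluates per-class AUC against the gold standard and
#' applies the multi-omics candidate rule.
#'
#' @param config A [sim_config()].
#' @param q_threshold Significance threshold for both disease signatures.
#' @return List: `disease`, `de_rna`, `de_protein`, `dsig_rna`,
#'   `dsig_protein`, `drugs` (see [simulate_drug_db()]), `scores_rna`,
#'   `scores_protein` (classified tables), `auc` (per-class table on the
#'   transcriptomic scores), `candidates` (CIDs).
#' @export
simulate_study <- function(config = sim_config(), q_threshold = 0.05) {
  stopifnot(inherits(config, "sim_config"))
  disease <- simulate_disease(config)
  de_rna <- differential_test(disease$case, disease$normal,
                              method = "log_welch_t")
  dsig_rna <- make_disease_signature(de_rna, q_threshold, origin = "AGPS",
                                     disease = "synthetic")

  set.seed(config$seed + 2L)
  genes <- sim_gene_ids(config$n_genes)
  n_prot <- max(2L, round(config$protein_fraction * config$n_genes))
  n_deg_prot <- min(config$n_degs, round(0.8 * n_prot), config$n_degs)
  prot_degs <- sample(disease$true_degs, n_deg_prot)
  prot_genes <- union(prot_degs,
                      sample(setdiff(genes, disease$true_degs),
                             max(0L, n_prot - n_deg_prot)))
  prot_layer <- simulate_layer(prot_genes,
                               disease$true_lfc[prot_degs],
                               config$n_case_protein, config$n_normal_protein,
                               config$noise_sd, config$baseline_log2,
                               prefix = "prot")
  de_protein <- differential_test(prot_layer$case, prot_layer$normal,
                                  method = "log_welch_t")
  dsig_protein <- make_disease_signature(de_protein, q_threshold,
                                         origin = "APPS",
                                         disease = "synthetic")

  drugs <- simulate_drug_db(config, dsig_rna)
  scores_rna <- classify_drpc(score_drugs(drugs$db, dsig_rna, drugs$pgl))
  scores_protein <- classify_drpc(score_drugs(drugs$db, dsig_protein,
                                              drugs$pgl))
  auc <- auc_per_class(scores_rna, drugs$gold)
  candidates <- select_candidates(
    list(rna = scores_rna, protein = scores_protein),
    transcriptomic_labels = "rna", proteomic_labels = "protein")
  list(disease = disease, de_rna = de_rna, de_protein = de_protein,
       dsig_rna = dsig_rna, dsig_protein = dsig_protein, drugs = drugs,
       scores_rna = scores_rna, scores_protein = scores_protein,
       auc = auc, candidates = candidates)
}
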