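# Small in-code fixtures shared across test files.

# treated/control profile in one cell line with replicates
tiny_drug_profile <- function() {
  values <- matrix(
    c(4, 6, 7, 2, 3,    # g1: treated reps 4,6 (cid 10) / 7 (cid 11); ctl 2,3
      8, 8, 2, 4, 4,    # g2
      1, 3, 5, 2, 2),   # g3
    nrow = 3, byrow = TRUE,
    dimnames = list(c("g1", "g2", "g3"),
                    c("t1", "t2", "t3", "c1", "c2")))
  meta <- data.frame(
    sample_id = c("t1", "t2", "t3", "c1", "c2"),
    role = c("treated", "treated", "treated", "control", "control"),
    compound_name = c("Selegiline", "Selegiline", "iproniazid", NA, NA),
    cid = c(10L, 10L, 11L, NA, NA),
    cell_line = "mcf7",
    dose = c("10um", "10um", "10um", NA, NA),
    time = c("6h", "6h", "6h", NA, NA),
    stringsAsFactors = FALSE)
  expression_profile(values, meta)
}

tiny_cid_map <- function() {
  data.frame(raw_name = c("selegiline", "iproniazid"),
             cid = c(26757L, 3748L), stringsAsFactors = FALSE)
}

# case/normal matrices with planted shifts on the first `n_deg` genes
tiny_disease_matrices <- function(n_genes = 50, n_deg = 10, n = 6,
                                  effect = 2, sd = 0.2, seed = 42) {
  set.seed(seed)
  genes <- sprintf("g%03d", seq_len(n_genes))
  base <- matrix(stats::rnorm(n_genes * 2 * n, 7, sd), n_genes, 2 * n,
                 dimnames = list(genes, c(sprintf("case%d", seq_len(n)),
                                          sprintf("norm%d", seq_len(n)))))
  shift <- rep(c(effect, 0), c(n_deg, n_genes - n_deg))
  base[, seq_len(n)] <- base[, seq_len(n)] + shift
  list(case = 2^base[, seq_len(n)], normal = 2^base[, n + seq_len(n)],
       degs = genes[seq_len(n_deg)])
}

score_table_fixture <- function(cids, drps_values) {
  tab <- data.frame(cid = as.integer(cids), drps = drps_values,
                    gene_mean = drps_values, pg_mean = 1,
                    n = 10L, m = 2L, cell_line = "cl1", dose = "10um",
                    time = "6h", stringsAsFactors = FALSE)
  class(tab) <- c("drug_score_table", "data.frame")
  tab
}
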