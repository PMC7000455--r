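# Independent brute-force evaluators used as oracles. Deliberately written
# with explicit loops over plain named vectors, sharing no code with the
# package implementation.

# gene-level score for one drug condition vs one disease signature
oracle_condition <- function(drug_f, disease_f, pgl_genes, floor = TRUE) {
  common <- character()
  for (g in names(drug_f)) if (g %in% names(disease_f)) common <- c(common, g)
  n <- length(common)
  if (n == 0L) return(list(gene_mean = 0, pg_mean = 0, product = 0,
                           n = 0L, m = 0L))
  gene_sum <- 0
  for (g in common) {
    fd <- disease_f[[g]]; fdr <- drug_f[[g]]
    if ((fdr > 0 && fd < 0) || (fdr < 0 && fd > 0)) {
      gene_sum <- gene_sum + (abs(fd) - abs(fdr))
    }
  }
  gene_mean <- gene_sum / n
  pg_common <- character()
  for (g in common) if (g %in% pgl_genes) pg_common <- c(pg_common, g)
  m <- length(pg_common)
  if (m == 0L) {
    pg_mean <- 0
  } else {
    pg_sum <- 0
    for (g in pg_common) {
      fd <- disease_f[[g]]; fdr <- drug_f[[g]]
      if ((fdr > 0 && fd < 0) || (fdr < 0 && fd > 0)) {
        pg_sum <- pg_sum + (abs(fd) - abs(fdr))
      }
    }
    pg_mean <- pg_sum / m
  }
  product <- if (floor) {
    max(gene_mean, 0) * max(pg_mean, 0)
  } else {
    gene_mean * pg_mean
  }
  list(gene_mean = gene_mean, pg_mean = pg_mean, product = product,
       n = n, m = m)
}

# max over conditions
oracle_drps <- function(condition_fs, disease_f, pgl_genes, floor = TRUE) {
  best <- -Inf
  for (f in condition_fs) {
    p <- oracle_condition(f, disease_f, pgl_genes, floor)$product
    if (p > best) best <- p
  }
  best
}

# exhaustive pairwise AUC with 0.5 for ties
oracle_auc <- function(score, positive) {
  pos <- score[positive]
  neg <- score[!positive]
  if (length(pos) == 0L || length(neg) == 0L) return(NA_real_)
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# random scoring instance: small gene universe, several drug conditions,
# fold changes with some exact zeros to exercise the strict-sign rule
random_instance <- function(seed, max_genes = 25L, max_conditions = 4L,
                            max_pgl = 6L) {
  set.seed(seed)
  n_genes <- sample(3:max_genes, 1L)
  genes <- sprintf("g%02d", seq_len(n_genes))
  rf <- function(k) {
    f <- round(stats::runif(k, -3, 3), 2)
    f[sample(k, size = max(0L, rbinom(1L, k, 0.1)))] <- 0
    f
  }
  disease_genes <- sample(genes, sample(2:n_genes, 1L))
  disease_f <- setNames(rf(length(disease_genes)), disease_genes)
  n_cond <- sample(seq_len(max_conditions), 1L)
  condition_fs <- lapply(seq_len(n_cond), function(e) {
    drug_genes <- sample(genes, sample(2:n_genes, 1L))
    setNames(rf(length(drug_genes)), drug_genes)
  })
  pgl_genes <- sample(genes, sample(0:min(max_pgl, n_genes), 1L))
  list(disease_f = disease_f, condition_fs = condition_fs,
       pgl_genes = pgl_genes)
}

as_sig <- function(f, origin = "CGPS", cid = 1L, e = 1L) {
  if (origin == "DGPS") {
    perturbation_signature(f, "DGPS",
                           key = condition_key(cid, "cl1", "1um",
                                               sprintf("%dh", e)))
  } else {
    perturbation_signature(f, origin, disease = "test")
  }
}

instance_drps <- function(inst, floor = TRUE, cid = 1L) {
  sigs <- lapply(seq_along(inst$condition_fs), function(e)
    as_sig(inst$condition_fs[[e]], "DGPS", cid = cid, e = e))
  dsig <- as_sig(inst$disease_f)
  suppressWarnings(
    drps(sigs, dsig, pharmacogene_list(inst$pgl_genes),
         floor_negative_means = floor)$drps)
}
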