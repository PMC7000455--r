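small_cfg <- function(...) {
  defaults <- list(n_genes = 200L, n_degs = 30L, n_drugs = 12L,
                   n_reversers = 3L, n_case = 6L, n_normal = 6L,
                   n_conditions_per_drug = 2L)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

test_that("generators are bit-reproducible under a fixed seed", {
  cfg <- small_cfg(seed = 7L)
  d1 <- simulate_disease(cfg)
  d2 <- simulate_disease(cfg)
  expect_identical(d1$case$values, d2$case$values)
  expect_identical(d1$true_lfc, d2$true_lfc)
  sig <- perturbation_signature(d1$true_lfc, "AGPS", disease = "synthetic")
  r1 <- simulate_drug_db(cfg, sig)
  r2 <- simulate_drug_db(cfg, sig)
  expect_identical(lapply(r1$db$signatures, as.numeric),
                   lapply(r2$db$signatures, as.numeric))
  expect_identical(r1$gold$cids, r2$gold$cids)
  # a different seed changes the draw
  d3 <- simulate_disease(small_cfg(seed = 8L))
  expect_false(identical(d1$case$values, d3$case$values))
})

test_that("planted fold changes are exact in the noiseless limit", {
  cfg <- small_cfg(noise_sd = 0, effect_size = 2, seed = 2L)
  d <- simulate_disease(cfg)
  res <- differential_test(d$case, d$normal)
  lfc <- setNames(res$log2fc, res$gene_id)
  expect_equal(unname(abs(lfc[d$true_degs])), rep(2, length(d$true_degs)))
  expect_equal(lfc[d$true_degs], d$true_lfc[names(lfc[d$true_degs])])
  expect_equal(unname(lfc[setdiff(names(lfc), d$true_degs)]),
               rep(0, cfg$n_genes - cfg$n_degs))
})

test_that("a null effect is statistically invisible", {
  hits <- vapply(1:5, function(s) {
    cfg <- small_cfg(effect_size = 0, noise_sd = 0.5, seed = s)
    d <- simulate_disease(cfg)
    res <- differential_test(d$case, d$normal, method = "log_welch_t")
    mean(res$q_value < 0.05)
  }, numeric(1))
  expect_lte(mean(hits), 0.01)
})

test_that("reversers outrank every non-reverser in the noiseless limit", {
  cfg <- small_cfg(noise_sd = 0, seed = 5L)
  d <- simulate_disease(cfg)
  # zero noise leaves no within-group variance for testing, so the true
  # planted signature plays the disease role here
  dsig <- perturbation_signature(d$true_lfc, "AGPS", disease = "synthetic")
  r <- simulate_drug_db(cfg, dsig)
  scores <- score_drugs(r$db, dsig, r$pgl)
  is_rev <- scores$cid %in% r$reversers
  expect_gt(min(scores$drps[is_rev]), max(scores$drps[!is_rev]))
  # noise-only drugs score exactly zero when noise is off
  expect_equal(scores$drps[!is_rev], rep(0, sum(!is_rev)))
})

test_that("the designated best condition attains the condition maximum", {
  cfg <- small_cfg(noise_sd = 0, seed = 6L)
  d <- simulate_disease(cfg)
  dsig <- perturbation_signature(d$true_lfc, "AGPS", disease = "synthetic")
  r <- simulate_drug_db(cfg, dsig)
  scores <- score_drugs(r$db, dsig, r$pgl)
  best_times <- scores$time[scores$cid %in% r$reversers]
  expect_true(all(best_times == "6h"))  # condition 1 is the designated best
  # mild reversal at ratio rho scores (1 - rho) |F_disease| per reversed gene
  rev_sig_keys <- r$db$index$key[r$db$index$cid == r$reversers[1]]
  cs_best <- condition_score(r$db$signatures[[rev_sig_keys[1]]], dsig, r$pgl)
  cs_other <- condition_score(r$db$signatures[[rev_sig_keys[2]]], dsig, r$pgl)
  expect_gt(cs_best$product, cs_other$product)
})

test_that("halved drug magnitude yields PS of half the disease magnitude", {
  dsig <- as_sig(c(g1 = 2, g2 = -2))
  half <- as_sig(c(g1 = -1, g2 = 1), "DGPS")
  inv <- inverse_gene_set(half, dsig)
  expect_setequal(inv$genes, c("g1", "g2"))
  expect_equal(perturbation_score(as.numeric(dsig[inv$genes]),
                                  as.numeric(half[inv$genes])),
               c(1, 1))
})

test_that("a null study with a random gold standard gives chance-level AUC", {
  aucs <- vapply(1:6, function(s) {
    cfg <- small_cfg(n_reversers = 0L, seed = 100L + s)
    d <- simulate_disease(cfg)
    dsig <- make_disease_signature(
      differential_test(d$case, d$normal, method = "log_welch_t"),
      origin = "AGPS")
    r <- simulate_drug_db(cfg, dsig)
    tab <- classify_drpc(score_drugs(r$db, dsig, r$pgl))
    res <- auc_per_class(tab, r$gold)
    res$auc[res$class == "global"]
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.15)
})

test_that("signature databases convert to expression profiles and back exactly", {
  cfg <- small_cfg(seed = 9L)
  d <- simulate_disease(cfg)
  dsig <- make_disease_signature(differential_test(d$case, d$normal),
                                 origin = "AGPS")
  r <- simulate_drug_db(cfg, dsig)
  expr <- db_to_expression(r$db)
  rebuilt <- build_signature_db(expr$profile, expr$cid_map)
  expect_setequal(names(rebuilt$signatures), names(r$db$signatures))
  for (k in names(r$db$signatures)) {
    orig <- r$db$signatures[[k]]
    expect_equal(as.numeric(rebuilt$signatures[[k]][names(orig)]),
                 as.numeric(orig), tolerance = 1e-12)
  }
})
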