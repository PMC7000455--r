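test_that("inverse gene sets use strict sign opposition over the intersection", {
  dgps <- as_sig(c(g1 = 1, g2 = -2, g3 = 1), "DGPS")
  dsig <- as_sig(c(g1 = -3, g2 = -1, g4 = 2))
  inv <- inverse_gene_set(dgps, dsig)
  expect_identical(inv$genes, "g1")
  expect_equal(inv$n, 2L)
  # zero fold change is never inverse
  inv0 <- inverse_gene_set(as_sig(c(g1 = 0, g2 = 1), "DGPS"),
                           as_sig(c(g1 = -1, g2 = -1)))
  expect_identical(inv0$genes, "g2")
  # identical signatures invert nothing
  same <- as_sig(c(g1 = 1, g2 = -1), "DGPS")
  inv_same <- inverse_gene_set(same, as_sig(c(g1 = 1, g2 = -1)))
  expect_equal(length(inv_same$genes), 0L)
  expect_equal(inv_same$n, 2L)
})

test_that("perturbation score is |disease| - |drug| and demands opposite signs", {
  expect_equal(perturbation_score(2, -1), 1)
  expect_equal(perturbation_score(-0.5, 3), -2.5)
  expect_equal(perturbation_score(c(2, -1), c(-1, 2)), c(1, -1))
  expect_error(perturbation_score(1, 1), "opposite signs")
  expect_error(perturbation_score(0, 1), "opposite signs")
})

test_that("the worked micro-example scores gene_mean 1, pg_mean 2, product 2", {
  dgps <- as_sig(c(g1 = -1, g2 = 1), "DGPS")
  dsig <- as_sig(c(g1 = 3, g2 = 2))
  cs <- condition_score(dgps, dsig, pharmacogene_list("g1"))
  expect_equal(cs$gene_mean, 1)
  expect_equal(cs$pg_mean, 2)
  expect_equal(cs$product, 2)
  expect_equal(cs$n, 2L)
  expect_equal(cs$m, 1L)
  # confirmed by the independent brute-force oracle
  orc <- oracle_condition(c(g1 = -1, g2 = 1), c(g1 = 3, g2 = 2), "g1")
  expect_equal(cs$gene_mean, orc$gene_mean)
  expect_equal(cs$pg_mean, orc$pg_mean)
  expect_equal(cs$product, orc$product)
})

test_that("missing pharmacogene overlap zeroes the score", {
  dgps <- as_sig(c(g1 = -1, g2 = 1), "DGPS")
  dsig <- as_sig(c(g1 = 3, g2 = 2))
  cs <- condition_score(dgps, dsig, pharmacogene_list("g9"))
  expect_equal(cs$m, 0L)
  expect_equal(cs$pg_mean, 0)
  expect_equal(cs$product, 0)
  # disjoint signatures give the all-zero score with a warning
  expect_warning(cs0 <- condition_score(as_sig(c(a = 1), "DGPS"),
                                        as_sig(c(b = -1)),
                                        pharmacogene_list("a")),
                 "no genes")
  expect_equal(cs0$product, 0)
  expect_equal(cs0$n, 0L)
})

test_that("negative component means are floored by default and kept when disabled", {
  # drug overshoots: |drug| > |disease| on every inverse gene
  dgps <- as_sig(c(g1 = -5, g2 = 4), "DGPS")
  dsig <- as_sig(c(g1 = 1, g2 = -1))
  pgl <- pharmacogene_list(c("g1", "g2"))
  floored <- condition_score(dgps, dsig, pgl)
  expect_equal(floored$product, 0)
  expect_lt(floored$gene_mean, 0)
  raw <- condition_score(dgps, dsig, pgl, floor_negative_means = FALSE)
  expect_equal(raw$product, raw$gene_mean * raw$pg_mean)
  expect_gt(raw$product, 0)  # two negatives multiply positive when unfloored
})

test_that("a drug's score is the maximum over conditions with deterministic ties", {
  dsig <- as_sig(c(g1 = 2, g2 = -2))
  pgl <- pharmacogene_list(c("g1", "g2"))
  weak <- as_sig(c(g1 = -1.9, g2 = 1.9), "DGPS", e = 1L)
  strong <- as_sig(c(g1 = -0.5, g2 = 0.5), "DGPS", e = 2L)
  res <- drps(list(weak, strong), dsig, pgl)
  expect_equal(res$drps, condition_score(strong, dsig, pgl)$product)
  expect_equal(res$best$key$time, "2h")
  # single condition returns its own product
  solo <- drps(list(weak), dsig, pgl)
  expect_equal(solo$drps, condition_score(weak, dsig, pgl)$product)
  # exact tie broken by lexicographically smallest key
  tie <- drps(list(as_sig(c(g1 = -1), "DGPS", e = 2L),
                   as_sig(c(g1 = -1), "DGPS", e = 1L)), dsig, pgl)
  expect_equal(tie$best$key$time, "1h")
  expect_error(drps(list(), dsig, pgl))
})

test_that("library DRPS matches the brute-force oracle on random instances", {
  for (seed in 1:25) {
    inst <- random_instance(seed)
    expect_equal(instance_drps(inst),
                 oracle_drps(inst$condition_fs, inst$disease_f,
                             inst$pgl_genes),
                 tolerance = 1e-12, info = paste("seed", seed))
    expect_equal(instance_drps(inst, floor = FALSE),
                 oracle_drps(inst$condition_fs, inst$disease_f,
                             inst$pgl_genes, floor = FALSE),
                 tolerance = 1e-12, info = paste("seed", seed))
  }
})

test_that("self-inversion gives exactly zero", {
  f <- c(g1 = 2, g2 = -1.5, g3 = 0.7)
  pgl <- pharmacogene_list(c("g1", "g3"))
  # drug equal to the disease: nothing is inverse
  expect_equal(drps(list(as_sig(f, "DGPS")), as_sig(f), pgl)$drps, 0)
  # exact self-negation: every gene inverse but PS = |F| - |F| = 0
  neg <- drps(list(as_sig(-f, "DGPS")), as_sig(f), pgl)
  expect_identical(neg$drps, 0)
  expect_equal(neg$best$n, 3L)
})

test_that("amplifying the disease on inverse genes never lowers a score", {
  for (seed in 26:40) {
    inst <- random_instance(seed)
    base <- instance_drps(inst)
    for (c_mult in c(1.5, 3)) {
      boosted <- inst
      fd <- boosted$disease_f
      # scale disease fold changes on genes inverse to ANY condition
      inv_any <- unique(unlist(lapply(inst$condition_fs, function(fdr) {
        common <- intersect(names(fdr), names(fd))
        common[(fdr[common] > 0 & fd[common] < 0) |
                 (fdr[common] < 0 & fd[common] > 0)]
      })))
      fd[inv_any] <- c_mult * fd[inv_any]
      boosted$disease_f <- fd
      expect_gte(instance_drps(boosted), base - 1e-12)
    }
  }
})

test_that("drugs inverting more of the disease never rank lower (equal magnitudes)", {
  genes <- sprintf("g%02d", 1:20)
  dsig <- as_sig(setNames(rep(2, 20), genes))
  pgl <- pharmacogene_list(genes[1:5])
  fracs <- c(0, 0.25, 0.5, 0.75, 1)
  products <- vapply(seq_along(fracs), function(i) {
    k <- round(fracs[i] * 20)
    f <- setNames(rep(1, 20), genes)       # same-direction background
    if (k > 0) f[1:k] <- -1                # inverted subset, equal magnitude
    drps(list(as_sig(f, "DGPS", cid = i)), dsig, pgl)$drps
  }, numeric(1))
  expect_true(all(diff(products) >= -1e-12))
})

test_that("tertile classification partitions drugs with sizes differing by at most one", {
  for (n in c(3, 9, 10, 100)) {
    tab <- classify_drpc(score_table_fixture(seq_len(n), rev(seq_len(n)) / n))
    expect_equal(nrow(tab), n)
    sizes <- table(tab$drpc)
    expect_equal(sum(sizes), n)
    expect_lte(max(sizes) - min(sizes), 1)
    expect_false(any(duplicated(tab$cid)))
  }
  # 10 drugs: remainder goes to the high class
  sizes10 <- table(classify_drpc(score_table_fixture(1:10, 10:1))$drpc)
  expect_equal(as.integer(sizes10), c(4L, 3L, 3L))
  # the top third by score really is the high class
  tab9 <- classify_drpc(score_table_fixture(1:9, c(9, 1:8)))
  expect_setequal(tab9$cid[tab9$drpc == "high"], c(1L, 8L, 9L))
  expect_error(classify_drpc(score_table_fixture(1:2, 1:2)), "at least 3")
})

test_that("all-tied scores are classified deterministically by CID", {
  tab <- score_table_fixture(c(7, 3, 9, 1, 5), rep(1, 5))
  out1 <- classify_drpc(tab)
  out2 <- classify_drpc(tab[sample(5), ])
  expect_identical(out1$cid, out2$cid)
  expect_identical(out1$drpc, out2$drpc)
  expect_equal(out1$cid, c(1, 3, 5, 7, 9))  # tie-break ascending CID
  expect_equal(as.integer(table(out1$drpc)), c(2L, 2L, 1L))
})

test_that("candidate selection needs omics-wide high class and no low class", {
  mk <- function(high, mid, low) {
    classify_drpc(score_table_fixture(c(high, mid, low),
                                      c(3, 2, 1)))
  }
  tables <- list(
    rnaseq = mk(1, 2, 3),
    microarray = mk(2, 1, 3),
    proteome = mk(1, 2, 3))
  # drug 1: high in rnaseq + proteome, intermediate in microarray -> selected
  sel <- select_candidates(tables, c("rnaseq", "microarray"), "proteome")
  expect_identical(sel, 1L)
  # drug high in transcriptomic+proteomic but low elsewhere -> excluded
  tables$microarray <- mk(2, 3, 1)
  expect_length(select_candidates(tables, c("rnaseq", "microarray"),
                                  "proteome"), 0L)
  # high in both transcriptomic tables but not in the proteome -> excluded
  tables <- list(rnaseq = mk(1, 2, 3), microarray = mk(1, 2, 3),
                 proteome = mk(2, 1, 3))
  expect_length(select_candidates(tables, c("rnaseq", "microarray"),
                                  "proteome"), 0L)
  # the "all" quantifier is stricter than "any"
  tables <- list(rnaseq = mk(1, 2, 3), microarray = mk(2, 1, 3),
                 proteome = mk(1, 2, 3))
  expect_identical(select_candidates(tables, c("rnaseq", "microarray"),
                                     "proteome"), 1L)
  expect_length(select_candidates(tables, c("rnaseq", "microarray"),
                                  "proteome",
                                  transcriptomic_quantifier = "all"), 0L)
  expect_error(select_candidates(tables, character(), "proteome"),
               "at least one")
})
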