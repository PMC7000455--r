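test_that("compound names normalize deterministically and reject empties", {
  expect_identical(normalize_name(" Selegiline "), "selegiline")
  expect_identical(normalize_name("iproniazid"), "iproniazid")
  expect_identical(normalize_name("  (+)-JQ1,  free  base. "), "jq1, free base")
  # idempotent on already-normalized input
  expect_identical(normalize_name(normalize_name("Foo  Bar")),
                   normalize_name("Foo  Bar"))
  expect_error(normalize_name(""), "non-empty")
  expect_error(normalize_name("   "), "non-empty")
})

test_that("CID lookup is case-insensitive and missing is a value", {
  tab <- tiny_cid_map()
  expect_identical(map_to_cid("Selegiline", tab), 26757L)
  expect_identical(map_to_cid("SELEGILINE", tab), 26757L)
  expect_identical(map_to_cid("unknowndrug", tab), NA_integer_)
  expect_identical(map_to_cid(c(" selegiline", "x", "Iproniazid"), tab),
                   c(26757L, NA_integer_, 3748L))
})

test_that("replicate collapsing averages per gene and validates inputs", {
  prof <- tiny_drug_profile()
  key <- condition_key(10, "mcf7", "10um", "6h")
  collapsed <- collapse_replicates(prof, key)
  # treated reps [4, 6] -> 5; controls [2, 3] -> 2.5
  expect_equal(unname(collapsed$values["g1", ]), c(5, 2.5))
  expect_equal(unname(collapsed$values["g2", "treated"]), 8)
  # single replicate passes through unchanged
  single <- collapse_replicates(prof, condition_key(11, "mcf7", "10um", "6h"))
  expect_equal(unname(single$values["g1", "treated"]), 7)
  expect_error(collapse_replicates(prof, condition_key(99, "mcf7", "10um", "6h")),
               "no treated sample")
  # treated sample present but its cell line has no vehicle control
  orphan <- expression_profile(
    prof$values[, 1, drop = FALSE],
    prof$sample_meta[1, , drop = FALSE])
  expect_error(collapse_replicates(orphan, condition_key(10, "mcf7", "10um", "6h")),
               "no control")
})

test_that("replicate collapsing is invariant to replicate order", {
  prof <- tiny_drug_profile()
  perm <- c(2, 1, 3, 5, 4)
  prof_perm <- expression_profile(prof$values[, perm],
                                  prof$sample_meta[perm, ])
  key <- condition_key(10, "mcf7", "10um", "6h")
  expect_equal(collapse_replicates(prof, key)$values,
               collapse_replicates(prof_perm, key)$values)
})

test_that("log2 fold-change signatures follow the closed form", {
  mk <- function(treated, control, pc = 0) {
    genes <- sprintf("g%d", seq_along(treated))
    prof <- expression_profile(
      matrix(c(treated, control), ncol = 2,
             dimnames = list(genes, c("treated", "control"))),
      data.frame(sample_id = c("treated", "control"),
                 role = c("treated", "control"), cid = c(1L, NA),
                 cell_line = "cl", dose = c("d", NA), time = c("t", NA),
                 stringsAsFactors = FALSE))
    build_dgps(prof, condition_key(1, "cl", "d", "t"), pseudocount = pc)
  }
  expect_equal(as.numeric(mk(8, 2)["g1"]), 2)
  expect_equal(as.numeric(mk(5, 5)["g1"]), 0)
  expect_equal(as.numeric(mk(0, 3, pc = 1)["g1"]), -2)
  # zero control at pseudocount 0: gene dropped with a warning, not an error
  expect_warning(sig <- mk(c(4, 8), c(0, 2)), "dropped")
  expect_identical(names(sig), "g2")
  # antisymmetry: swapping treated and control negates every fold change
  t_vals <- c(3, 9, 1.5, 7)
  c_vals <- c(6, 2, 1.5, 3.5)
  expect_equal(as.numeric(mk(t_vals, c_vals)), -as.numeric(mk(c_vals, t_vals)))
})

test_that("database assembly indexes compounds and rejects duplicate keys", {
  f <- c(g1 = 1, g2 = -1)
  sigs <- list(as_sig(f, "DGPS", cid = 1L, e = 1L),
               as_sig(f, "DGPS", cid = 1L, e = 2L),
               as_sig(f, "DGPS", cid = 2L, e = 1L))
  db <- assemble_database(sigs)
  expect_equal(length(db), 3L)
  expect_equal(sort(unique(db$index$cid)), c(1L, 2L))
  expect_error(assemble_database(c(sigs, sigs[1])), "duplicate")
  empty <- assemble_database(list())
  expect_equal(length(empty), 0L)
  expect_equal(nrow(empty$index), 0L)
})

test_that("end-to-end database build resolves names and drops unmapped compounds", {
  prof <- tiny_drug_profile()
  meta <- prof$sample_meta
  meta$cid <- NA_integer_  # force resolution through the mapping table
  meta$compound_name[3] <- "notindb"
  prof <- expression_profile(prof$values, meta)
  expect_message(db <- build_signature_db(prof, tiny_cid_map()),
                 "excluding 1")
  expect_equal(unique(db$index$cid), 26757L)
  sig <- db$signatures[[1]]
  expect_equal(as.numeric(sig["g1"]), log2(5 / 2.5))
})

test_that("signature database round-trips through disk bit-exactly", {
  set.seed(7)
  sigs <- lapply(1:4, function(i)
    as_sig(setNames(rnorm(20), sprintf("g%02d", 1:20)), "DGPS",
           cid = (i + 1L) %/% 2L, e = i %% 2L + 1L))
  db <- assemble_database(sigs)
  dir <- withr::local_tempdir()
  write_signature_db(db, dir)
  db2 <- read_signature_db(dir)
  expect_identical(db2$index, db$index)
  for (k in names(db$signatures)) {
    expect_identical(as.numeric(db2$signatures[[k]]),
                     as.numeric(db$signatures[[k]]))
    expect_identical(names(db2$signatures[[k]]), names(db$signatures[[k]]))
  }
})
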