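make_task <- function(peptide, binders) {
  tasks <- stratify_peptides(binding_records(rep(peptide, length(binders)),
                                             cdr3b = binders, label = "binder"))
  tasks[[1]]
}

test_that("background negatives exclude known binders and hit the requested count", {
  ds <- small_dataset()
  tasks <- stratify_peptides(ds$records)
  t3 <- tasks[[which.min(task_summary(tasks)$n_binders)]]
  neg <- draw_background_negatives(t3, ds$repertoire, ratio = 1L, seed = 2L)
  expect_equal(nrow(neg), length(t3$binders))
  expect_length(intersect(neg$tcr, t3$binders), 0L)
  expect_true(all(neg$label == "non-binder"))
})

test_that("a binder present in a small repertoire is never drawn", {
  t1 <- make_task("GILGFVFTL", "CASSAAAAF")
  rep5 <- repertoire(c("CASSAAAAF", "CASSCCCCF", "CASSDDDDF",
                       "CASSEEEEF", "CASSFFFFF"))
  for (s in 1:20) {
    neg <- draw_background_negatives(t1, rep5, seed = s)
    expect_false("CASSAAAAF" %in% neg$tcr)
    expect_equal(nrow(neg), 1L)
  }
})

test_that("insufficient repertoire raises with counts", {
  t1 <- make_task("GILGFVFTL", c("CASSAAAAF", "CASSCCCCF", "CASSDDDDF"))
  expect_error(
    draw_background_negatives(t1, repertoire(c("CASSEEEEF", "CASSFFFFF")),
                              seed = 1L),
    "need 3 negative\\(s\\), only 2 available")
})

test_that("background draws are seed-deterministic and cover the draw space", {
  # small instance: choose 2 of 7 eligible sequences; all 21 subsets of
  # size 2 must appear over many seeds, and a fixed seed must reproduce
  t1 <- make_task("GILGFVFTL", c("CASSAAAAF", "CASSZZZZF"))
  pool <- repertoire(c("CASSAAAAF",
                       paste0("CASSPOOL", strsplit("CDEFGHI", "")[[1]], "F")))
  expect_identical(draw_background_negatives(t1, pool, ratio = 1L, seed = 9L),
                   draw_background_negatives(t1, pool, ratio = 1L, seed = 9L))
  draws <- vapply(1:300, function(s) {
    paste(sort(draw_background_negatives(t1, pool, ratio = 1L, seed = s)$tcr),
          collapse = "|")
  }, "")
  # 2 negatives per draw (ratio 1, two positives), from 7 eligible: C(7,2)=21
  expect_equal(length(unique(draws)), 21L)
})

test_that("reshuffling two positives yields exactly the crossed pairs", {
  r <- binding_records(c("GILGFVFTL", "NLVPMVATV"),
                       cdr3b = c("CASSAAAAF", "CASSCCCCF"), label = "binder")
  neg <- reshuffle_negatives(r, seed = 1L)
  expect_equal(nrow(neg), 2L)
  got <- sort(paste(neg$peptide, neg$tcr))
  expect_equal(got, sort(c("GILGFVFTL CASSCCCCF", "NLVPMVATV CASSAAAAF")))
})

test_that("single-peptide reshuffling is undefined", {
  r <- binding_records("GILGFVFTL", "CASSAAAAF", label = "binder")
  expect_error(reshuffle_negatives(r, seed = 1L), "reshuffling undefined")
})

test_that("reshuffling preserves the TCR multiset and avoids all positives", {
  set.seed(42)
  peps <- replicate(10, paste(sample(strsplit("ACDEFGHIKLMNPQRSTVY", "")[[1]],
                                     9, TRUE), collapse = ""))
  tcrs <- replicate(100, paste0("CASS", paste(sample(strsplit("ACDEFGHIKLMN", "")[[1]],
                                                     8, TRUE), collapse = ""), "F"))
  r <- binding_records(sample(peps, 100, TRUE), cdr3b = tcrs, label = "binder")
  neg <- reshuffle_negatives(r, seed = 3L)
  expect_equal(nrow(neg), 100L)
  expect_equal(sort(neg$tcr), sort(tcrs))  # marginal multiset preserved
  pos_key <- paste(r$peptide, r$cdr3b)
  expect_length(intersect(paste(neg$peptide, neg$tcr), pos_key), 0L)
})

test_that("balanced folds are exactly balanced per peptide with fixed positives", {
  ds <- small_dataset()
  tasks <- stratify_peptides(ds$records)[1:2]
  ns <- vapply(tasks, function(t) length(t$binders), 0L)
  spec <- sampling_spec("background_drawing", seed = 5L, n_folds = 10L)
  folds <- make_balanced_folds(tasks, ds$repertoire, spec)
  for (fid in unique(folds$fold_id)) {
    f <- folds[folds$fold_id == fid, ]
    tab <- table(f$peptide, f$label)
    expect_true(all(tab[, "binder"] == tab[, "non-binder"]))
    expect_false(any(duplicated(paste(f$peptide, f$tcr, f$label))))
  }
  # positives identical across folds
  pos1 <- sort(paste(folds$peptide, folds$tcr)[folds$fold_id == 1 &
                                                 folds$label == "binder"])
  pos2 <- sort(paste(folds$peptide, folds$tcr)[folds$fold_id == 7 &
                                                 folds$label == "binder"])
  expect_identical(pos1, pos2)
})

test_that("a single fold is balanced and a fixed spec reproduces folds exactly", {
  ds <- small_dataset()
  tasks <- stratify_peptides(ds$records)[1:3]
  spec1 <- sampling_spec("background_drawing", seed = 77L, n_folds = 1L)
  f1 <- make_balanced_folds(tasks, ds$repertoire, spec1)
  expect_equal(sum(f1$label == "binder"), sum(f1$label == "non-binder"))
  f2 <- make_balanced_folds(tasks, ds$repertoire, spec1)
  expect_identical(f1, f2)
})

test_that("negatives accumulated across folds exceed any single fold's coverage", {
  t1 <- make_task("GILGFVFTL", c("CASSAAAAF", "CASSCCCCF", "CASSDDDDF"))
  set.seed(1)
  rep1k <- repertoire(replicate(1000, paste0(
    "CASS", paste(sample(strsplit("ACDEFGHIKLMN", "")[[1]], 9, TRUE),
                  collapse = ""), "F")))
  spec <- sampling_spec("background_drawing", seed = 2L, n_folds = 100L)
  folds <- make_balanced_folds(list(t1), rep1k, spec)
  negs <- folds[folds$label == "non-binder", ]
  per_fold <- tapply(negs$tcr, negs$fold_id, function(x) length(unique(x)))
  expect_gt(length(unique(negs$tcr)), max(per_fold))
})

test_that("reshuffling folds are balanced and leak-free", {
  ds <- small_dataset()
  tasks <- stratify_peptides(ds$records)[1:4]
  spec <- sampling_spec("reshuffling", seed = 9L, n_folds = 5L)
  folds <- make_balanced_folds(tasks, spec = spec)
  pos_key <- unlist(lapply(tasks, function(t) paste(t$peptide, t$query)))
  for (fid in unique(folds$fold_id)) {
    f <- folds[folds$fold_id == fid, ]
    neg <- f[f$label == "non-binder", ]
    expect_length(intersect(paste(neg$peptide, neg$tcr), pos_key), 0L)
    expect_equal(nrow(neg), sum(f$label == "binder"))
  }
})
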