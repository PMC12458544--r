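test_that("validation keeps well-formed records and rejects alphabet violations", {
  r <- tiny_records()
  out <- validate_records(r, quiet = TRUE)
  expect_equal(nrow(out), 3L)

  bad <- binding_records("GILGFVFTL", "CASS1RS", label = "binder")
  expect_error(validate_records(bad, quiet = TRUE), "no valid records")

  mixed <- rbind(tiny_records(), binding_records("GILGFVFTL", "CASS1RSXX",
                                                 label = "binder"))
  out <- validate_records(mixed, quiet = TRUE)
  expect_equal(nrow(out), 3L)
  expect_equal(attr(out, "rejects")$reason, "invalid CDR3 sequence")
})

test_that("records with empty peptides are counted as rejects", {
  r <- rbind(tiny_records(),
             binding_records(c("", "", ""), "CASSIRSSYEQYF", label = "binder"))
  out <- validate_records(r, quiet = TRUE)
  expect_equal(nrow(out), 3L)
  expect_equal(nrow(attr(out, "rejects")), 3L)
})

test_that("length bounds and missing-chain rules are enforced", {
  r <- binding_records(
    peptide = c("GILGFVFTL", "ACDEF", "GILGFVFTL"),
    cdr3b = c("CASSF", NA, "CASSIRSSYEQYF"),
    label = "binder")
  out <- validate_records(r, quiet = TRUE)
  expect_equal(nrow(out), 1L)
  reasons <- attr(out, "rejects")$reason
  expect_setequal(reasons, c("invalid CDR3 sequence",
                             "peptide length out of bounds"))
})

test_that("stratification assigns groups as a pure function of binder count", {
  th <- group_thresholds()
  mk <- function(n_binders, pep) {
    binding_records(rep(pep, n_binders),
                    cdr3b = vapply(seq_len(n_binders), function(i) {
                      paste0("CASS", paste(sample(strsplit("ACDEFGHIKLMN", "")[[1]],
                                                  8, TRUE), collapse = ""), "F")
                    }, ""),
                    label = "binder")
  }
  set.seed(1)
  recs <- rbind(mk(150, "AAAAAAAAA"), mk(100, "CCCCCCCCC"),
                mk(50, "DDDDDDDDD"), mk(5, "EEEEEEEEE"),
                mk(4, "FFFFFFFFF"), mk(2, "GGGGGGGGG"))
  tasks <- stratify_peptides(recs, th)
  s <- task_summary(tasks)
  got <- setNames(s$group, s$peptide)
  expect_equal(unname(got[c("AAAAAAAAA", "CCCCCCCCC")]),
               c("majority", "majority"))  # >= 100 binders
  expect_equal(unname(got[c("DDDDDDDDD", "EEEEEEEEE")]),
               c("fewshot", "fewshot"))    # 5-100 binders
  expect_equal(unname(got[c("FFFFFFFFF", "GGGGGGGGG")]),
               c("zeroshot", "zeroshot"))  # < 5 binders

  # the 100-binder boundary is switchable
  tasks2 <- stratify_peptides(recs, group_thresholds(majority_min = 101L))
  s2 <- task_summary(tasks2)
  expect_equal(s2$group[s2$peptide == "CCCCCCCCC"], "fewshot")
})

test_that("stratification is a partition, order-invariant and dedup-invariant", {
  ds <- small_dataset()
  tasks <- stratify_peptides(ds$records)
  s <- task_summary(tasks)
  expect_equal(nrow(s), length(unique(ds$records$peptide)))
  expect_equal(sum(table(s$group)), nrow(s))

  # shuffled and duplicated input gives the same stratification
  set.seed(7)
  shuffled <- ds$records[sample(nrow(ds$records)), ]
  doubled <- rbind(shuffled, shuffled)
  s2 <- task_summary(stratify_peptides(doubled))
  expect_equal(s2[order(s2$peptide), ], s[order(s$peptide), ],
               ignore_attr = TRUE)
})

test_that("conflicting labels drop both records with a warning", {
  r <- rbind(tiny_records(),
             binding_records("GILGFVFTL", "CASSIRSSYEQYF", label = "non-binder"))
  expect_warning(tasks <- stratify_peptides(r), "conflicting labels")
  s <- task_summary(tasks)
  expect_equal(s$n_binders[s$peptide == "GILGFVFTL"], 1L)
})

test_that("zero-binder peptides are excluded with a warning", {
  r <- rbind(tiny_records(),
             binding_records("ALSKGVHFV", "CASSLAPGATNEKLFF", label = "non-binder"))
  expect_warning(tasks <- stratify_peptides(r), "zero binders")
  expect_false("ALSKGVHFV" %in% task_summary(tasks)$peptide)
})

test_that("support/query splits are disjoint, exhaustive and seeded", {
  ds <- small_dataset()
  tasks <- stratify_peptides(ds$records)
  t_maj <- tasks[[which(task_summary(tasks)$group == "majority")[1]]]
  t1 <- split_support_query(t_maj, 5L, seed = 3L)
  expect_length(intersect(t1$support, t1$query), 0L)
  expect_setequal(c(t1$support, t1$query), t1$binders)
  t2 <- split_support_query(t_maj, 5L, seed = 3L)
  expect_identical(t1$support, t2$support)
  expect_error(split_support_query(t_maj, length(t_maj$binders), seed = 1L),
               "query binder")
})

test_that("seen/unseen split partitions records by reference membership", {
  r <- binding_records(
    peptide = rep("GILGFVFTL", 4),
    cdr3b = c("CASSAAAAF", "CASSCCCCF", "CASSDDDDF", "CASSEEEEF"),
    label = "binder")
  ref <- c("CASSAAAAF", "CASSCCCCF")
  sp <- split_seen_unseen(r, ref)
  expect_equal(nrow(sp$seen), 2L)
  expect_equal(nrow(sp$unseen), 2L)
  expect_true(all(sp$seen$cdr3b %in% ref))
  expect_false(any(sp$unseen$cdr3b %in% ref))

  all_ref <- split_seen_unseen(r, r$cdr3b)
  expect_equal(nrow(all_ref$unseen), 0L)
})

test_that("seen/unseen counts match a linear-scan oracle on a planted fixture", {
  ds <- small_dataset(seed = 23L)
  recs <- validate_records(ds$records, quiet = TRUE)
  recs <- recs[seq_len(100), ]
  # plant 30 novel TCRs: reference = everything except the TCRs of 30 rows
  set.seed(5)
  novel_rows <- sample(nrow(recs), 30)
  novel_tcrs <- unique(recs$cdr3b[novel_rows])
  ref <- setdiff(unique(recs$cdr3b), novel_tcrs)
  sp <- split_seen_unseen(recs, ref)
  # oracle: linear scan with a membership set
  expected_unseen <- sum(vapply(recs$cdr3b, function(t) !(t %in% ref), NA))
  expect_equal(nrow(sp$unseen), expected_unseen)
  expect_equal(nrow(sp$seen) + nrow(sp$unseen), nrow(recs))
  expect_equal(sp$n_novel_tcrs, length(novel_tcrs))
})
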