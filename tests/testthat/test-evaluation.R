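test_that("the oracle scorer is perfect in every classification fold", {
  ds <- small_dataset()
  tasks <- stratify_peptides(ds$records)
  orc <- make_scorer("oracle", ds$truth)
  spec <- sampling_spec("background_drawing", seed = 2L, n_folds = 10L)
  recs <- run_classification_eval(orc, tasks, ds$repertoire, spec)
  expect_true(all(recs$value[recs$metric == "roc_auc"] == 1))
  expect_true(all(recs$value[recs$metric == "pr_auc"] == 1))
  # every binder clears the 0.5 threshold (affinities >= 0.8 by design)
  expect_true(all(recs$value[recs$metric == "fn"] == 0))
})

test_that("record completeness: folds x groups x metrics", {
  ds <- small_dataset()
  tasks <- stratify_peptides(ds$records)
  rnd <- make_scorer("random", seed = 1L)
  spec <- sampling_spec("background_drawing", seed = 4L, n_folds = 7L)
  recs <- run_classification_eval(rnd, tasks, ds$repertoire, spec)
  n_groups <- length(unique(task_summary(tasks)$group))
  expect_equal(nrow(recs), 7L * n_groups * 6L)  # 6 metrics per cell
  expect_false(any(duplicated(
    recs[c("metric", "fold_id", "group", "strategy", "scorer")])))
})

test_that("a random scorer sits at chance in fold-mean ROC-AUC", {
  ds <- small_dataset(seed = 13L)
  tasks <- stratify_peptides(ds$records)
  rnd <- make_scorer("random", seed = 8L)
  spec <- sampling_spec("background_drawing", seed = 6L, n_folds = 25L)
  recs <- run_classification_eval(rnd, tasks, ds$repertoire, spec)
  auc <- recs$value[recs$metric == "roc_auc"]
  se <- sd(auc) / sqrt(length(auc))
  expect_lt(abs(mean(auc) - 0.5), 4 * se + 0.01)
})

test_that("screening evaluation reports per-group early-enrichment metrics", {
  ds <- small_dataset()
  tasks <- stratify_peptides(ds$records)
  orc <- make_scorer("oracle", ds$truth)
  res <- run_screening_eval(orc, tasks, ds$repertoire, chunk_size = 1000L)
  expect_setequal(unique(res$records$group),
                  unique(task_summary(tasks)$group))
  # oracle ceiling: group bedroc equals the closed-form maximum (ranks 1..n)
  grp_of <- setNames(task_summary(tasks)$group, task_summary(tasks)$peptide)
  for (g in unique(res$records$group)) {
    sc <- res$screens[vapply(res$screens, function(s)
      grp_of[[s$peptide]] == g, NA)]
    best <- mean(vapply(sc, function(s) {
      bedroc_direct_sum(seq_len(s$n), s$total)
    }, 0))
    got <- res$records$value[res$records$metric == "bedroc" &
                               res$records$group == g]
    expect_equal(got, best, tolerance = 1e-9)
  }
  # success at every cutoff is 1 for the oracle
  sr <- res$records[grepl("^success_rate", res$records$metric), ]
  expect_true(all(sr$value == 1))
})

test_that("an empty group is simply absent from screening records", {
  cfg <- synthetic_config(group_sizes = c(majority = 0L, fewshot = 3L,
                                          zeroshot = 2L),
                          repertoire_size = 800L, seed = 3L)
  ds <- generate_dataset(cfg)
  tasks <- stratify_peptides(ds$records)
  res <- run_screening_eval(make_scorer("oracle", ds$truth), tasks,
                            ds$repertoire, chunk_size = 500L)
  expect_false("majority" %in% res$records$group)
  expect_setequal(unique(res$records$group), c("fewshot", "zeroshot"))
})

test_that("peptide folds are balanced, exhaustive and seeded", {
  peps <- sprintf("PEP%04d", 1:1880)
  split <- make_peptide_folds(peps, n_folds = 10L, seed = 2L)
  sizes <- table(split$assignment)
  expect_true(all(sizes == 188L))
  expect_setequal(names(split$assignment), peps)
  split2 <- make_peptide_folds(peps, n_folds = 10L, seed = 2L)
  expect_identical(split$assignment, split2$assignment)

  one_each <- make_peptide_folds(peps[1:10], n_folds = 10L, seed = 1L)
  expect_true(all(table(one_each$assignment) == 1L))
  expect_error(make_peptide_folds(peps[1:5], n_folds = 10L), "exceeds")
})

test_that("aggregation summarises and is invariant to fold order", {
  recs <- data.frame(metric = "roc_auc", value = c(0.7, 0.7, 0.7),
                     fold_id = 1:3, group = "fewshot",
                     strategy = "background_drawing", scorer = "x")
  agg <- aggregate_metrics(recs)
  expect_equal(agg$sd, 0)
  expect_equal(agg$mean, 0.7)

  set.seed(1)
  recs2 <- data.frame(metric = "roc_auc", value = runif(20), fold_id = 1:20,
                      group = "all", strategy = "screening", scorer = "y")
  perm <- recs2[sample(20), ]
  expect_equal(aggregate_metrics(recs2), aggregate_metrics(perm))
})

test_that("paired contrasts detect planted gaps and pass null contrasts", {
  set.seed(4)
  base <- runif(100, 0.6, 0.7)
  recs <- rbind(
    data.frame(metric = "roc_auc", value = base, fold_id = 1:100,
               group = "all", strategy = "s", scorer = "a"),
    data.frame(metric = "roc_auc", value = base, fold_id = 1:100,
               group = "all", strategy = "s", scorer = "b"))
  null_res <- contrast_scorers(recs, "roc_auc", c("a", "b"), seed = 1L)
  expect_gt(null_res$p_value, 0.9)

  recs$value[recs$scorer == "a"] <- base + rnorm(100, 0.2, 0.01)
  gap <- contrast_scorers(recs, "roc_auc", c("a", "b"), seed = 1L)
  expect_lt(gap$p_value, 0.001)
  expect_equal(gap$mean_diff, 0.2, tolerance = 0.01)
})

test_that("the full pipeline is deterministic end to end", {
  run_once <- function() {
    ds <- small_dataset(seed = 21L)
    tasks <- stratify_peptides(ds$records)
    sc <- make_scorer("noisy_oracle", ds$truth, seed = 3L, noise_sd = 0.3)
    spec <- sampling_spec("background_drawing", seed = 11L, n_folds = 4L)
    cl <- run_classification_eval(sc, tasks, ds$repertoire, spec)
    scr <- run_screening_eval(sc, tasks, ds$repertoire, chunk_size = 700L)
    list(cl = cl, scr = scr$records)
  }
  expect_identical(run_once(), run_once())
})
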