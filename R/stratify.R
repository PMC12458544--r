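# Task stratification (majority / few-shot / zero-shot), support/query
# splits and seen/unseen partitions.

#' Grouping thresholds on binder counts
#'
#' Peptides are grouped by their number of known TCR binders:
#' `>= majority_min` is "majority", `>= fewshot_min` (and below
#' `majority_min`) is "fewshot", anything below is "zeroshot". The
#' defaults put peptides with at least 100 binders in the majority
#' group, 5-99 in few-shot and 1-4 in zero-shot. Whether exactly 100
#' binders counts as majority is controlled by `majority_min`: set it
#' to 101 to treat 100 binders as few-shot instead.
#'
#' @param majority_min minimum binder count for the majority group.
#' @param fewshot_min minimum binder count for the few-shot group.
#' @return a `group_thresholds` object.
#' @export
group_thresholds <- function(majority_min = 100L, fewshot_min = 5L) {
  majority_min <- .assert_scalar_int(majority_min, "majority_min", 2L)
  fewshot_min <- .assert_scalar_int(fewshot_min, "fewshot_min", 1L)
  if (fewshot_min >= majority_min) {
    stop("'fewshot_min' must be below 'majority_min'")
  }
  structure(list(majority_min = majority_min, fewshot_min = fewshot_min),
            class = "group_thresholds")
}

.assign_group <- function(n_binders, thresholds) {
  ifelse(n_binders >= thresholds$majority_min, "majority",
         ifelse(n_binders >= thresholds$fewshot_min, "fewshot", "zeroshot"))
}

.new_task <- function(peptide, binders, group) {
  structure(list(peptide = peptide, binders = binders, group = group,
                 support = character(0), query = binders),
            class = "peptide_task")
}

#' @export
print.peptide_task <- function(x, ...) {
  cat(sprintf("<peptide_task> %s: %d binder(s), group=%s, support=%d\n",
              x$peptide, length(x$binders), x$group, length(x$support)))
  invisible(x)
}

#' Stratify peptides into evaluation tasks
#'
#' Groups validated binding records by peptide and assigns each distinct
#' peptide to the majority, few-shot or zero-shot group as a pure
#' function of its binder count under the active thresholds. Duplicate
#' (peptide, TCR, label) rows are collapsed first; (peptide, TCR) pairs
#' that occur with both labels are dropped entirely with a warning,
#' since no resolution rule is defensible without provenance weighting.
#' Peptides with no binder at all cannot form a task and are dropped
#' with a warning.
#'
#' @param records validated binding records.
#' @param thresholds a [group_thresholds()] object.
#' @param chain which CDR3 chain column defines the TCR identity.
#' @return a list of `peptide_task` objects (class `"peptide_tasks"`),
#'   one per distinct peptide with at least one binder.
#' @seealso [task_summary()], [split_support_query()]
#' @export
stratify_peptides <- function(records, thresholds = group_thresholds(),
                              chain = c("beta", "alpha")) {
  chain <- match.arg(chain)
  records <- .coerce_records(records)
  col <- .tcr_column(chain)
  tcr <- records[[col]]
  ok <- !is.na(tcr) & nzchar(tcr)
  if (!all(ok)) {
    warning(sprintf("dropping %d record(s) without a %s chain", sum(!ok), chain))
    records <- records[ok, , drop = FALSE]
    tcr <- tcr[ok]
  }

  key3 <- paste(records$peptide, tcr, records$label, sep = "\r")
  dedup <- !duplicated(key3)
  records <- records[dedup, , drop = FALSE]
  tcr <- tcr[dedup]

  key2 <- paste(records$peptide, tcr, sep = "\r")
  conflicted <- key2 %in% key2[duplicated(key2)]
  if (any(conflicted)) {
    warning(sprintf(
      "dropping %d record(s) over %d (peptide, TCR) pair(s) with conflicting labels",
      sum(conflicted), length(unique(key2[conflicted]))))
    records <- records[!conflicted, , drop = FALSE]
    tcr <- tcr[!conflicted]
  }

  is_pos <- records$label == "binder"
  peptides <- unique(records$peptide)
  binders_by_pep <- split(tcr[is_pos], records$peptide[is_pos])

  no_binder <- setdiff(peptides, names(binders_by_pep))
  if (length(no_binder) > 0L) {
    warning(sprintf("excluding %d peptide(s) with zero binders", length(no_binder)))
  }

  # preserve first-occurrence order of peptides
  keep <- peptides[peptides %in% names(binders_by_pep)]
  tasks <- lapply(keep, function(p) {
    b <- binders_by_pep[[p]]
    .new_task(p, b, .assign_group(length(b), thresholds))
  })
  structure(tasks, class = c("peptide_tasks", "list"))
}

#' Summarise peptide tasks
#'
#' @param tasks output of [stratify_peptides()].
#' @return a `data.frame` with peptide, binder count and group.
#' @export
task_summary <- function(tasks) {
  data.frame(peptide = vapply(tasks, `[[`, "", "peptide"),
             n_binders = vapply(tasks, function(t) length(t$binders), 0L),
             group = vapply(tasks, `[[`, "", "group"),
             stringsAsFactors = FALSE)
}

#' Reserve a support set within a task
#'
#' Splits a task's binders into a seeded random support subset (for
#' adaptation protocols) and the remaining query set used for
#' evaluation. Support and query are always disjoint and their union is
#' the full binder set.
#'
#' @param task a `peptide_task`.
#' @param support_size number of binders to reserve (must leave at least
#'   one query binder).
#' @param seed integer seed.
#' @return the task with `support` and `query` filled in.
#' @export
split_support_query <- function(task, support_size, seed = 1L) {
  support_size <- .assert_scalar_int(support_size, "support_size", 0L)
  n <- length(task$binders)
  if (support_size >= n) {
    stop(sprintf("support_size (%d) must leave at least one query binder (have %d)",
                 support_size, n))
  }
  idx <- withr::with_seed(seed, sample.int(n, support_size))
  task$support <- task$binders[sort(idx)]
  task$query <- task$binders[setdiff(seq_len(n), sort(idx))]
  task
}

#' Partition test records into seen and unseen TCR subsets
#'
#' Splits records by exact membership of their TCR sequence in a
#' reference TCR set (e.g. the training repertoire of a model). Records
#' whose TCR occurs in the reference form the "seen" subset; the rest,
#' carrying novel TCRs, form the stricter "unseen" generalization test.
#'
#' @param test_records validated binding records.
#' @param reference_tcrs character vector (or [repertoire()]) of
#'   reference TCR sequences.
#' @param chain which CDR3 chain defines TCR identity.
#' @return a `split_report` list with `seen`, `unseen`,
#'   `n_reference_tcrs`, `n_novel_tcrs`.
#' @export
split_seen_unseen <- function(test_records, reference_tcrs,
                              chain = c("beta", "alpha")) {
  chain <- match.arg(chain)
  reference_tcrs <- unique(as.character(reference_tcrs))
  if (length(reference_tcrs) == 0L) stop("reference TCR set is empty")
  test_records <- .coerce_records(test_records)
  tcr <- test_records[[.tcr_column(chain)]]
  seen_mask <- tcr %in% reference_tcrs
  structure(list(
    seen = test_records[seen_mask, , drop = FALSE],
    unseen = test_records[!seen_mask, , drop = FALSE],
    n_reference_tcrs = length(reference_tcrs),
    n_novel_tcrs = length(unique(tcr[!seen_mask]))
  ), class = "split_report")
}

#' @export
print.split_report <- function(x, ...) {
  cat(sprintf("<split_report> seen: %d record(s); unseen: %d record(s) over %d novel TCR(s)\n",
              nrow(x$seen), nrow(x$unseen), x$n_novel_tcrs))
  invisible(x)
}
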