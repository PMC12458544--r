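# Orchestration of the two evaluation protocols and aggregation.

.metric_record <- function(metric, value, fold_id, group, strategy, scorer) {
  data.frame(metric = metric, value = as.numeric(value),
             fold_id = as.integer(fold_id), group = group,
             strategy = strategy, scorer = scorer,
             stringsAsFactors = FALSE)
}

#' Balanced multi-fold classification evaluation
#'
#' Runs the balanced classification protocol: negatives are resampled
#' independently in each of `spec$n_folds` folds under the chosen
#' strategy, every pair is scored, and per fold and peptide group the
#' ROC-AUC, PR-AUC and confusion counts at the decision threshold are
#' recorded. Scorers whose outputs leave \[0, 1\] are min-max
#' normalized per fold before thresholding (AUCs are rank-based and
#' unaffected).
#'
#' @param scorer a [scorer()].
#' @param tasks list of `peptide_task`s.
#' @param repertoire background repertoire (required for
#'   background-drawing).
#' @param spec a [sampling_spec()].
#' @param threshold decision threshold for the confusion counts.
#' @return a `data.frame` of metric records with columns `metric`,
#'   `value`, `fold_id`, `group`, `strategy`, `scorer`; one row per
#'   (fold, group present, metric in roc_auc / pr_auc / tp / fp / tn /
#'   fn).
#' @export
run_classification_eval <- function(scorer, tasks, repertoire = NULL,
                                    spec = sampling_spec(), threshold = 0.5) {
  stopifnot(inherits(scorer, "tcr_scorer"))
  folds <- make_balanced_folds(tasks, repertoire, spec)
  group_of <- setNames(vapply(tasks, `[[`, "", "group"),
                       vapply(tasks, `[[`, "", "peptide"))
  chain <- if (scorer$chains == "alpha") "alpha" else "beta"

  out <- vector("list", spec$n_folds)
  for (fid in seq_len(spec$n_folds)) {
    sub <- folds[folds$fold_id == fid, , drop = FALSE]
    scores <- numeric(nrow(sub))
    for (p in unique(sub$peptide)) {
      sel <- sub$peptide == p
      scores[sel] <- scorer$score_batch(p, sub$tcr[sel])
    }
    if (min(scores) < 0 || max(scores) > 1) {
      rng <- range(scores)
      scores <- if (rng[2] > rng[1]) (scores - rng[1]) / (rng[2] - rng[1]) else
        rep(0.5, length(scores))
    }
    y <- sub$label
    grp <- group_of[sub$peptide]
    recs <- lapply(sort(unique(grp)), function(g) {
      sel <- grp == g
      cm <- confusion_at(y[sel], scores[sel], threshold)
      .metric_record(
        metric = c("roc_auc", "pr_auc", "tp", "fp", "tn", "fn"),
        value = c(roc_auc(y[sel], scores[sel]), pr_auc(y[sel], scores[sel]),
                  cm$tp, cm$fp, cm$tn, cm$fn),
        fold_id = fid, group = g, strategy = spec$strategy,
        scorer = scorer$name)
    })
    out[[fid]] <- do.call(rbind, recs)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Repertoire-scale virtual-screening evaluation
#'
#' Screens every task's peptide against its candidate library (the
#' background repertoire plus that peptide's own query binders,
#' deduplicated - so each screen ranks its true binders within the
#' full universe) and summarises early enrichment per group: mean
#' per-peptide BEDROC, mean hit rate and success rate at each
#' top-fraction cutoff. Enrichment curves per peptide are returned
#' alongside.
#'
#' @param scorer a [scorer()].
#' @param tasks list of `peptide_task`s.
#' @param repertoire background repertoire.
#' @param alpha BEDROC weighting parameter.
#' @param variant BEDROC variant (see [bedroc()]).
#' @param k_grid top fractions of the library defining the hit-rate and
#'   success-rate cutoffs (`k = ceiling(f * N)`, at least 1).
#' @param chunk_size candidates per scorer call.
#' @param curve_grid fractions for the enrichment curves.
#' @param pooled_bedroc if `TRUE`, additionally report a pooled-ranks
#'   BEDROC per group (all screens' normalized ranks pooled into one
#'   summation) instead of only the per-peptide mean.
#' @return a list with `records` (metric `data.frame`, `fold_id = 0`,
#'   strategy `"screening"`), `curves` (named list of per-peptide
#'   enrichment curves), `screens`, and `failures`.
#' @export
run_screening_eval <- function(scorer, tasks, repertoire,
                               alpha = 20, variant = "relative",
                               k_grid = c(0.0001, 0.001, 0.01, 0.05, 0.1),
                               chunk_size = 10000L,
                               curve_grid = c(0.0001, 0.001, 0.01, 0.05,
                                              0.1, 0.25, 0.5, 1),
                               pooled_bedroc = FALSE) {
  stopifnot(inherits(scorer, "tcr_scorer"))
  screens <- screen_all(scorer, tasks, .rep_seqs(repertoire),
                        chunk_size = chunk_size, per_task_library = TRUE)
  failures <- attr(screens, "failures")
  ok_peptides <- vapply(screens, `[[`, "", "peptide")
  group_of <- setNames(vapply(tasks, `[[`, "", "group"),
                       vapply(tasks, `[[`, "", "peptide"))
  grp <- group_of[ok_peptides]

  curves <- lapply(screens, enrichment_curve, grid = curve_grid)
  names(curves) <- ok_peptides

  recs <- lapply(sort(unique(grp)), function(g) {
    sc <- screens[grp == g]
    bed <- vapply(sc, bedroc, 0, alpha = alpha, variant = variant)
    rows <- list(.metric_record("bedroc", mean(bed), 0L, g, "screening",
                                scorer$name))
    if (pooled_bedroc) {
      # pool normalized ranks over all screens in the group into one sum
      pre <- alpha / (1 - exp(-alpha))
      terms <- unlist(lapply(sc, function(s) {
        exp(-alpha * (s$binder_ranks - 1) / (s$total - 1))
      }))
      rows <- c(rows, list(.metric_record("bedroc_pooled", pre * mean(terms),
                                          0L, g, "screening", scorer$name)))
    }
    for (f in k_grid) {
      hr <- mean(vapply(sc, function(s) {
        hit_rate(s, max(1L, as.integer(ceiling(f * s$total))))
      }, 0))
      # success judged at each screen's own top-f cutoff
      sr <- mean(vapply(sc, function(s) {
        any(s$binder_ranks <= max(1L, as.integer(ceiling(f * s$total))))
      }, NA))
      rows <- c(rows, list(
        .metric_record(sprintf("hit_rate@%g", f), hr, 0L, g, "screening",
                       scorer$name),
        .metric_record(sprintf("success_rate@%g", f), sr, 0L, g, "screening",
                       scorer$name)))
    }
    do.call(rbind, rows)
  })
  records <- do.call(rbind, recs)
  rownames(records) <- NULL
  list(records = records, curves = curves, screens = screens,
       failures = failures)
}

#' Peptide-level fold assignment
#'
#' Seeded, size-balanced partition of the peptide set into `n_folds`
#' folds (sizes differ by at most one; no peptide spans folds). This is
#' the split protocol used for retraining-style evaluations where each
#' fold's peptides are held out together with all their pairs.
#'
#' @param peptides character vector of distinct peptides.
#' @param n_folds number of folds.
#' @param seed integer seed.
#' @return a `peptide_fold_split` list with `n_folds` and `assignment`
#'   (named integer vector, peptide -> fold).
#' @export
make_peptide_folds <- function(peptides, n_folds = 10L, seed = 1L) {
  peptides <- unique(as.character(peptides))
  n_folds <- .assert_scalar_int(n_folds, "n_folds", 1L)
  if (n_folds > length(peptides)) {
    stop(sprintf("n_folds (%d) exceeds the number of peptides (%d)",
                 n_folds, length(peptides)))
  }
  perm <- withr::with_seed(seed, sample(peptides))
  assignment <- setNames(rep_len(seq_len(n_folds), length(perm)), perm)
  assignment <- assignment[peptides]   # report in input order
  structure(list(n_folds = n_folds, assignment = assignment),
            class = "peptide_fold_split")
}

#' Aggregate metric records
#'
#' Summarises metric records per (metric, group, strategy, scorer):
#' mean, standard deviation, min, max and fold count. Because reported
#' spreads are sometimes ranges and sometimes standard deviations, both
#' are always present (`max - min` is recoverable from the columns).
#'
#' @param records metric records from the evaluation runners.
#' @return a summary `data.frame`, one row per combination.
#' @export
aggregate_metrics <- function(records) {
  if (is.null(records) || nrow(records) == 0L) stop("no metric records to aggregate")
  key <- interaction(records$metric, records$group, records$strategy,
                     records$scorer, drop = TRUE, sep = "\r")
  parts <- split(records, key)
  out <- do.call(rbind, lapply(parts, function(d) {
    data.frame(metric = d$metric[1], group = d$group[1],
               strategy = d$strategy[1], scorer = d$scorer[1],
               mean = mean(d$value),
               sd = if (nrow(d) > 1L) stats::sd(d$value) else 0,
               min = min(d$value), max = max(d$value),
               n_folds = nrow(d), stringsAsFactors = FALSE)
  }))
  out <- out[order(out$metric, out$group, out$strategy, out$scorer), ]
  rownames(out) <- NULL
  out
}

#' Paired resampling contrast between two scorers
#'
#' Two-sided paired sign-flip resampling test on fold-wise metric
#' differences between two scorers evaluated on shared folds: the
#' observed mean difference is compared against the null distribution
#' obtained by randomly flipping the sign of each fold's difference.
#'
#' @param records metric records containing both scorers.
#' @param metric metric name to contrast.
#' @param scorers length-2 character vector of scorer names (a - b).
#' @param group,strategy optional filters (default: use all shared
#'   rows).
#' @param n_resample number of sign-flip resamples.
#' @param seed integer seed.
#' @return a list with `mean_diff`, `p_value`, `n_folds`.
#' @export
contrast_scorers <- function(records, metric, scorers, group = NULL,
                             strategy = NULL, n_resample = 5000L, seed = 1L) {
  stopifnot(length(scorers) == 2L)
  sel <- records$metric == metric
  if (!is.null(group)) sel <- sel & records$group == group
  if (!is.null(strategy)) sel <- sel & records$strategy == strategy
  d <- records[sel, , drop = FALSE]
  a <- d[d$scorer == scorers[1], c("fold_id", "value")]
  b <- d[d$scorer == scorers[2], c("fold_id", "value")]
  m <- merge(a, b, by = "fold_id", suffixes = c("_a", "_b"))
  if (nrow(m) == 0L) stop("no shared folds between the two scorers")
  diffs <- m$value_a - m$value_b
  obs <- mean(diffs)
  flips <- withr::with_seed(seed, {
    matrix(sample(c(-1, 1), n_resample * length(diffs), replace = TRUE),
           nrow = n_resample)
  })
  null <- as.numeric(flips %*% diffs) / length(diffs)
  p <- (1 + sum(abs(null) >= abs(obs) - 1e-15)) / (n_resample + 1)
  list(mean_diff = obs, p_value = p, n_folds = length(diffs))
}
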