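# Negative-pair construction (background-drawing and reshuffling) and
# balanced evaluation folds.

#' Negative-sampling specification
#'
#' @param strategy `"background_drawing"` draws non-binding TCRs
#'   uniformly from a background repertoire; `"reshuffling"` permutes
#'   the TCR column of the known positive pairs.
#' @param ratio negatives per positive (>= 1).
#' @param seed integer master seed; each fold derives its own seed from
#'   it (bitwise XOR with the fold id), so a fixed spec reproduces
#'   byte-identical folds.
#' @param n_folds number of independent balanced negative resamplings
#'   (positives are identical across folds).
#' @return a `sampling_spec` object.
#' @export
sampling_spec <- function(strategy = c("background_drawing", "reshuffling"),
                          ratio = 1L, seed = 1L, n_folds = 100L) {
  strategy <- match.arg(strategy)
  structure(list(strategy = strategy,
                 ratio = .assert_scalar_int(ratio, "ratio", 1L),
                 seed = .assert_scalar_int(seed, "seed", 0L),
                 n_folds = .assert_scalar_int(n_folds, "n_folds", 1L)),
            class = "sampling_spec")
}

# Draw negatives for one task from the current RNG stream.
.draw_background <- function(task, pool, ratio) {
  need <- ratio * length(task$query)
  if (length(pool) < need) {
    stop(sprintf(
      "repertoire too small for peptide %s: need %d negative(s), only %d available",
      task$peptide, need, length(pool)))
  }
  pool[sample.int(length(pool), need)]
}

#' Draw background negatives for one peptide task
#'
#' Samples non-binding TCRs for a peptide uniformly without replacement
#' from the background repertoire, excluding the peptide's known
#' binders (so no sampled negative can be a known positive pair).
#' Unknown cross-reactive binders cannot be excluded; that residual
#' bias is inherent to the strategy.
#'
#' @param task a `peptide_task`.
#' @param repertoire background [repertoire()] or character vector.
#' @param ratio negatives per positive.
#' @param seed integer seed; a fixed seed reproduces the draw exactly.
#' @param exclude_binders set `FALSE` to draw from the full repertoire
#'   without removing the peptide's known binders.
#' @return a `data.frame` with columns `peptide`, `tcr`, `label`
#'   (all `"non-binder"`).
#' @export
draw_background_negatives <- function(task, repertoire, ratio = 1L,
                                      seed = 1L, exclude_binders = TRUE) {
  ratio <- .assert_scalar_int(ratio, "ratio", 1L)
  pool <- .rep_seqs(repertoire)
  if (exclude_binders) pool <- setdiff(pool, task$binders)
  neg <- withr::with_seed(seed, .draw_background(task, pool, ratio))
  data.frame(peptide = rep(task$peptide, length(neg)), tcr = neg,
             label = rep("non-binder", length(neg)),
             stringsAsFactors = FALSE)
}

# Reshuffle negatives from the current RNG stream. positives: data.frame
# with peptide, tcr. Returns data.frame(peptide, tcr).
.reshuffle <- function(positives, max_tries = 20L) {
  n <- nrow(positives)
  pos_key <- paste(positives$peptide, positives$tcr, sep = "\r")
  best <- NULL
  best_bad <- n + 1L
  for (try in seq_len(max_tries)) {
    perm <- sample.int(n)
    cand <- positives$tcr[perm]
    bad <- paste(positives$peptide, cand, sep = "\r") %in% pos_key
    if (sum(bad) < best_bad) {
      best <- cand
      best_bad <- sum(bad)
    }
    if (best_bad == 0L) break
  }
  cand <- best
  if (best_bad > 0L) {
    # greedy repair: swap each colliding assignment with a partner such
    # that both resulting pairs are non-positive
    bad_idx <- which(paste(positives$peptide, cand, sep = "\r") %in% pos_key)
    for (i in bad_idx) {
      if (!paste(positives$peptide[i], cand[i], sep = "\r") %in% pos_key) next
      for (j in sample.int(n)) {
        if (j == i) next
        pi_new <- paste(positives$peptide[i], cand[j], sep = "\r")
        pj_new <- paste(positives$peptide[j], cand[i], sep = "\r")
        if (!pi_new %in% pos_key && !pj_new %in% pos_key) {
          tmp <- cand[i]; cand[i] <- cand[j]; cand[j] <- tmp
          break
        }
      }
    }
  }
  still_bad <- paste(positives$peptide, cand, sep = "\r") %in% pos_key
  out <- data.frame(peptide = positives$peptide[!still_bad],
                    tcr = cand[!still_bad], stringsAsFactors = FALSE)
  if (any(still_bad)) {
    warning(sprintf("reshuffling: dropped %d irreparable collision(s)",
                    sum(still_bad)))
  }
  out
}

#' Construct reshuffled negatives
#'
#' Forms non-binding pairs by permuting the TCR column across the known
#' positive pairs, rejecting permutations that recreate a known
#' positive; after a bounded number of rejected permutations the best
#' candidate is repaired greedily by pairwise swaps. The marginal TCR
#' multiset of the positives is preserved (before any irreparable
#' collisions are dropped), yielding one negative per positive when
#' achievable.
#'
#' @param records binding records whose `label == "binder"` rows are the
#'   positive pairs (non-binder rows are ignored).
#' @param seed integer seed.
#' @param chain which CDR3 chain defines the TCR.
#' @param max_tries maximum rejected whole permutations before repair.
#' @return a `data.frame` with columns `peptide`, `tcr`, `label`.
#' @export
reshuffle_negatives <- function(records, seed = 1L,
                                chain = c("beta", "alpha"), max_tries = 20L) {
  chain <- match.arg(chain)
  records <- .coerce_records(records)
  pos <- records[records$label == "binder", , drop = FALSE]
  positives <- data.frame(peptide = pos$peptide,
                          tcr = pos[[.tcr_column(chain)]],
                          stringsAsFactors = FALSE)
  positives <- positives[!is.na(positives$tcr) & nzchar(positives$tcr), ]
  if (length(unique(positives$peptide)) < 2L) {
    stop("reshuffling undefined: need positives from at least 2 distinct peptides")
  }
  out <- withr::with_seed(seed, .reshuffle(positives, max_tries))
  out$label <- "non-binder"
  out
}

#' Assemble balanced evaluation folds
#'
#' Builds `n_folds` balanced classification folds. Positives (each
#' task's query binders) are identical across folds; each fold draws an
#' independent set of negatives under the chosen strategy with fold
#' seed `xor(spec$seed, fold_id)`, so repeated negative resampling
#' covers far more distinct negatives than any single balanced subset.
#' Within a fold every peptide has `ratio` negatives per positive
#' (exactly balanced at the default ratio 1) and no pair occurs twice.
#'
#' @param tasks a list of `peptide_task`s ([stratify_peptides()]).
#' @param repertoire background repertoire; required for the
#'   background-drawing strategy.
#' @param spec a [sampling_spec()].
#' @return a `data.frame` with columns `fold_id`, `peptide`, `tcr`,
#'   `label`, `strategy`.
#' @export
make_balanced_folds <- function(tasks, repertoire = NULL,
                                spec = sampling_spec()) {
  if (!inherits(spec, "sampling_spec")) stop("'spec' must be a sampling_spec")
  if (spec$strategy == "background_drawing" && is.null(repertoire)) {
    stop("background_drawing requires a repertoire")
  }
  positives <- do.call(rbind, lapply(tasks, function(t) {
    data.frame(peptide = t$peptide, tcr = t$query, label = "binder",
               stringsAsFactors = FALSE)
  }))
  if (is.null(positives) || nrow(positives) == 0L) stop("no positive pairs in tasks")
  if (spec$strategy == "reshuffling" &&
      length(unique(positives$peptide)) < 2L) {
    stop("reshuffling undefined: need positives from at least 2 distinct peptides")
  }
  pool_all <- if (!is.null(repertoire)) .rep_seqs(repertoire) else NULL

  folds <- lapply(seq_len(spec$n_folds), function(fold_id) {
    fold_seed <- bitwXor(spec$seed, fold_id)
    neg <- withr::with_seed(fold_seed, {
      if (spec$strategy == "background_drawing") {
        do.call(rbind, lapply(tasks, function(t) {
          pool <- setdiff(pool_all, t$binders)
          tryCatch(
            data.frame(peptide = t$peptide,
                       tcr = .draw_background(t, pool, spec$ratio),
                       label = "non-binder", stringsAsFactors = FALSE),
            error = function(e) stop(sprintf("fold %d: %s", fold_id,
                                             conditionMessage(e)), call. = FALSE))
        }))
      } else {
        ns <- .reshuffle(positives)
        if (spec$ratio > 1L) {
          extra <- lapply(seq_len(spec$ratio - 1L), function(k) .reshuffle(positives))
          ns <- unique(rbind(ns, do.call(rbind, extra)))
        }
        ns$label <- "non-binder"
        ns
      }
    })
    out <- rbind(positives, neg)
    out <- out[!duplicated(paste(out$peptide, out$tcr, out$label, sep = "\r")), ]
    cbind(fold_id = fold_id, out)
  })
  out <- do.call(rbind, folds)
  out$strategy <- spec$strategy
  rownames(out) <- NULL
  out
}
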