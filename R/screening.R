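# Scorer contract and repertoire-scale virtual screening.

#' Construct a scorer
#'
#' The scorer contract abstracts any peptide-TCR binding predictor: a
#' function that maps one peptide and a batch of TCR sequences to a
#' numeric score per TCR, where higher scores mean higher predicted
#' binding likelihood. Scorers must be deterministic (a stochastic
#' predictor must carry its own fixed seed) so that screening results
#' do not depend on how the library is chunked.
#'
#' @param name identity string, recorded in metric tables.
#' @param score_batch `function(peptide, tcrs)` returning
#'   `length(tcrs)` numeric scores.
#' @param chains which chain(s) the scorer consumes: `"beta"`,
#'   `"alpha"` or `"alphabeta"`.
#' @return a `tcr_scorer` object.
#' @seealso [make_scorer()] for synthetic scorers,
#'   [score_table_scorer()] for pre-computed score tables.
#' @export
scorer <- function(name, score_batch, chains = c("beta", "alpha", "alphabeta")) {
  chains <- match.arg(chains)
  if (!is.function(score_batch) || length(formals(score_batch)) < 2L) {
    stop("'score_batch' must be a function(peptide, tcrs)")
  }
  structure(list(name = as.character(name), chains = chains,
                 score_batch = score_batch),
            class = "tcr_scorer")
}

#' @export
print.tcr_scorer <- function(x, ...) {
  cat(sprintf("<tcr_scorer> %s (%s chain)\n", x$name, x$chains))
  invisible(x)
}

#' Scorer backed by a pre-computed score table
#'
#' Offline mode: evaluate an external predictor without code coupling
#' by loading its per-pair scores from a table with columns `peptide`,
#' `tcr`, `score`. Requests for pairs absent from the table raise an
#' error (which [screen_all()] collects per peptide into its failure
#' report).
#'
#' @param table a `data.frame` with columns `peptide`, `tcr`, `score`,
#'   e.g. from [read_score_table()].
#' @param name identity string.
#' @param chains chain tag (bookkeeping only).
#' @return a `tcr_scorer`.
#' @export
score_table_scorer <- function(table, name = "score_table", chains = "beta") {
  stopifnot(is.data.frame(table),
            all(c("peptide", "tcr", "score") %in% names(table)))
  key <- paste(table$peptide, table$tcr, sep = "\r")
  if (anyDuplicated(key)) stop("score table contains duplicate (peptide, tcr) pairs")
  score <- as.numeric(table$score)
  lookup <- new.env(parent = emptyenv(), size = length(key))
  # environment hash gives O(1) lookup without bringing in a dependency
  split_scores <- split(seq_along(key), table$peptide)
  for (p in names(split_scores)) {
    idx <- split_scores[[p]]
    assign(p, list(tcr = table$tcr[idx], score = score[idx]), envir = lookup)
  }
  scorer(name, chains = chains, score_batch = function(peptide, tcrs) {
    if (!exists(peptide, envir = lookup, inherits = FALSE)) {
      stop(sprintf("no scores for peptide %s in score table", peptide))
    }
    entry <- get(peptide, envir = lookup, inherits = FALSE)
    m <- match(tcrs, entry$tcr)
    if (anyNA(m)) {
      stop(sprintf("score table missing %d TCR score(s) for peptide %s",
                   sum(is.na(m)), peptide))
    }
    entry$score[m]
  })
}

#' Screen one peptide against a candidate library
#'
#' Scores every candidate in the library in chunks, ranks by descending
#' score (ties broken by library position, deterministically), and
#' extracts the ranks of the true binders by exact sequence match.
#' Scores are materialized only for the current peptide; rankings are
#' identical for any chunk size.
#'
#' @param scorer a [scorer()].
#' @param peptide peptide sequence.
#' @param library candidate [repertoire()] or character vector (the
#'   screening universe N).
#' @param binders character vector of the peptide's true binders (the
#'   truth set; exact matches within the library).
#' @param chunk_size candidates scored per scorer call.
#' @param keep_ranking also return the full ranked library as attribute
#'   `"ranking"` (order of library indices) and `"scores"`.
#' @return a [ranked_screen()].
#' @export
screen_peptide <- function(scorer, peptide, library, binders = character(0),
                           chunk_size = 10000L, keep_ranking = FALSE) {
  stopifnot(inherits(scorer, "tcr_scorer"))
  lib <- .rep_seqs(library)
  N <- length(lib)
  if (N == 0L) stop("screening library is empty")
  chunk_size <- .assert_scalar_int(chunk_size, "chunk_size", 1L)
  scores <- numeric(N)
  start <- 1L
  while (start <= N) {
    end <- min(start + chunk_size - 1L, N)
    s <- scorer$score_batch(peptide, lib[start:end])
    if (!is.numeric(s) || length(s) != end - start + 1L) {
      stop(sprintf(
        "scorer '%s' violated its contract: expected %d numeric scores, got %d",
        scorer$name, end - start + 1L, length(s)))
    }
    scores[start:end] <- s
    start <- end + 1L
  }
  ord <- order(-scores, seq_len(N))
  pos_idx <- which(lib %in% binders)
  ranks <- sort(match(pos_idx, ord))
  out <- ranked_screen(ranks, total = N, peptide = peptide)
  if (keep_ranking) {
    attr(out, "ranking") <- ord
    attr(out, "scores") <- scores
  }
  out
}

#' Screen a set of peptide tasks against a library
#'
#' Runs [screen_peptide()] for each task (truth set = the task's query
#' binders), preserving task order. Per-peptide failures do not abort
#' the run; they are collected into attribute `"failures"`.
#'
#' @param scorer a [scorer()].
#' @param tasks list of `peptide_task`s.
#' @param library screening library.
#' @param chunk_size candidates per scorer call.
#' @param per_task_library if `TRUE`, each peptide is screened against
#'   `library` augmented with its own query binders (deduplicated), so
#'   every screen contains its truth set; if `FALSE` the library is
#'   used as-is.
#' @param verbose log progress per peptide.
#' @return a list of [ranked_screen()]s (failed peptides omitted), with
#'   attribute `"failures"`: a `data.frame` of peptide and error
#'   message.
#' @export
screen_all <- function(scorer, tasks, library, chunk_size = 10000L,
                       per_task_library = FALSE, verbose = FALSE) {
  failures <- list()
  screens <- list()
  lib0 <- .rep_seqs(library)
  for (t in tasks) {
    lib <- if (per_task_library) unique(c(lib0, t$query)) else lib0
    res <- tryCatch(
      screen_peptide(scorer, t$peptide, lib, binders = t$query,
                     chunk_size = chunk_size),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <-
        data.frame(peptide = t$peptide, error = conditionMessage(res),
                   stringsAsFactors = FALSE)
    } else {
      if (verbose) {
        message(sprintf("screened %s: %d binder(s) in %d candidates",
                        t$peptide, res$n, res$total))
      }
      screens[[length(screens) + 1L]] <- res
    }
  }
  attr(screens, "failures") <- if (length(failures) > 0L) {
    do.call(rbind, failures)
  } else {
    data.frame(peptide = character(0), error = character(0))
  }
  screens
}

#' Fuse alpha- and beta-chain scores
#'
#' Combines per-pair predictions from a TCR-alpha model and a TCR-beta
#' model into a single binding score by the element-wise arithmetic
#' mean, the standard late-fusion rule for paired-chain prediction.
#'
#' @param score_alpha,score_beta equal-length numeric vectors.
#' @return the element-wise mean.
#' @export
fuse_alpha_beta <- function(score_alpha, score_beta) {
  if (length(score_alpha) != length(score_beta)) {
    stop("alpha and beta score vectors differ in length")
  }
  (as.numeric(score_alpha) + as.numeric(score_beta)) / 2
}
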