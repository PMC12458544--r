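# Classification and early-enrichment metrics.

#' Construct a ranked screen
#'
#' Summary of one virtual screen: a library of `total` candidates was
#' ranked by descending predicted score and the true binders sit at the
#' 1-based positions `binder_ranks`. This is the sole input to all
#' early-enrichment metrics.
#'
#' @param binder_ranks strictly increasing integer positions in
#'   `[1, total]`.
#' @param total library size N.
#' @param peptide optional peptide identifier.
#' @return a `ranked_screen` object with fields `peptide`, `total`,
#'   `binder_ranks`, `n`.
#' @export
ranked_screen <- function(binder_ranks, total, peptide = NA_character_) {
  total <- .assert_scalar_int(total, "total", 1L)
  binder_ranks <- as.integer(binder_ranks)
  if (length(binder_ranks) > 0L) {
    if (any(is.na(binder_ranks)) || any(binder_ranks < 1L) ||
        any(binder_ranks > total)) {
      stop("binder_ranks must lie in [1, total]")
    }
    if (any(diff(binder_ranks) <= 0L)) {
      stop("binder_ranks must be strictly increasing")
    }
  }
  structure(list(peptide = as.character(peptide), total = total,
                 binder_ranks = binder_ranks,
                 n = length(binder_ranks)),
            class = "ranked_screen")
}

#' @export
print.ranked_screen <- function(x, ...) {
  cat(sprintf("<ranked_screen> %s: %d binder(s) in a library of %d; best rank %s\n",
              x$peptide, x$n, x$total,
              if (x$n > 0) x$binder_ranks[1] else "-"))
  invisible(x)
}

#' BEDROC early-enrichment score
#'
#' Boltzmann-enhanced discrimination of ROC: ranks of true binders are
#' weighted exponentially, so binders recovered early in the ranked
#' list dominate the score. With normalized ranks
#' \eqn{R_i = (r_i - 1)/(N - 1)}, the default `"relative"` variant is
#' \deqn{\frac{\alpha}{1 - e^{-\alpha}} \cdot \frac{1}{n}
#'       \sum_{i=1}^{n} e^{-\alpha R_i}.}
#' Under a uniform random ranking its expectation is ~1 (for
#' \eqn{N \gg 1}) and its maximum, with all binders at the very top,
#' approaches \eqn{\alpha/(1 - e^{-\alpha})}; read it as a fold
#' enrichment over random. The `"truchon_bayly"` variant is the
#' classical formulation bounded to \[0, 1\] via the robust initial
#' enhancement; it is offered for comparability with the virtual
#' screening literature and is never substituted silently.
#'
#' @param screen a [ranked_screen()].
#' @param alpha positive weighting parameter; the default 20
#'   concentrates weight on the earliest ranks.
#' @param variant `"relative"` (default) or `"truchon_bayly"`.
#' @return a single numeric score.
#' @examples
#' s <- ranked_screen(c(1L, 10L), total = 10L)
#' bedroc(s, alpha = 20)
#' @export
bedroc <- function(screen, alpha = 20, variant = c("relative", "truchon_bayly")) {
  variant <- match.arg(variant)
  stopifnot(inherits(screen, "ranked_screen"))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0) {
    stop("'alpha' must be a positive scalar")
  }
  n <- screen$n
  N <- screen$total
  if (n == 0L) stop("bedroc undefined for a screen with no binders")
  if (N < 2L) stop("bedroc requires a library of at least 2 (rank normalization)")
  r <- screen$binder_ranks
  if (variant == "relative") {
    R <- (r - 1) / (N - 1)
    return(alpha / (1 - exp(-alpha)) * mean(exp(-alpha * R)))
  }
  # Truchon-Bayly: RIE scaled to [0, 1]
  ra <- n / N
  rie <- mean(exp(-alpha * r / N)) /
    ((1 / N) * (1 - exp(-alpha)) / (exp(alpha / N) - 1))
  rie * ra * sinh(alpha / 2) /
    (cosh(alpha / 2) - cosh(alpha / 2 - alpha * ra)) +
    1 / (1 - exp(alpha * (1 - ra)))
}

#' Enrichment curve
#'
#' Cumulative fraction of true binders recovered as a function of the
#' fraction of the ranked library examined. At fraction `f` the top
#' `ceiling(f * N)` candidates are examined.
#'
#' @param screen a [ranked_screen()].
#' @param grid fractions in (0, 1].
#' @return a `data.frame` with columns `fraction_examined`,
#'   `fraction_recovered`; non-decreasing, ending at 1 when the grid
#'   includes 1.
#' @export
enrichment_curve <- function(screen, grid = c(0.0001, 0.001, 0.01, 0.05,
                                              0.1, 0.25, 0.5, 1)) {
  stopifnot(inherits(screen, "ranked_screen"))
  if (length(grid) == 0L) stop("enrichment grid is empty")
  if (any(grid <= 0 | grid > 1)) stop("grid fractions must lie in (0, 1]")
  if (screen$n == 0L) stop("enrichment undefined for a screen with no binders")
  grid <- sort(unique(grid))
  rec <- vapply(grid, function(f) {
    sum(screen$binder_ranks <= ceiling(f * screen$total)) / screen$n
  }, 0)
  data.frame(fraction_examined = grid, fraction_recovered = rec)
}

#' Hit rate at top-k
#'
#' Proportion of a peptide's true binders retrieved within the top `k`
#' ranked candidates.
#'
#' @param screen a [ranked_screen()].
#' @param k integer cutoff, `1 <= k <= N`.
#' @return a fraction in \[0, 1\].
#' @export
hit_rate <- function(screen, k) {
  stopifnot(inherits(screen, "ranked_screen"))
  k <- .assert_scalar_int(k, "k", 1L)
  if (k > screen$total) stop("'k' exceeds the library size")
  if (screen$n == 0L) stop("hit rate undefined for a screen with no binders")
  sum(screen$binder_ranks <= k) / screen$n
}

#' Success rate at top-k
#'
#' Fraction of query peptides whose screen recovered at least one true
#' binder within the top `k` ranks. This is the standard virtual
#' screening convention for "success"; cutoffs larger than a screen's
#' library are capped at its size.
#'
#' @param screens a list of [ranked_screen()] objects (one per peptide).
#' @param k integer cutoff.
#' @return a fraction in \[0, 1\].
#' @export
success_rate <- function(screens, k) {
  if (length(screens) == 0L) stop("no screens supplied")
  k <- .assert_scalar_int(k, "k", 1L)
  mean(vapply(screens, function(s) {
    any(s$binder_ranks <= min(k, s$total))
  }, NA))
}

#' ROC-AUC
#'
#' Area under the ROC curve via the rank-sum (Mann-Whitney)
#' formulation: the probability that a random positive outscores a
#' random negative, with ties counted one half.
#'
#' @param labels binary labels (`"binder"`/`"non-binder"`, logical, or
#'   0/1).
#' @param scores numeric scores, higher = more binder-like.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(labels, scores) {
  y <- .as_binary(labels)
  if (length(y) != length(scores)) stop("labels and scores differ in length")
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) stop("roc_auc requires both classes")
  r <- rank(scores)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' PR-AUC (average precision)
#'
#' Step-wise average precision: precision at each positive-containing
#' prefix of the descending-score ordering, averaged over positives
#' (\eqn{\sum_k (R_k - R_{k-1}) P_k}). Ties are broken by original
#' position, matching the ranking tie policy used throughout.
#'
#' @inheritParams roc_auc
#' @return average precision in (0, 1].
#' @export
pr_auc <- function(labels, scores) {
  y <- .as_binary(labels)
  if (length(y) != length(scores)) stop("labels and scores differ in length")
  n1 <- sum(y == 1L)
  if (n1 == 0L) stop("pr_auc requires at least one positive")
  ord <- order(-scores, seq_along(scores))
  ys <- y[ord]
  prec_at <- cumsum(ys) / seq_along(ys)
  sum(prec_at[ys == 1L]) / n1
}

#' Confusion matrix at a score threshold
#'
#' Scores at or above the threshold are predicted binders. The four
#' counts always partition the evaluated pairs; the false-positive rate
#' `fp / (fp + tn)` is the quantity that separates the two
#' negative-sampling strategies for memorization-driven predictors.
#'
#' @inheritParams roc_auc
#' @param threshold decision threshold on the score.
#' @return a `confusion_matrix` list with `tp`, `fp`, `tn`, `fn`,
#'   `threshold`.
#' @export
confusion_at <- function(labels, scores, threshold = 0.5) {
  y <- .as_binary(labels)
  if (length(y) != length(scores)) stop("labels and scores differ in length")
  pred <- scores >= threshold
  structure(list(tp = sum(pred & y == 1L),
                 fp = sum(pred & y == 0L),
                 tn = sum(!pred & y == 0L),
                 fn = sum(!pred & y == 1L),
                 threshold = threshold),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> @%.3g  tp=%d fp=%d tn=%d fn=%d (fpr=%.3f)\n",
              x$threshold, x$tp, x$fp, x$tn, x$fn,
              if (x$fp + x$tn > 0) x$fp / (x$fp + x$tn) else NA_real_))
  invisible(x)
}

#' False-positive rate of a confusion matrix
#' @param cm a `confusion_matrix`.
#' @return `fp / (fp + tn)`.
#' @export
false_positive_rate <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (cm$fp + cm$tn == 0L) return(NA_real_)
  cm$fp / (cm$fp + cm$tn)
}
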