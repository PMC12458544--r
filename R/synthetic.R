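# Synthetic peptide/TCR data with exact ground truth, plus synthetic
# scorers. Every pipeline stage can be exercised without trained models.
#
# Construction guarantees exact labels: each peptide carries a hidden
# CDR3 motif containing motif_mismatch + 1 tryptophan (W) anchor
# positions, while background repertoire sequences are drawn from the
# 19-letter alphabet without W. A sequence matching the motif with at
# most motif_mismatch substitutions (never at an anchor) reaches the
# binder threshold; no background sequence can, so truth labels are a
# pure function of sequence.

.BG_AA <- setdiff(.AA, "W")

#' Synthetic dataset configuration
#'
#' Describes a synthetic multi-peptide binding table with heavy-tailed
#' binder counts spanning the three task groups, plus a large disjoint
#' background repertoire. Defaults give 30 peptides (5 majority, 15
#' few-shot, 10 zero-shot under the default [group_thresholds()]) over
#' a 10,000-sequence repertoire.
#'
#' @param group_sizes named integer vector: peptides per group
#'   (`majority`, `fewshot`, `zeroshot`).
#' @param repertoire_size background library size.
#' @param peptide_length,cdr3_length inclusive length ranges.
#' @param motif_length length of the hidden binding motif.
#' @param motif_mismatch maximum substitutions a binder may carry
#'   relative to the motif.
#' @param noise_sd Gaussian score noise used by the `noisy_oracle`
#'   scorer (the ground truth itself is noise-free).
#' @param chains `"beta"` for single-chain data, `"alphabeta"` for
#'   paired-chain data where each chain carries an independent motif.
#' @param majority_count,fewshot_count,zeroshot_count inclusive binder
#'   count ranges per group, chosen to straddle the default group
#'   thresholds (>= 100, 5-100, < 5).
#' @param seed integer seed; generation is a pure function of the
#'   config.
#' @return a `synthetic_config` object.
#' @export
synthetic_config <- function(group_sizes = c(majority = 5L, fewshot = 15L,
                                             zeroshot = 10L),
                             repertoire_size = 10000L,
                             peptide_length = c(8L, 15L),
                             cdr3_length = c(12L, 20L),
                             motif_length = 5L,
                             motif_mismatch = 1L,
                             noise_sd = 0.1,
                             chains = c("beta", "alphabeta"),
                             majority_count = c(100L, 150L),
                             fewshot_count = c(5L, 99L),
                             zeroshot_count = c(1L, 4L),
                             seed = 42L) {
  chains <- match.arg(chains)
  stopifnot(all(c("majority", "fewshot", "zeroshot") %in% names(group_sizes)),
            all(group_sizes >= 0L), sum(group_sizes) >= 1L,
            motif_length >= 2L, motif_mismatch >= 0L,
            motif_mismatch + 1L < motif_length,
            cdr3_length[1] >= motif_length,
            noise_sd >= 0)
  structure(list(group_sizes = group_sizes,
                 repertoire_size = .assert_scalar_int(repertoire_size,
                                                      "repertoire_size", 1L),
                 peptide_length = as.integer(peptide_length),
                 cdr3_length = as.integer(cdr3_length),
                 motif_length = as.integer(motif_length),
                 motif_mismatch = as.integer(motif_mismatch),
                 noise_sd = noise_sd,
                 chains = chains,
                 majority_count = as.integer(majority_count),
                 fewshot_count = as.integer(fewshot_count),
                 zeroshot_count = as.integer(zeroshot_count),
                 seed = .assert_scalar_int(seed, "seed", 0L)),
            class = "synthetic_config")
}

# Random sequences over `letters`, lengths uniform in len_range; uses
# the current RNG stream.
.rand_seqs <- function(n, len_range, letters) {
  lens <- sample(seq(len_range[1], len_range[2]), n, replace = TRUE)
  chars <- sample(letters, sum(lens), replace = TRUE)
  vapply(split(chars, rep.int(seq_len(n), lens)), paste, "", collapse = "")
}

.rand_unique_seqs <- function(n, len_range, letters) {
  out <- character(0)
  tries <- 0L
  while (length(out) < n) {
    tries <- tries + 1L
    if (tries > 50L) stop("cannot generate enough unique sequences; ",
                          "increase length range")
    out <- unique(c(out, .rand_seqs(n - length(out) + 16L, len_range, letters)))
  }
  out[seq_len(n)]
}

#' Generate a synthetic background repertoire
#'
#' Unique CDR3-like sequences with lengths in the configured range,
#' drawn from the 19-letter alphabet excluding tryptophan so that no
#' background sequence can reach any planted motif's binder threshold
#' (the repertoire is guaranteed disjoint from every peptide's binder
#' set).
#'
#' @param size number of sequences.
#' @param config a [synthetic_config()]; its seed (offset for this
#'   stream) makes the repertoire reproducible.
#' @return a [repertoire()].
#' @export
generate_repertoire <- function(size, config = synthetic_config()) {
  size <- .assert_scalar_int(size, "size", 1L)
  lr <- config$cdr3_length
  capacity <- sum(length(.BG_AA)^(seq(lr[1], min(lr[2], lr[1] + 3L))))
  if (size > capacity / 4) {
    stop("requested repertoire size is infeasible for the configured lengths")
  }
  seqs <- withr::with_seed(.child_seed(config$seed, 7919L),
                           .rand_unique_seqs(size, lr, .BG_AA))
  repertoire(seqs, chain = if (config$chains == "beta") "beta" else "alphabeta")
}

# One motif: motif_mismatch + 1 anchor W's at random positions, rest
# from the background alphabet.
.make_motif <- function(config) {
  m <- sample(.BG_AA, config$motif_length, replace = TRUE)
  anchors <- sample.int(config$motif_length, config$motif_mismatch + 1L)
  m[anchors] <- "W"
  paste(m, collapse = "")
}

# One binder CDR3 embedding `motif` with `nmut` substitutions at
# non-anchor motif positions.
.make_binder <- function(motif, config) {
  L <- sample(seq(config$cdr3_length[1], config$cdr3_length[2]), 1L)
  chars <- sample(.BG_AA, L, replace = TRUE)
  mc <- strsplit(motif, "")[[1]]
  ml <- length(mc)
  nmut <- sample.int(config$motif_mismatch + 1L, 1L) - 1L
  if (nmut > 0L) {
    non_anchor <- which(mc != "W")
    for (p in sample(non_anchor, nmut)) {
      mc[p] <- sample(setdiff(.BG_AA, mc[p]), 1L)
    }
  }
  start <- sample.int(L - ml + 1L, 1L)
  chars[start:(start + ml - 1L)] <- mc
  paste(chars, collapse = "")
}

#' Generate a synthetic binding dataset with ground truth
#'
#' Emits a binding table of positive records whose peptides span the
#' majority, few-shot and zero-shot groups with the configured counts,
#' a disjoint background repertoire, and a `ground_truth` object from
#' which every label regenerates exactly: a pair is a binder iff its
#' motif-match affinity ([truth_affinity()]) reaches
#' `truth$binder_threshold`. For `chains = "alphabeta"` each peptide
#' carries one motif per chain and both chains carry signal.
#'
#' @param config a [synthetic_config()].
#' @return a list with `records` (binding table), `truth`
#'   (`ground_truth`), `repertoire` ([repertoire()]).
#' @export
generate_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  chains <- if (config$chains == "beta") "beta" else c("alpha", "beta")

  gen <- withr::with_seed(config$seed, {
    n_pep <- sum(config$group_sizes)
    peptides <- .rand_unique_seqs(n_pep, config$peptide_length, .AA)
    counts <- unlist(lapply(c("majority", "fewshot", "zeroshot"), function(g) {
      k <- config$group_sizes[[g]]
      if (k == 0L) return(integer(0))
      rng <- config[[paste0(g, "_count")]]
      sample(seq(rng[1], rng[2]), k, replace = TRUE)
    }))
    # interleave group membership by construction order
    motifs <- lapply(peptides, function(p) {
      ms <- lapply(chains, function(ch) .make_motif(config))
      names(ms) <- chains
      ms
    })
    names(motifs) <- peptides
    rec_list <- vector("list", n_pep)
    for (i in seq_len(n_pep)) {
      p <- peptides[i]
      cols <- list()
      for (ch in chains) {
        seqs <- character(0)
        while (length(seqs) < counts[i]) {
          seqs <- unique(c(seqs, vapply(seq_len(counts[i] - length(seqs)),
                                        function(j) .make_binder(motifs[[p]][[ch]],
                                                                 config), "")))
        }
        cols[[ch]] <- seqs
      }
      rec_list[[i]] <- data.frame(
        peptide = p,
        cdr3b = if ("beta" %in% chains) cols[["beta"]] else NA_character_,
        cdr3a = if ("alpha" %in% chains) cols[["alpha"]] else NA_character_,
        label = "binder",
        source = "synthetic",
        stringsAsFactors = FALSE)
    }
    list(records = do.call(rbind, rec_list), motifs = motifs)
  })

  records <- .coerce_records(gen$records)
  truth <- structure(list(
    motifs = gen$motifs,
    motif_length = config$motif_length,
    motif_mismatch = config$motif_mismatch,
    binder_threshold = (config$motif_length - config$motif_mismatch) /
      config$motif_length,
    binders = lapply(setNames(nm = chains), function(ch) {
      col <- if (ch == "beta") "cdr3b" else "cdr3a"
      unique(records[[col]])
    }),
    chains = config$chains,
    noise_sd = config$noise_sd
  ), class = "ground_truth")

  list(records = records,
       truth = truth,
       repertoire = generate_repertoire(config$repertoire_size, config))
}

#' Motif-match affinity of TCR sequences for a peptide
#'
#' The synthetic ground-truth affinity: the best sliding-window match
#' fraction between the TCR sequence and the peptide's hidden motif
#' (matches / motif length, maximised over windows). A pair is labelled
#' binder iff this value is at least `truth$binder_threshold`.
#'
#' @param truth a `ground_truth` from [generate_dataset()].
#' @param peptide peptide sequence (must be part of the truth).
#' @param tcrs character vector of CDR3 sequences.
#' @param chain which chain's motif to match against.
#' @return numeric affinities in \[0, 1\].
#' @export
truth_affinity <- function(truth, peptide, tcrs, chain = c("beta", "alpha")) {
  chain <- match.arg(chain)
  stopifnot(inherits(truth, "ground_truth"))
  m <- truth$motifs[[peptide]]
  if (is.null(m)) stop(sprintf("peptide %s is not part of the ground truth", peptide))
  motif <- m[[chain]]
  if (is.null(motif)) stop(sprintf("ground truth has no %s-chain motif", chain))
  mc <- strsplit(motif, "")[[1]]
  ml <- length(mc)
  vapply(strsplit(as.character(tcrs), ""), function(tc) {
    L <- length(tc)
    if (L < ml) return(0)
    best <- 0L
    for (s in seq_len(L - ml + 1L)) {
      hits <- sum(tc[s:(s + ml - 1L)] == mc)
      if (hits > best) best <- hits
    }
    best / ml
  }, 0)
}

#' Construct a synthetic scorer
#'
#' Four reference scorers close the loop between generator and
#' evaluator:
#' * `oracle` - returns the true motif-match affinity; the ideal
#'   predictor, defining the performance ceiling.
#' * `noisy_oracle` - affinity plus deterministic pseudo-Gaussian noise
#'   (`noise_sd`), for dialling difficulty.
#' * `random` - deterministic pseudo-uniform scores keyed by
#'   (seed, peptide, TCR); the calibration null.
#' * `tcr_memorization` - scores a TCR high iff it is a known binder of
#'   *any* peptide in the truth, ignoring the peptide entirely. This
#'   operationalizes label memorization of TCRs and reproduces the
#'   inflated false-positive rate that reshuffled negatives expose.
#'
#' All four satisfy the scorer contract exactly: scores depend only on
#' (peptide, TCR), never on batch composition, so screening is
#' chunk-invariant.
#'
#' @param kind scorer kind (see above).
#' @param truth `ground_truth`; required for all kinds except
#'   `random`.
#' @param seed integer seed folded into the deterministic noise /
#'   random streams.
#' @param noise_sd noise level for `noisy_oracle` (defaults to the
#'   truth's configured `noise_sd`).
#' @param chain which chain the scorer reads.
#' @return a [scorer()].
#' @export
make_scorer <- function(kind = c("oracle", "noisy_oracle", "random",
                                 "tcr_memorization"),
                        truth = NULL, seed = 1L, noise_sd = NULL,
                        chain = c("beta", "alpha")) {
  kind <- match.arg(kind)
  chain <- match.arg(chain)
  seed <- .assert_scalar_int(seed, "seed", 0L)
  if (kind != "random" && !inherits(truth, "ground_truth")) {
    stop(sprintf("scorer kind '%s' requires a ground_truth object", kind))
  }
  fn <- switch(kind,
    oracle = function(peptide, tcrs) {
      truth_affinity(truth, peptide, tcrs, chain = chain)
    },
    noisy_oracle = {
      sdv <- noise_sd %||% truth$noise_sd
      function(peptide, tcrs) {
        aff <- truth_affinity(truth, peptide, tcrs, chain = chain)
        u <- .hash_unit(tcrs, salt = paste0("noise:", seed, ":", peptide))
        aff + stats::qnorm(pmin(pmax(u, 1e-12), 1 - 1e-12)) * sdv
      }
    },
    random = function(peptide, tcrs) {
      .hash_unit(tcrs, salt = paste0("rand:", seed, ":", peptide))
    },
    tcr_memorization = {
      ch_key <- if (chain == "beta") "beta" else "alpha"
      known <- truth$binders[[ch_key]]
      if (is.null(known)) stop("ground truth carries no binders for this chain")
      function(peptide, tcrs) {
        base <- ifelse(tcrs %in% known, 0.9, 0.1)
        base + 0.05 * (.hash_unit(tcrs, salt = paste0("mem:", seed)) - 0.5)
      }
    })
  scorer(name = kind, score_batch = fn,
         chains = if (chain == "beta") "beta" else "alpha")
}
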