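# Shared fixtures and independent oracles used across the suite.
# Oracles are written as plain loops so they share no code path with
# the package implementations they check.

# Direct-summation BEDROC oracle (relative variant), scalar loop.
bedroc_direct_sum <- function(ranks, N, alpha = 20) {
  total <- 0
  for (r in ranks) {
    total <- total + exp(-alpha * (r - 1) / (N - 1))
  }
  (alpha / (1 - exp(-alpha))) * total / length(ranks)
}

# Brute-force pairwise-concordance ROC-AUC oracle.
roc_auc_pairwise <- function(labels, scores) {
  y <- if (is.character(labels)) labels == "binder" else as.logical(labels)
  sp <- scores[y]
  sn <- scores[!y]
  acc <- 0
  for (a in sp) {
    for (b in sn) {
      acc <- acc + if (a > b) 1 else if (a == b) 0.5 else 0
    }
  }
  acc / (length(sp) * length(sn))
}

# Tiny well-formed binding table: two peptides, three binders.
tiny_records <- function() {
  binding_records(
    peptide = c("GILGFVFTL", "GILGFVFTL", "NLVPMVATV"),
    cdr3b = c("CASSIRSSYEQYF", "CASSLAPGATNEKLFF", "CASSPVTGGIYGYTF"),
    label = "binder"
  )
}

# Small synthetic dataset used by most pipeline tests.
small_config <- function(seed = 11L, ...) {
  synthetic_config(group_sizes = c(majority = 2L, fewshot = 4L, zeroshot = 3L),
                   repertoire_size = 2000L, seed = seed, ...)
}

small_dataset <- function(seed = 11L, ...) {
  generate_dataset(small_config(seed = seed, ...))
}

# Random ranked screens for property tests (uniform binder ranks).
random_screen <- function(n, N) {
  ranked_screen(sort(sample.int(N, n)), total = N)
}
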