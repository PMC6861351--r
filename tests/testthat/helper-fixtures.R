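# Shared fixtures and independent oracles.

# The published three-way concordance of the 488-participant cotinine
# subset, as per-participant call vectors (questionnaire / cotinine / CpG
# model; 1 = called smoker). Cell counts: 340 non-smokers and 75 smokers by
# all three methods, 12 smokers by questionnaire + CpG model, 30 by
# questionnaire + cotinine, 2 by cotinine + CpG model, 23 by questionnaire
# only, 2 by CpG model only, 4 by cotinine only.
cotinine_subset_calls <- function() {
  cells <- data.frame(
    q = c(0, 1, 1, 1, 0, 1, 0, 0),
    co = c(0, 1, 1, 0, 1, 0, 0, 1),
    m = c(0, 1, 0, 1, 1, 0, 1, 0),
    n = c(340, 75, 30, 12, 2, 23, 2, 4)
  )
  idx <- rep(seq_len(nrow(cells)), cells$n)
  list(
    questionnaire = cells$q[idx],
    cotinine = cells$co[idx],
    cpg = cells$m[idx]
  )
}

# Child-cohort call-count fixtures: probabilities encoding the printed
# numbers of children called smoker (> 0.5) vs non-smoker, labels all
# non-smoker.
children_call_fixture <- function(n_total, n_called_smoker) {
  list(
    probs = c(rep(0.9, n_called_smoker), rep(0.1, n_total - n_called_smoker)),
    labels = rep(0L, n_total)
  )
}

# Brute-force pair-counting AUC oracle (ties half-credited).
auc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# Triple-loop enumeration oracle for the 8-cell concordance partition.
partition_enum <- function(q, co, m) {
  out <- array(0L, c(2, 2, 2))
  for (i in seq_along(q)) {
    out[q[i] + 1, co[i] + 1, m[i] + 1] <- out[q[i] + 1, co[i] + 1, m[i] + 1] + 1L
  }
  out
}

# Small two-group synthetic cohort used across module tests.
quick_params <- function(n = 500, seed = 1L, deltas = c(-0.15, -0.12),
                         n_decoy = 1, noise = 0.3,
                         mix = c(current = 0.3, former = 0.3, never = 0.4)) {
  panel <- cpg_spec(
    cpg_id = sprintf("cgTST%02d", seq_along(deltas)),
    baseline_beta = rep(c(0.7, 0.55), length.out = length(deltas)),
    smoker_delta = deltas,
    reversion_timescale = 10
  )
  synthetic_params(
    n_participants = n, class_mix = mix, cpg_specs = panel,
    n_decoy_cpgs = n_decoy, noise_sd_logit = noise, seed = seed
  )
}
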