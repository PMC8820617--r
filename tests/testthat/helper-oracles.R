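# Independent oracles used across the suite. These deliberately avoid
# the package's own code paths: similarities come from ChemmineR::fpSim
# one molecule at a time, correlations from the raw sum formula, and
# clustering from a literal transcription of the leader rule.

# Pairwise Tanimoto matrix via ChemmineR::fpSim (independent of the
# package's bit-matrix algebra).
oracle_tanimoto <- function(records, kind) {
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(
    stats::setNames(records$smiles, records$id)
  ))
  fpset <- ChemmineR::fingerprintOB(sdf, switch(kind, fp2 = "FP2", maccs = "MACCS"))
  n <- nrow(records)
  s <- matrix(0, n, n, dimnames = list(records$id, records$id))
  for (i in seq_len(n)) {
    s[i, ] <- ChemmineR::fpSim(fpset[i], fpset, method = "Tanimoto", sorted = FALSE)
  }
  diag(s) <- 1
  (s + t(s)) / 2
}

# Literal leader clustering: descending neighbour count, ties by
# ascending id, assign every unassigned molecule within the cutoff.
oracle_leader_cluster <- function(sim, ids, cutoff) {
  n <- length(ids)
  neigh <- sapply(seq_len(n), function(i) sum(sim[i, ] >= cutoff) - 1L)
  ord <- order(-neigh, ids)
  cluster <- rep(NA_integer_, n)
  k <- 0L
  for (i in ord) {
    if (!is.na(cluster[i])) next
    k <- k + 1L
    for (j in seq_len(n)) {
      if (is.na(cluster[j]) && sim[i, j] >= cutoff) cluster[j] <- k
    }
  }
  cluster
}

# Pearson r by the raw-sums formula.
oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# Closed-form confusion-matrix metrics (fractions, not percent).
oracle_metrics <- function(tp, fn, tn, fp) {
  list(
    accuracy = (tp + tn) / (tp + fn + tn + fp),
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    mcc = (tp * tn - fp * fn) /
      sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  )
}

# Valid drug-like fixture molecules (invalid entry removed).
fixture_valid <- function() {
  mols <- fixture_molecules()
  mols[mols$id != "bad_smiles", ]
}

# Small labeled fixture for model tests.
make_fixture <- function(n_per_class = 60, n_noise = 20, effect = 3, seed = 11) {
  gen_descriptor_table(fixture_spec(
    n_active = n_per_class, n_inactive = n_per_class,
    n_informative = 5, n_noise = n_noise, effect_size = effect, seed = seed
  ))
}
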