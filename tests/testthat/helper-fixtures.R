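# Shared fixtures built in code.

# Three methods scored over five systems (per-target AUC values); column
# means 0.580, 0.754, 0.748.
table2_matrix <- function() {
  performance_matrix(cbind(
    A = c(0.60, 0.65, 0.70, 0.45, 0.50),
    B = c(0.81, 0.75, 0.72, 0.69, 0.80),
    C = c(0.74, 0.70, 0.85, 0.70, 0.75)
  ))
}

# The two p-value families tested against a reference method A.
table1_pvalues <- function(list_no) {
  if (list_no == 1) c(B = 0.02, C = 0.005, D = 0.01, E = 0.03, F = 0.008)
  else c(B = 0.01, C = 0.025, D = 0.005, E = 0.03, F = 0.015)
}

# Score fixture with the canonical 8-active / 10-inactive enrichment
# marginals at f = 0.2 (3/8 and 4/8 selected, joint 2/8; joint top-2
# inactive 1/10). Scores are synthetic; only the selection pattern is pinned.
fig3_score_sets <- function() {
  read_score_table(system.file("extdata", "fig3_synthetic_scores.csv",
                               package = "mmcompare"))
}

# Narrative pairwise-verdict fixture for the grouping layout: six methods,
# F > all except E; {E, A, B} mutually equivalent; {D, C} equivalent; B ~ D.
fig8_fixture <- function() {
  labs <- c("F", "E", "A", "B", "D", "C")
  means <- c(F = 0.90, E = 0.85, A = 0.84, B = 0.83, D = 0.80, C = 0.79)
  diffm <- matrix(TRUE, 6, 6, dimnames = list(labs, labs))
  diag(diffm) <- FALSE
  equiv <- rbind(c("F", "E"), c("E", "A"), c("E", "B"), c("A", "B"),
                 c("D", "C"), c("B", "D"))
  for (k in seq_len(nrow(equiv))) {
    diffm[equiv[k, 1], equiv[k, 2]] <- FALSE
    diffm[equiv[k, 2], equiv[k, 1]] <- FALSE
  }
  list(means = means, different = diffm)
}

# Brute-force AUC oracle: explicit double loop over all (active, inactive)
# pairs, ties credited one half.
auc_bruteforce <- function(active, inactive) {
  tot <- 0
  for (a in active) for (i in inactive) {
    tot <- tot + (a > i) + 0.5 * (a == i)
  }
  tot / (length(active) * length(inactive))
}
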