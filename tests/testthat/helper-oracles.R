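# Independent oracles used across the suite. These deliberately take the
# slow, brute-force route and never share code with the implementation.

# Exact two-sided Mann-Whitney p by full enumeration of all C(n1+n2, n1)
# assignments of ranks to group 1 (no ties assumed).
mw_enumeration_p <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(pooled), n1)
  u_all <- apply(combos, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  p_lo <- mean(u_all <= u_obs)
  p_hi <- mean(u_all >= u_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# AUC as the Mann-Whitney concordance proportion, ties counted one half,
# by a double loop over all case-control pairs.
concordance_auc <- function(scores, labels) {
  cases <- scores[labels == 1]
  controls <- scores[labels == 0]
  total <- 0
  for (a in cases) {
    for (b in controls) {
      total <- total + (a > b) + 0.5 * (a == b)
    }
  }
  total / (length(cases) * length(controls))
}

# Hanley-McNeil standard error of an empirical AUC
auc_se <- function(auc, n_pos, n_neg) {
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  sqrt((auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
          (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg))
}

# single log2-dMoM feature drawn binormally for two groups
binormal_feature <- function(n_per_group, loc_rpl, loc_control, sigma, seed) {
  set.seed(seed)
  list(
    x = matrix(c(stats::rnorm(n_per_group, log2(loc_rpl), sigma),
                 stats::rnorm(n_per_group, log2(loc_control), sigma)),
               ncol = 1, dimnames = list(NULL, "marker")),
    y = rep(c(1, 0), each = n_per_group)
  )
}

# minimal valid cohort rows for I/O tests
make_cohort_tbl <- function(ga = c(50L, 63L, 80L),
                            group = c("RPL", "CONTROL", "CONTROL")) {
  n <- length(ga)
  tibble::tibble(
    subject_id = sprintf("P%02d", seq_len(n)),
    group = group, ga_days = ga,
    maternal_age_years = 30, gravidity = 2, parity = 1, prior_losses = 0,
    conc_free_bhcg = 30, conc_pappa = 0.5, conc_plgf = 20
  )
}
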