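# Independent oracles, written as direct transcriptions of the defining
# formulas (loop style, no shared code with the package implementation).

R_VPDB_ORACLE <- 0.0112372

# delta-13C from an atom fraction f.
delta_from_f_oracle <- function(f) {
  r <- f / (1 - f)
  (r / R_VPDB_ORACLE - 1) * 1000
}

# Chao1, classic unless the doubleton count is zero.
chao1_oracle <- function(counts) {
  counts <- counts[counts > 0]
  s <- length(counts)
  f1 <- 0; f2 <- 0
  for (c_i in counts) {
    if (c_i == 1) f1 <- f1 + 1
    if (c_i == 2) f2 <- f2 + 1
  }
  if (f2 > 0) s + f1 * f1 / (2 * f2) else s + f1 * (f1 - 1) / (2 * (f2 + 1))
}

# ACE per the coverage formula, written independently with explicit loops.
ace_oracle <- function(counts, thr = 10) {
  counts <- counts[counts > 0]
  s_ab <- 0; rare <- c()
  for (c_i in counts) {
    if (c_i > thr) s_ab <- s_ab + 1 else rare <- c(rare, c_i)
  }
  if (length(rare) == 0) return(s_ab)
  n_rare <- sum(rare)
  f1 <- sum(rare == 1)
  cov <- 1 - f1 / n_rare
  if (cov == 0) return(chao1_oracle(counts))
  acc <- 0
  for (k in 1:thr) acc <- acc + k * (k - 1) * sum(rare == k)
  g2 <- s_ab_rare <- length(rare) * acc / (cov * n_rare * (n_rare - 1)) - 1
  g2 <- max(0, g2)
  s_ab + length(rare) / cov + f1 / cov * g2
}

# Closed-form simple linear regression (least squares).
lsq_oracle <- function(x, y) {
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  c(intercept = mean(y) - b * mean(x), slope = b)
}

# A small scenario for fast pipeline tests.
fast_scenario <- function(cv = 0, n_rep = 2, seed = 1L) {
  scenario_config(replicate_cv = cv, n_replicates = n_rep,
                  sample_times = c(0, 12, 24), seed = seed)
}
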