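# Shared independent oracles for the statistics module.

toy_table <- function() {
  as.matrix(read.csv(system.file("extdata", "toy_rm_anova.csv",
                                 package = "retorg")))
}

# Independent oracle: explicit sums-of-squares loops.
rm_anova_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  ss_subj <- 0
  for (i in seq_len(n)) ss_subj <- ss_subj + k * (mean(m[i, ]) - grand)^2
  ss_time <- 0
  for (j in seq_len(k)) ss_time <- ss_time + n * (mean(m[, j]) - grand)^2
  ss_tot <- 0
  for (i in seq_len(n)) for (j in seq_len(k))
    ss_tot <- ss_tot + (m[i, j] - grand)^2
  ss_err <- ss_tot - ss_subj - ss_time
  f <- unname((ss_time / (k - 1)) / (ss_err / ((k - 1) * (n - 1))))
  list(F = f, p = unname(pf(f, k - 1, (k - 1) * (n - 1), lower.tail = FALSE)))
}

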