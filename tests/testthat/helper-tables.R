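# Small fixtures built in code.

toy_table <- function(n = 6, p = 3, seed = 1, labels = NULL) {
  vals <- withr::with_seed(seed, matrix(rnorm(n * p), n, p))
  descriptor_table(vals, sprintf("mol%02d", seq_len(n)),
                   sprintf("d%d", seq_len(p)), labels = labels)
}

# Two well-separated Gaussian classes for classifier checks: a direct
# construction independent of the synthetic_data module.
separable_table <- function(n_per_class = 100, p = 5, delta = 4, seed = 1) {
  withr::with_seed(seed, {
    x1 <- matrix(rnorm(n_per_class * p), n_per_class, p)
    x2 <- matrix(rnorm(n_per_class * p), n_per_class, p)
    x2[, 1] <- x2[, 1] + delta
    descriptor_table(rbind(x1, x2),
                     sprintf("mol%03d", seq_len(2 * n_per_class)),
                     sprintf("d%d", seq_len(p)),
                     labels = rep(c("active", "inactive"),
                                  each = n_per_class))
  })
}

scaled_copy <- function(table) apply_scaler(table, fit_scaler(table))
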