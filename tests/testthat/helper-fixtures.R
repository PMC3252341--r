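# Small builders shared across test files.

# Tiny raw cohort with planted effects, cheap enough for unit tests.
tiny_cohort <- function(seed = 1, n_differential = 8, n_up = 3, ...) {
  generate_cohort(synthetic_spec(
    n_cases = 14, n_controls = 16, n_features = 150,
    n_differential = n_differential, n_up = n_up, seed = seed, ...
  ))
}

# Feature x sample matrix with one strongly separating feature; the rest is
# standard normal noise.
separable_matrix <- function(n_per_class = 30, n_features = 50, shift = 10,
                             noise = 1, seed = 5) {
  set.seed(seed)
  n <- 2 * n_per_class
  x <- matrix(stats::rnorm(n_features * n, sd = noise), n_features, n,
              dimnames = list(sprintf("f%03d", seq_len(n_features)),
                              sprintf("s%03d", seq_len(n))))
  lab <- rep(c("case", "control"), each = n_per_class)
  x[1, lab == "case"] <- x[1, lab == "case"] + shift
  list(x = x, labels = lab)
}

# Brute-force Benjamini-Hochberg step-up, straight from the definition.
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    js <- i:m
    adj[o[i]] <- min(1, min(m * p[o[js]] / js))
  }
  adj
}

# Brute-force AUC by pair counting, ties worth 1/2, folded to >= 0.5.
auc_brute <- function(x_case, x_control) {
  wins <- 0
  for (a in x_case) {
    for (b in x_control) {
      wins <- wins + (a > b) + 0.5 * (a == b)
    }
  }
  u <- wins / (length(x_case) * length(x_control))
  max(u, 1 - u)
}
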