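# Shared fixtures, computed once per test session.

.fixture_env <- new.env(parent = emptyenv())

# The study-sized cohort (24 normal / 62 murmur) and its extracted features;
# reused by the structural and classification acceptance tests.
get_cohort_features <- function() {
  if (is.null(.fixture_env$cohort_features)) {
    cohort <- synthesize_cohort(24, 62, seed = 20)
    .fixture_env$cohort_features <- extract_cohort_features(cohort)
  }
  .fixture_env$cohort_features
}

# A linearly separable two-cluster toy set in 10 dimensions.
make_toy_clusters <- function(n_per = 10, sep = 4, seed = 5) {
  set.seed(seed)
  x <- rbind(matrix(stats::rnorm(n_per * 10), n_per),
             matrix(stats::rnorm(n_per * 10, mean = sep / sqrt(10)), n_per))
  list(x = x, y = rep(c(0, 1), each = n_per))
}
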