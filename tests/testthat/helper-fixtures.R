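# Shared fixtures: a small valid schema and a tag-instance generator used by
# the clustering oracle tests.

toy_schema <- function(...) example_schema(...)

# a multiset of counting tags: n_true true molecules, each observed several
# times, a fraction of observations carrying 1-3 substitutions in the random
# bases (so they stay within / just beyond the clustering distance)
random_tag_instance <- function(schema, n_true = 20L, mean_depth = 5L,
                                p_error = 0.3) {
  true <- random_counting_tag(schema$pattern, n_true)
  depth <- 1L + stats::rpois(n_true, mean_depth)
  tags <- rep(true, depth)
  mutate <- which(stats::runif(length(tags)) < p_error)
  free <- which(strsplit(schema$pattern$pattern, "")[[1]] == "N")
  for (i in mutate) {
    s <- strsplit(tags[i], "")[[1]]
    for (p in sample(free, sample(1:3, 1L))) {
      s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1L)
    }
    tags[i] <- paste(s, collapse = "")
  }
  tags
}
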