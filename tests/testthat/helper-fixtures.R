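# Shared fixtures: tiny deterministic trial tables and reduced study/fit
# settings used across test files.

standard_task <- make_standard_task()

# standard schedule with effectively unattainable criteria: sessions always
# run the full six blocks, removing the optional-stopping selection bias
# when measuring an agent's raw accuracy
no_stop_task <- local({
  t <- make_standard_task()
  t$criteria[] <- 1.0
  t
})

# a hand-built single-block trial table for the standard task
tiny_block <- function(n_per_pair = 2L) {
  pairs <- c("AB", "CD", "EF")
  better <- c(AB = "A", CD = "C", EF = "E")
  worse <- c(AB = "B", CD = "D", EF = "F")
  pair <- rep(pairs, each = n_per_pair)
  data.frame(
    subject = "s1", condition = "none", block = 1L,
    trial = seq_along(pair), pair_encounter = rep(seq_len(n_per_pair), 3),
    pair = pair, left = better[pair], right = worse[pair],
    chosen = better[pair], chose_optimal = TRUE,
    feedback = 1L, rt = 0.8, stringsAsFactors = FALSE
  )
}

# a small two-condition synthetic study, cached per session
small_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_study(study_preset("paper_like", n_subjects = 6,
                                            seed = 1))
    cache
  }
})

# reduced sampler settings for fast unit-level fits (short chains trip the
# convergence warning by design; these tests assert other properties)
quick_fit <- function(data, ...) {
  suppressWarnings(
    fit_rlddm(data, draws = 500, burn = 150, chains = 1, seed = 5, ...))
}
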