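# Shared fixtures, built in code. Small enough to keep every file fast.

# A hand-sized hierarchy:        ROOT
#                              /      \
#                            mid1     mid2
#                           /    \   /    \
#                          d1    d2 d3    d4
tiny_dag <- function() {
  disease_dag(child = c("d1", "d2", "d3", "d4", "mid1", "mid2"),
              parent = c("mid1", "mid1", "mid2", "mid2", "ROOT", "ROOT"))
}

tiny_sequences <- function() {
  c(m1 = "ACGACGACGACG", m2 = "ACGACGACGACU",
    m3 = "UUUGGGUUUGGG", m4 = "UUUGGGUUUGGC")
}

tiny_associations <- function() {
  association_table(c("m1", "m2", "m3", "m4", "m1"),
                    c("d1", "d2", "d3", "d4", "d2"),
                    source_tag = "tiny")
}

# Fast encoder for pipeline-level tests.
small_encoder <- function(seed = 1L) {
  encoder_spec(hidden_dims = c(24L, 8L), epochs_pretrain = 20L,
               epochs_finetune = 40L, seed = seed)
}

# Small planted-partition dataset with strong signal, memoized per session.
small_synth <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_mda_data(synth_config(
        n_mirnas = 60L, n_diseases = 30L, n_groups = 3L,
        p_in = 0.5, p_out = 0.02, seed = 42L))
    }
    cache
  }
})

# Random row-stochastic matrix (all rows positive).
random_stochastic <- function(n) {
  P <- matrix(runif(n * n), n, n)
  P / rowSums(P)
}

expect_symmetric_unit_diag <- function(S) {
  expect_true(isSymmetric(unname(S)))
  expect_equal(unname(diag(S)), rep(1, nrow(S)))
  expect_true(all(S >= 0 & S <= 1))
}
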