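test_that("state space has 2NK states with consistent accessors", {
  msa <- random_gapped_alignment(2L, 10L)
  cfg <- model_config(mu = 1e-3, rates = c(0.01, 0.05, 0.1))
  sp <- build_state_space(msa, cfg)
  expect_equal(sp$n_states, 12L)
  expect_equal(sum(!sp$chimeric), 6L)
  expect_equal(sum(sp$chimeric), 6L)

  set.seed(41)
  for (rep in 1:5) {
    N <- sample.int(10L, 1L); K <- sample.int(10L, 1L)
    m <- random_gapped_alignment(N, 5L)
    cfgk <- model_config(mu = if (K == 1) 0 else 1e-3,
                         rates = seq(0.01, 0.2, length.out = K))
    spk <- build_state_space(m, cfgk)
    i <- sample.int(spk$n_states, 1L)
    expect_length(R_states(spk, i), K)
    expect_length(Rstar_states(spk, i), 2L * K)
    expect_equal(state_index(spk, spk$ref[i], spk$rate_class[i],
                             spk$chimeric[i]), i)
  }
  expect_equal(psi_star(sp, c(1L, 7L), 1e-4), c(0, 1e-4))
})

test_that("emission law: match 1-m, mismatch m/3, neutral 1, reference gap m/3", {
  expect_equal(emission_prob("A", "A", 0.005), 0.995)
  expect_equal(emission_prob("A", "C", 0.03), 0.01)
  expect_equal(emission_prob("G", "-", 0.9), 1)
  expect_equal(emission_prob("G", "N", 0.3), 1)
  expect_equal(emission_prob("-", "A", 0.03), 0.01)
  expect_error(emission_prob("X", "A", 0.1), "state_nt")
  expect_error(emission_prob("A", "Z", 0.1), "obs")
})

test_that("transition law matches the structured form and rows sum to 1", {
  msa <- random_gapped_alignment(50L, 5L)
  cfg <- model_config(psi = 1e-4, mu = 1e-3, rates = seq(0, 0.25, length.out = 15))
  sp <- build_state_space(msa, cfg)
  expect_equal(transition_prob(1L, 1L, sp, cfg), 0.9989)
  # into a chimeric state of a different reference: psi / ((N-1)K)
  j <- state_index(sp, 2L, 1L, chimeric = TRUE)
  expect_equal(transition_prob(1L, j, sp, cfg), 1e-4 / 735)
  # into a non-chimeric state of a different reference: impossible
  expect_equal(transition_prob(1L, state_index(sp, 2L, 1L, FALSE), sp, cfg), 0)

  set.seed(42)
  for (rep in 1:6) {
    N <- sample.int(6L, 1L); K <- sample.int(4L, 1L)
    m <- random_gapped_alignment(N, 4L)
    cfgk <- model_config(psi = runif(1, 0, 0.05),
                         mu = if (K == 1) 0 else runif(1, 0, 0.05),
                         rates = seq(0.01, 0.2, length.out = K))
    spk <- build_state_space(m, cfgk)
    S <- spk$n_states
    A <- outer(seq_len(S), seq_len(S),
               function(i, j) transition_prob(i, j, spk, cfgk))
    expect_true(all(abs(rowSums(A) - 1) < 1e-12))
  }
})

test_that("chimeric posterior is exactly zero when chimeras are unreachable", {
  msa1 <- as_reference_msa(c(solo = "ACGTACGTAC"))
  cfg <- model_config(psi = 1e-3, mu = 1e-3, rates = c(0.01, 0.1))
  f <- forward_linear(random_obs(10L), msa1, cfg)
  expect_identical(f$posterior, 0)
  expect_identical(f$log_chimeric_mass, -Inf)

  msa2 <- diverged_pair_msa()
  cfg0 <- model_config(psi = 0, mu = 1e-3, rates = c(0.01, 0.1))
  q <- paste0(substr(msa2$seqs[1], 1, 10), substr(msa2$seqs[2], 11, 20))
  expect_identical(forward_linear(q, msa2, cfg0)$posterior, 0)
})

test_that("linear forward matches the dense quadratic oracle", {
  set.seed(1234)
  for (rep in 1:60) {
    inst <- random_instance()
    f1 <- forward_linear(inst$obs, inst$msa, inst$config)
    f2 <- forward_quadratic_oracle(inst$obs, inst$msa, inst$config)
    expect_lt(abs(f1$log_evidence - f2$log_evidence),
              1e-10 * max(1, abs(f2$log_evidence)))
    expect_lt(abs(f1$posterior - f2$posterior), 1e-10)
    # scale factors multiply to the likelihood and never exceed 1
    expect_true(all(f1$scale_factors <= 1 + 1e-12))
    expect_equal(sum(log(f1$scale_factors)), f1$log_evidence)
  }
})

test_that("an obvious two-parent chimera gets posterior near 1", {
  msa <- diverged_pair_msa()
  cfg <- model_config(psi = 1e-4, mu = 1e-3, rates = c(0.005, 0.05, 0.1))
  q <- paste0(substr(msa$seqs[1], 1, 10), substr(msa$seqs[2], 11, 20))
  f <- forward_linear(q, msa, cfg)
  expect_gt(f$posterior, 0.999)
  expect_lte(f$log_chimeric_mass, f$log_evidence)
  # the same construction through the oracle agrees
  expect_gt(forward_quadratic_oracle(q, msa, cfg)$posterior, 0.999)
})

test_that("posterior of a non-chimeric query is non-decreasing in psi", {
  set.seed(9)
  msa <- random_gapped_alignment(4L, 40L)
  q <- mutate_sequence(msa$seqs[2], 0.05)
  post <- vapply(c(1e-6, 1e-5, 1e-4, 1e-3, 1e-2), function(psi) {
    forward_linear(q, msa, model_config(psi = psi, mu = 1e-3,
                                        rates = c(0.01, 0.1)))$posterior
  }, numeric(1))
  expect_true(all(diff(post) >= -1e-15))
})

test_that("per-column operation count grows linearly in the state count", {
  L <- 30L
  ops <- vapply(c(2L, 4L, 8L), function(N) {
    msa <- random_gapped_alignment(N, L, gap_prob = 0)
    cfg <- model_config(mu = 1e-3, rates = c(0.01, 0.1))
    forward_linear(random_obs(L), msa, cfg)$n_ops
  }, numeric(1))
  expect_equal(ops[2] / ops[1], 2)
  expect_equal(ops[3] / ops[2], 2)
})

test_that("linear Viterbi matches dense Viterbi and reports clean segments", {
  set.seed(77)
  for (rep in 1:40) {
    inst <- random_instance()
    v1 <- viterbi_linear(inst$obs, inst$msa, inst$config)
    v2 <- vchimera:::viterbi_dense(inst$obs, inst$msa, inst$config)
    expect_identical(v1$path, as.integer(v2$path))
    expect_equal(v1$log_path_prob, v2$log_path_prob, tolerance = 1e-12)
    # best single path never beats the total evidence
    f <- forward_linear(inst$obs, inst$msa, inst$config)
    expect_lte(v1$log_path_prob, f$log_evidence + 1e-9)
    # segments tile 1..L
    segs <- v1$segments
    expect_equal(segs$start[1], 1L)
    expect_equal(segs$end[nrow(segs)], inst$msa$L)
    if (nrow(segs) > 1L)
      expect_equal(segs$start[-1L], segs$end[-nrow(segs)] + 1L)
    # determinism
    expect_identical(v1$path, viterbi_linear(inst$obs, inst$msa, inst$config)$path)
  }
})

test_that("Viterbi explains an unmutated reference as one segment, no breakpoints", {
  msa <- diverged_pair_msa()
  cfg <- model_config(psi = 1e-4, mu = 1e-3, rates = c(0, 0.05, 0.1))
  v <- viterbi_linear(msa$seqs[1], msa, cfg)
  expect_equal(nrow(v$segments), 1L)
  expect_equal(v$segments$reference, "a")
  expect_equal(v$segments$rate_class, 1L)  # lowest-rate class
  expect_equal(v$segments[, c("start", "end")],
               data.frame(start = 1L, end = msa$L))
  expect_length(v$breakpoints, 0L)
})

test_that("Viterbi breakpoint lands at the junction when parents are fully diverged", {
  msa <- antipodal_msa(24L)
  cfg <- model_config(psi = 1e-3, mu = 0, rates = 0.01)
  # both segments >= 2 columns: a 1-column foreign tail is cheaper to explain
  # as a point mismatch than as a template switch, and rightly so
  for (bp in c(3L, 9L, 17L, 23L)) {
    q <- paste0(strrep("A", bp - 1L), strrep("C", 24L - bp + 1L))
    v <- viterbi_linear(q, msa, cfg)
    expect_equal(v$breakpoints, bp)
    expect_equal(v$segments$reference, c("a", "b"))
  }
})

test_that("chimera calls use the >= threshold convention", {
  cfg <- model_config(threshold = 0.95)
  expect_true(chimera_call(list(posterior = 0.951), cfg))
  expect_false(chimera_call(list(posterior = 0.949), cfg))
  expect_true(chimera_call(list(posterior = 0.95), cfg))
})
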