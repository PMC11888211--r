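# Fixtures are built in code; nothing is read from disk except what a test
# itself writes to tempfiles.

tiny_msa <- function() as_reference_msa(c(a = "ACGT", b = "A-GT"))

# two references differing at every column
antipodal_msa <- function(L = 20L) {
  as_reference_msa(c(a = strrep("A", L), b = strrep("C", L)))
}

diverged_pair_msa <- function() {
  as_reference_msa(c(a = "ACGTACGTACGTACGTACGT",
                     b = "TGCATGCATGCATGCATGCA"))
}

random_gapped_alignment <- function(N, L, gap_prob = 0.08) {
  seqs <- replicate(N, paste(
    sample(c("A", "C", "G", "T", "-"), L, replace = TRUE,
           prob = c(rep((1 - gap_prob) / 4, 4), gap_prob)), collapse = ""))
  # ensure no all-gap row
  seqs <- vapply(seqs, function(s) {
    if (!grepl("[ACGT]", s)) sub("-", "A", s) else s
  }, character(1L))
  as_reference_msa(setNames(seqs, paste0("r", seq_len(N))))
}

random_obs <- function(L, neutral_prob = 0.1) {
  sample(c("A", "C", "G", "T", "-", "N"), L, replace = TRUE,
         prob = c(rep((1 - neutral_prob) / 4, 4), neutral_prob / 2,
                  neutral_prob / 2))
}

random_instance <- function(nmax = 5L, kmax = 3L, lmax = 50L) {
  N <- sample.int(nmax, 1L)
  K <- sample.int(kmax, 1L)
  L <- sample(10:lmax, 1L)
  msa <- random_gapped_alignment(N, L)
  mu <- if (K == 1L) 0 else runif(1, 0, 0.02)
  cfg <- model_config(psi = runif(1, 1e-5, 0.05), mu = mu,
                      rates = sort(sample(seq(0.002, 0.3, by = 0.002), K)))
  list(msa = msa, config = cfg, obs = random_obs(L))
}

# dense scaled backward pass, independent of the C++ path
dense_backward <- function(obs, msa, config, scale_factors) {
  space <- build_state_space(msa, config)
  S <- space$n_states
  A <- outer(seq_len(S), seq_len(S),
             function(i, j) transition_prob(i, j, space, config))
  rm <- vchimera:::rates_matrix(config, msa$N)
  m_of_state <- rm[cbind(space$ref, space$rate_class)]
  obs_codes <- vchimera:::encode_obs(obs)
  emis_col <- function(t) {
    if (obs_codes[t] == 4L) return(rep(1, S))
    refc <- msa$codes[space$ref, t]
    ifelse(refc == obs_codes[t], 1 - m_of_state, m_of_state / 3)
  }
  beta <- matrix(0, msa$L, S)
  beta[msa$L, ] <- 1
  for (t in rev(seq_len(msa$L - 1L))) {
    beta[t, ] <- as.vector(A %*% (emis_col(t + 1L) * beta[t + 1L, ])) /
      scale_factors[t + 1L]
  }
  beta
}

write_airr_tsv <- function(dt, path = tempfile(fileext = ".tsv")) {
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  path
}

# a minimal one-row AIRR record
airr_record <- function(id = "q1", v_call = "a", seq_aln, germ_aln,
                        start = 1L, end = NULL) {
  if (is.null(end))
    end <- start + nchar(gsub("-", "", germ_aln)) - 1L
  data.table::data.table(
    sequence_id = id, v_call = v_call,
    v_sequence_alignment = seq_aln, v_germline_alignment = germ_aln,
    v_germline_start = start, v_germline_end = end)
}
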