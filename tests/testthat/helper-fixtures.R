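# Small fixtures built in code.

toy_ps_matrix <- function(n_ps = 6, n_samples = 4, seed = 42,
                          with_p = TRUE) {
  set.seed(seed)
  m <- matrix(rnorm(n_ps * n_samples, 8, 1), n_ps, n_samples,
              dimnames = list(sprintf("PS%07d", seq_len(n_ps)),
                              sprintf("s%02d", seq_len(n_samples))))
  p <- if (with_p) {
    pm <- matrix(runif(n_ps * n_samples, 1e-6, 1), n_ps, n_samples,
                 dimnames = dimnames(m))
    pm
  } else NULL
  ps_matrix(m, p)
}

toy_annotation <- function(n_genes = 2, ps_per_gene = 3) {
  n <- n_genes * ps_per_gene
  ps_annotation(data.frame(
    probeset_id = sprintf("PS%07d", seq_len(n)),
    transcript_cluster_id = rep(sprintf("TC%05d", seq_len(n_genes)),
                                each = ps_per_gene),
    ordinal = rep(seq_len(ps_per_gene) - 1L, n_genes),
    evidence = "core",
    stringsAsFactors = FALSE))
}

# independent brute-force evaluation of the three window contrasts,
# written from the contrast definitions, not via the package internals
oracle_window <- function(d) {
  step <- (d[1] + d[2]) / 2 - (d[3] + d[4]) / 2
  bump <- (d[2] + d[3]) / 2 - (d[1] + d[4]) / 2
  spike <- d[2] - (d[1] + d[3] + d[4]) / 3
  c(step, bump, spike)
}

oracle_dsiT <- function(delta) {
  L <- length(delta)
  out <- rep(NA_real_, L)
  for (n in seq_len(L - 3)) {
    out[n] <- sum(abs(oracle_window(delta[n:(n + 3)])))
  }
  out
}

# brute-force two-sided Fisher p by hypergeometric enumeration on a 2x2
# table given as (a, b, c, d) = (q_in, q_out, rest_in, rest_out)
oracle_fisher_p <- function(a, b, c_, d) {
  K <- a + c_              # category size
  nq <- a + b              # query size
  N <- a + b + c_ + d
  x <- max(0, K + nq - N):min(K, nq)
  probs <- dhyper(x, K, N - K, nq)
  p_obs <- dhyper(a, K, N - K, nq)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
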