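# shared fixture builders; everything is generated in code, no stored data

# tiny expression matrix with explicit values
tiny_matrix <- function(values, scale = "normalized", annotation = NULL) {
  expression_matrix(values, scale = scale, annotation = annotation)
}

# a DEResult-shaped data.frame built directly (for signature-selection
# tests that need full control over ranks and symbols)
fake_de <- function(probeset_id, symbol, p, t, direction, q = p) {
  de <- data.frame(probeset_id = probeset_id, symbol = symbol,
                   beta = ifelse(direction == "FNE-up", 1, -1) * abs(t),
                   v = 1, s2 = 1, df = 2, s2_post = 1, t = t, df_total = 6,
                   p = p, q = q, direction = direction,
                   stringsAsFactors = FALSE)
  class(de) <- c("DEResult", "data.frame")
  de
}

# balanced 10-probeset signature SIG01..SIG10, +1 for the first five
balanced_signature <- function(k = 5L) {
  signature_set(sprintf("SIG%02d_at", seq_len(2 * k)),
                sprintf("GENE%02d", seq_len(2 * k)),
                rep(c(1L, -1L), each = k))
}

# raw intensities under an additive+multiplicative error model:
# y = a_s + b_s * mu_g * exp(eta) + eps
raw_two_noise_matrix <- function(G = 2000, arrays = 4, a = NULL, b = NULL,
                                 sd_mult = 0.1, sd_add = 30, seed = 1) {
  set.seed(seed)
  if (is.null(a)) a <- seq(0, 50, length.out = arrays)
  if (is.null(b)) b <- seq(1, 1.6, length.out = arrays)
  mu <- exp(rnorm(G, 6, 1.5))
  y <- sapply(seq_len(arrays), function(s) {
    a[s] + b[s] * mu * exp(rnorm(G, 0, sd_mult)) + rnorm(G, 0, sd_add)
  })
  rownames(y) <- sprintf("PS%05d_at", seq_len(G))
  colnames(y) <- sprintf("array%d", seq_len(arrays))
  expression_matrix(y, scale = "raw")
}

# shared-variance two-component normal log-likelihood on a grid (oracle)
grid_mixture_loglik <- function(x, n_pi = 9, n_mu = 25, n_sigma = 15) {
  pis <- seq(0.1, 0.9, length.out = n_pi)
  mus <- seq(min(x), max(x), length.out = n_mu)
  sds <- seq(sd(x) / 10, sd(x) * 1.5, length.out = n_sigma)
  best <- -Inf
  for (p1 in pis) for (m1 in mus) for (m2 in mus) for (s in sds) {
    ll <- sum(log((1 - p1) * dnorm(x, m1, s) + p1 * dnorm(x, m2, s)))
    if (ll > best) best <- ll
  }
  best
}
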