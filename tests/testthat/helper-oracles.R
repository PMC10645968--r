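# Brute-force re-derivation of Duncan significance with the containment
# rule, written against the definition rather than the implementation.
duncan_bruteforce <- function(means, n, mse, df, alpha = 0.05) {
  k <- length(means)
  ord <- order(means, decreasing = TRUE)
  m <- means[ord]
  sig <- matrix(FALSE, k, k)
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    span <- j - i + 1
    Rp <- qtukey((1 - alpha)^(span - 1), span, df) * sqrt(mse / n)
    sig[i, j] <- (m[i] - m[j]) > Rp
  }
  # protection: a pair inside any non-significant wider range is declared
  # non-significant
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    if (sig[i, j]) {
      for (a in 1:i) for (b in j:k) {
        if ((a < i || b > j)) {
          span <- b - a + 1
          Rp <- qtukey((1 - alpha)^(span - 1), span, df) * sqrt(mse / n)
          if ((m[a] - m[b]) <= Rp) sig[i, j] <- FALSE
        }
      }
    }
  }
  list(means_sorted = m, significant = sig)
}
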