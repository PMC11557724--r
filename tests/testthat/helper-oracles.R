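# Naive two-pass oracle implementations of the inequality indices, kept
# deliberately independent of the package's vectorised code paths.
naive_gei <- function(b, alpha = 2) {
  n <- length(b)
  mu <- 0
  for (x in b) mu <- mu + x / n
  acc <- 0
  for (x in b) acc <- acc + ((x / mu)^alpha - 1)
  acc / (n * alpha * (alpha - 1))
}

naive_between <- function(b, g, alpha = 2) {
  n <- length(b)
  mu <- mean(b)
  acc <- 0
  for (lv in unique(g)) {
    bg <- b[g == lv]
    acc <- acc + length(bg) / (n * alpha * (alpha - 1)) *
      ((mean(bg) / mu)^alpha - 1)
  }
  acc
}
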