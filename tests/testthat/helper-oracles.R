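# brute-force reimplementation of the coiled-coil window/register scan,
# kept naive on purpose: explicit loops, geometric mean via prod()^(1/w)
brute_coils <- function(seq, params) {
  res <- strsplit(seq, "")[[1]]
  n <- length(res); w <- params$window
  p <- params$propensity
  get_p <- function(r, h) if (r %in% rownames(p)) p[r, h] else 1
  if (n < w) return(list(prob = numeric(n), score = numeric(n)))
  score <- numeric(n)
  for (i in 1:(n - w + 1L)) {
    best <- 0
    for (reg in 0:6) {
      vals <- vapply(0:(w - 1L), function(k) {
        h <- ((i + k + reg - 1L) %% 7L) + 1L
        get_p(res[i + k], h)
      }, numeric(1))
      best <- max(best, prod(vals)^(1 / w))
    }
    rng <- i:(i + w - 1L)
    score[rng] <- pmax(score[rng], best)
  }
  fcc <- stats::dnorm(score, params$cc_stats[["mean"]], params$cc_stats[["sd"]])
  fg <- stats::dnorm(score, params$g_stats[["mean"]], params$g_stats[["sd"]])
  prob <- fcc / (fcc + params$g_weight * fg)
  prob[score == 0] <- 0
  list(prob = prob, score = score)
}
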