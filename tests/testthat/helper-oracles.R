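# Independent brute-force oracles, kept deliberately naive and separate
# from the package implementation paths they check.

# approximate entropy straight from the definition: explicit template
# matrices, Chebyshev distance, self-matches included
oracle_apen <- function(x, m, r) {
  n <- length(x)
  phi <- function(mm) {
    nt <- n - mm + 1
    tmpl <- sapply(seq_len(nt), function(i) x[i:(i + mm - 1)])
    tmpl <- matrix(tmpl, nrow = mm)
    cnt <- sapply(seq_len(nt), function(i) {
      sum(sapply(seq_len(nt), function(j) {
        max(abs(tmpl[, i] - tmpl[, j])) <= r
      }))
    })
    mean(log(cnt / nt))
  }
  phi(m) - phi(m + 1)
}

# the ten window statistics from textbook formulas
oracle_stats <- function(x) {
  pop_sd <- sqrt(sum((x - mean(x))^2) / length(x))
  c(mean = mean(x),
    std = pop_sd,
    rms = sqrt(sum(x^2) / length(x)),
    amplitude = (max(x) - min(x)) / 2,
    max = max(x),
    min = min(x),
    range = max(x) - min(x),
    apen = if (pop_sd == 0) 0 else oracle_apen(x, 2, 0.2 * pop_sd),
    median = stats::median(x),
    iqr = unname(stats::quantile(x, 0.75) - stats::quantile(x, 0.25)))
}

# regression metrics from their definitions
oracle_metrics <- function(truth, pred, divisor) {
  c(r2 = 1 - sum((truth - pred)^2) / sum((truth - mean(truth))^2),
    r = stats::cor(truth, pred),
    mae = mean(abs(truth - pred)),
    nmae = mean(abs(truth - pred)) / divisor,
    rmse = sqrt(mean((truth - pred)^2)),
    nrmse = sqrt(mean((truth - pred)^2)) / divisor)
}
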