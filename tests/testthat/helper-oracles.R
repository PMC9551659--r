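# Independent brute-force oracles used to check the package implementations.
# These deliberately use plain loops and textbook formulas, not the code
# paths under test.

# Running-sum enrichment score of one set for one expression vector:
# walk the genes from highest to lowest expression; in-set steps add
# rank^alpha (normalized over in-set weights), out-of-set steps subtract
# 1 / n_out; the score is the sum of the running values.
oracle_ssgsea_one <- function(expr_vec, set_idx, alpha) {
  n <- length(expr_vec)
  r <- rank(expr_vec, ties.method = "average")
  ord <- order(expr_vec, decreasing = TRUE)
  w <- r^alpha
  w_in_total <- sum(w[set_idx])
  n_out <- n - length(set_idx)
  running <- 0
  total <- 0
  for (g in ord) {
    if (g %in% set_idx) running <- running + w[g] / w_in_total
    else running <- running - 1 / n_out
    total <- total + running
  }
  unname(total)
}

# Plain silhouette under a supplied distance matrix.
oracle_silhouette <- function(d, labels) {
  labels <- as.character(labels)
  n <- length(labels)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels[i]
    mates <- setdiff(which(labels == own), i)
    if (length(mates) == 0L) { s[i] <- 0; next }
    a <- mean(d[i, mates])
    b <- Inf
    for (g in setdiff(unique(labels), own))
      b <- min(b, mean(d[i, labels == g]))
    s[i] <- (b - a) / max(a, b)
  }
  s
}

# Two-group log-rank by direct O - E / V accumulation at each event time.
oracle_logrank_2g <- function(time, event, group) {
  group <- as.integer(factor(group))
  stopifnot(all(group %in% 1:2))
  u <- 0; v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at <- time >= t
    n <- sum(at); n1 <- sum(at & group == 1)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & group == 1)
    u <- u + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  u^2 / v
}

# Product-limit estimator by explicit loop over distinct event times.
oracle_km <- function(time, event) {
  s <- 1
  out <- numeric(0)
  for (t in sort(unique(time[event == 1]))) {
    n_risk <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / n_risk)
    out <- c(out, s)
  }
  out
}

# Textbook Pearson correlation.
oracle_pearson <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

rand_expr <- function(n_genes, n_samples, seed, prefix = "G") {
  set.seed(seed)
  matrix(rnorm(n_genes * n_samples), n_genes, n_samples,
         dimnames = list(paste0(prefix, seq_len(n_genes)),
                         paste0("S", seq_len(n_samples))))
}

write_tsv_fixture <- function(df, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  write.table(df, path, sep = if (ext == ".csv") "," else "\t",
              quote = FALSE, row.names = FALSE)
  path
}
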