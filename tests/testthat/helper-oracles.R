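# Independent brute-force oracles, written against the definitions (pair
# counting, cross-tables) rather than the package's matrix algebra.

# overall agreement: loop over items and all rater pairs
oracle_po <- function(calls) {
  calls <- as.matrix(calls)
  n <- ncol(calls)
  agree <- apply(calls, 1, function(r) {
    tot <- 0L
    hits <- 0L
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      tot <- tot + 1L
      if (r[i] == r[j]) hits <- hits + 1L
    }
    hits / tot
  })
  mean(agree)
}

# Cohen's kappa from the explicit 2-rater cross-table
oracle_cohen <- function(calls, categories) {
  tab <- table(factor(calls[, 1], levels = categories),
               factor(calls[, 2], levels = categories))
  N <- sum(tab)
  p_o <- sum(diag(tab)) / N
  p_e <- sum((rowSums(tab) / N) * (colSums(tab) / N))
  if (p_e >= 1 - 1e-12) return(NA_real_)
  (p_o - p_e) / (1 - p_e)
}

# Fleiss' kappa from first principles
oracle_fleiss <- function(calls, categories) {
  calls <- as.matrix(calls)
  N <- nrow(calls); n <- ncol(calls)
  counts <- sapply(categories, function(l) rowSums(calls == l))
  counts <- matrix(counts, nrow = N)
  P_i <- (rowSums(counts^2) - n) / (n * (n - 1))
  p_j <- colSums(counts) / (N * n)
  P_e <- sum(p_j^2)
  if (P_e >= 1 - 1e-12) return(NA_real_)
  (mean(P_i) - P_e) / (1 - P_e)
}

oracle_randolph <- function(calls, k) {
  (oracle_po(calls) - 1 / k) / (1 - 1 / k)
}

# hand-coded truth table for the 3-panelist consensus: map each call,
# take any 2/3 majority, otherwise indeterminate
oracle_rpd_consensus <- function(c1, c2, c3) {
  mp <- c(none = "SIRS", possible = "indeterminate",
          probable = "sepsis", definite = "sepsis")
  v <- c(mp[[c1]], mp[[c2]], mp[[c3]])
  tb <- sort(table(v), decreasing = TRUE)
  if (tb[1] >= 2) names(tb)[1] else "indeterminate"
}

# small convenience: two-rater rating matrix over the diagnosis scale
rm2 <- function(a, b) {
  rating_matrix(cbind(as.character(a), as.character(b)),
                categories = category_levels())
}
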