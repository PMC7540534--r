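# Independent oracles used by dual-route checks.  These deliberately use
# brute force / closed forms, never package code paths.

# Exact two-sided Mann-Whitney p-value by full enumeration of all
# choose(nx+ny, nx) group assignments (tie-free data only).
wilcoxon_exact_enum <- function(x, y) {
  nx <- length(x)
  pool <- c(x, y)
  r <- rank(pool)
  cmb <- utils::combn(length(pool), nx)
  Us <- apply(cmb, 2, function(ix) sum(r[ix]) - nx * (nx + 1) / 2)
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  min(1, 2 * min(mean(Us <= u), mean(Us >= u)))
}

# Pearson chi-square statistic by the closed form sum((O-E)^2/E).
chisq_closed_form <- function(O) {
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  sum((O - E)^2 / E)
}
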