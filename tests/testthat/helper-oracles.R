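# Independent oracles, written from first principles and kept deliberately
# separate from the package's implementations.

# Step-up FDR adjustment, literal definition: sort p ascending, q_(i) =
# min_{j >= i} m * p_(j) / j (capped at 1), un-sort.
bh_brute <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(m)
  for (i in seq_len(m)) {
    cand <- vapply(i:m, function(j) m * ps[j] / j, 0)
    q[i] <- min(1, min(cand))
  }
  out <- numeric(m)
  out[ord] <- q
  out
}

# Upper-tail hypergeometric P(X >= x) by direct summation of point masses.
hyper_brute <- function(N, K, n, x) {
  hi <- min(K, n)
  if (x > hi) return(0)
  i <- max(x, max(0, n - (N - K))):hi
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Median-of-ratios size factors by explicit loops.
sf_brute <- function(mat) {
  all_pos <- apply(mat > 0, 1, all)
  geo <- apply(mat[all_pos, , drop = FALSE], 1, function(r) exp(mean(log(r))))
  vapply(seq_len(ncol(mat)), function(s) {
    stats::median(mat[all_pos, s] / geo)
  }, 0)
}

rollup_of <- c(P1 = "additive", P2 = "additive", P3 = "HPD", P4 = "HPD",
               P5 = "LPD", P6 = "LPD", P7 = "UOD", P8 = "UOD", P9 = "UOD",
               P10 = "DOD", P11 = "DOD", P12 = "DOD", NC = "none")

# Small deterministic trio fixture: 6 genes x (2+2+2) samples.
make_tiny_trio <- function() {
  m <- matrix(c(
    10, 12, 100, 110, 50, 55,
    200, 180, 210, 190, 205, 195,
    0, 0, 0, 0, 0, 0,
    30, 35, 30, 28, 120, 130,
    80, 75, 20, 22, 82, 78,
    5, 6, 5, 7, 6, 5), nrow = 6, byrow = TRUE,
    dimnames = list(paste0("g", 1:6), NULL))
  trio_counts(m, roles = rep(c("parent_female", "parent_male", "f1"), each = 2))
}

tiny_lengths <- function(x) {
  stats::setNames(rep(1000, nrow(x$counts)), rownames(x$counts))
}

write_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
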