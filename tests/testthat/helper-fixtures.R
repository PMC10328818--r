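# small in-code fixtures and independent brute-force oracles

tiny_count_table <- function(counts = rbind(c(1, 2), c(0, 3), c(4, 0)),
                             ids = c("s1", "s2"),
                             genera = c("Bifidobacterium", "Bacteroides",
                                        "Escherichia")) {
  count_table(counts,
              data.frame(taxon_id = genera, rank = "genus",
                         family = paste0(genera, "aceae")),
              ids)
}

tiny_metadata <- function(n = 6, timepoint = "3w", role = "infant") {
  df <- data.frame(
    sample_id = sprintf("s%d", seq_len(n)),
    subject_id = sprintf("i%d", seq_len(n)),
    family_id = sprintf("f%d", seq_len(n)),
    role = role, timepoint = timepoint,
    grp = rep(c("a", "b"), length.out = n),
    x = seq_len(n) / n)
  sample_metadata(df, data.frame(
    name = c("grp", "x"), type = c("categorical", "numeric"),
    role = c("biological", "biological"), levels = c("a,b", NA)))
}

# all permutations of 1:n (n small), one per row
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    block <- cbind(k, matrix(setdiff(seq_len(n), k)[sub], nrow(sub)))
    out <- rbind(out, block)
  }
  out
}

# brute-force alpha indices from first principles
bf_shannon <- function(x) { p <- x[x > 0] / sum(x); -sum(p * log(p)) }
bf_chao1 <- function(x) {
  s <- sum(x > 0); f1 <- sum(x == 1); f2 <- sum(x == 2)
  s + f1 * (f1 - 1) / (2 * (f2 + 1))
}
bf_pielou <- function(x) bf_shannon(x) / log(sum(x > 0))
bf_skew <- function(x) {
  n <- length(x); m <- mean(x)
  (sum((x - m)^3) / n) / (sqrt(sum((x - m)^2) / (n - 1)))^3
}

# brute-force one-factor PERMANOVA F from raw pairwise distances
bf_onefactor_F <- function(d, g) {
  n <- length(g)
  ss_t <- sum(d[upper.tri(d)]^2) / n
  ss_w <- 0
  for (lev in unique(g)) {
    i <- which(g == lev)
    if (length(i) > 1)
      ss_w <- ss_w + sum(d[i, i][upper.tri(d[i, i])]^2) / length(i)
  }
  a <- length(unique(g))
  ((ss_t - ss_w) / (a - 1)) / (ss_w / (n - a))
}

# brute-force BH step-up
bf_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in m:1) {
    val <- min(prev, p[o[i]] * m / i)
    q[o[i]] <- val
    prev <- val
  }
  q
}

quiet <- function(expr) suppressMessages(suppressWarnings(expr))
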