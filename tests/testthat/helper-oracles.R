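# Independent brute-force oracles, coded directly from the definitions
# and kept free of the package's implementation paths.

# Step-up BH: sort ascending, multiply p_(i) * n / i, running minimum
# from the largest rank down, cap at 1, undo the sort.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  stepped <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(stepped)))
  adj[adj > 1] <- 1
  out <- numeric(n)
  out[o] <- adj
  out
}

# Two-sided Fisher by explicit enumeration of all tables with the
# observed margins, summing point masses computed from log-binomials.
oracle_fisher_two_sided <- function(a, b, cc, d) {
  m <- a + b; n <- cc + d; k <- a + cc
  lo <- max(0, k - n); hi <- min(k, m)
  logmass <- function(x) lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k)
  mass <- exp(vapply(lo:hi, logmass, numeric(1L)))
  p_obs <- exp(logmass(a))
  min(sum(mass[mass <= p_obs * (1 + 1e-7)]), 1)
}

# cOR evaluated straight from the stated formula: per-dimension 2x2
# odds ratios (0.5 added to all cells of a table containing a zero),
# mean, minus the root-mean-square deviation from the mean.
oracle_cor <- function(m, genes, divisor = length(colnames(m))) {
  inS <- rownames(m) %in% genes
  ors <- numeric(ncol(m))
  for (j in seq_len(ncol(m))) {
    a <- sum(m[inS, j] == 1); b <- sum(m[inS, j] == 0)
    cc <- sum(m[!inS, j] == 1); d <- sum(m[!inS, j] == 0)
    if (min(a, b, cc, d) == 0) {
      a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5
    }
    ors[j] <- (a * d) / (b * cc)
  }
  mu <- mean(ors)
  mu - sqrt(sum((ors - mu)^2) / divisor)
}

# Internal-edge count by scanning every edge.
oracle_internal_edges <- function(edges, gene_set) {
  cnt <- 0L
  for (i in seq_len(nrow(edges))) {
    if (edges$from[i] %in% gene_set && edges$to[i] %in% gene_set) {
      cnt <- cnt + 1L
    }
  }
  cnt
}

# Random 2x2 table with margins bounded by max_margin.
random_table2x2 <- function(max_margin = 40) {
  repeat {
    t <- c(sample.int(max_margin + 1L, 2L, replace = TRUE) - 1L,
           sample.int(max_margin + 1L, 2L, replace = TRUE) - 1L)
    if (sum(t) >= 1) return(t)
  }
}

# Small random binary evidence matrix with guaranteed non-degenerate
# columns is handy for optimizer oracle checks.
random_small_matrix <- function(n_genes = 12, n_dims = 3) {
  m <- matrix(rbinom(n_genes * n_dims, 1L, runif(1, 0.2, 0.6)),
              n_genes, n_dims,
              dimnames = list(sprintf("G%02d", seq_len(n_genes)),
                              sprintf("dim%d", seq_len(n_dims))))
  storage.mode(m) <- "integer"
  m
}
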