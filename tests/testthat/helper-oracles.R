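# Independent brute-force oracles used across the suite. Each is written
# from the definition, not from the implementation it checks.

# sup over all pooled evaluation points of |F_x(t) - F_y(t)|
oracle_ks_statistic <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(abs(vapply(pts, function(t) mean(x <= t) - mean(y <= t), numeric(1))))
}

# BH step-up: sort ascending, p(i) * m / i, reverse cumulative minimum,
# clip at 1, restore input order
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  scaled <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(scaled)))
  pmin(adj, 1)[order(ord)]
}

# AUC by enumerating every positive-negative pair; ties count one half
oracle_auc <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# two-sided Fisher exact p by full enumeration of all 2x2 tables with the
# observed margins, summing hypergeometric masses <= the observed mass
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; c1 <- a + c_; n <- a + b + c_ + d
  a_range <- max(0, c1 - (n - r1)):min(r1, c1)
  mass <- dhyper(a_range, c1, n - c1, r1)
  p_obs <- dhyper(a, c1, n - c1, r1)
  sum(mass[mass <= p_obs * (1 + 1e-7)])
}

# interpolated quartile partition via an independent sort-based quantile
oracle_quartiles <- function(v) {
  s <- sort(unname(v)); n <- length(v)
  qat <- function(prob) {
    h <- (n - 1) * prob + 1
    lo <- floor(h); hi <- ceiling(h)
    s[lo] + (h - lo) * (s[hi] - s[lo])
  }
  c(q1 = qat(0.25), q3 = qat(0.75))
}

# tiny deterministic expression fixture
make_expr <- function(values, samples, genes) {
  expression_matrix(matrix(values, length(samples), length(genes),
                           dimnames = list(samples, genes)))
}
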