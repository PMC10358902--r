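# Independent brute-force oracles used to cross-check the package's
# statistical routines. These deliberately avoid the code paths they check.

# Two-sided Fisher exact p by full enumeration over all tables with the
# observed margins, summing probabilities <= the observed table's
# (with the conventional 1 + 1e-7 relative tolerance). 2 x 2 and 2 x 3.
fisher_p_enum <- function(tab) {
  r <- rowSums(tab)
  cs <- colSums(tab)
  n <- sum(tab)
  log_tab_prob <- function(row1) {
    row2 <- cs - row1
    if (any(row2 < 0)) return(-Inf)
    sum(lgamma(r + 1)) + sum(lgamma(cs + 1)) - lgamma(n + 1) -
      sum(lgamma(c(row1, row2) + 1))
  }
  if (ncol(tab) == 2) {
    grid <- expand.grid(a = 0:min(r[1], cs[1]))
    grid$b <- r[1] - grid$a
    keep <- grid$b >= 0 & grid$b <= cs[2]
    rows1 <- as.matrix(grid[keep, c("a", "b")])
  } else {
    grid <- expand.grid(a = 0:min(r[1], cs[1]), b = 0:min(r[1], cs[2]))
    grid$c <- r[1] - grid$a - grid$b
    keep <- grid$c >= 0 & grid$c <= cs[3]
    rows1 <- as.matrix(grid[keep, c("a", "b", "c")])
  }
  logp <- apply(rows1, 1, log_tab_prob)
  obs_logp <- log_tab_prob(tab[1, ])
  sum(exp(logp)[exp(logp) <= exp(obs_logp) * (1 + 1e-7)])
}

# Pearson chi-square on a 2 x 2 table via the closed form
# N (ad - bc)^2 / (r1 r2 c1 c2)
chisq_2x2_closed <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  n <- a + b + c + d
  n * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
}

# One-way ANOVA F from first principles (sums of squares)
anova_f_hand <- function(groups) {
  all_vals <- unlist(groups)
  grand <- mean(all_vals)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - grand)^2,
                    numeric(1)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df1 <- length(groups) - 1
  df2 <- length(all_vals) - length(groups)
  f <- (ssb / df1) / (ssw / df2)
  list(f = f, p = stats::pf(f, df1, df2, lower.tail = FALSE))
}

# Mann-Whitney U (pairs of x > y) by direct enumeration
u_stat_enum <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}
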