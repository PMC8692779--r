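# Independent oracles: brute-force / closed-form implementations used to
# check the package's statistics. Deliberately slow and simple.

# step-up BH from the definition: adj_(i) = min_{j >= i} p_(j) * n / j, capped
oracleBH <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o]
  adj <- numeric(n)
  for (i in seq_len(n)) {
    adj[i] <- min(1, min(ranked[i:n] * n / (i:n)))
  }
  out <- numeric(n)
  out[o] <- adj
  out
}

# exhaustive two-sided rank-sum p by enumerating all assignments of the
# pooled ranks to group a (no ties assumed)
oracleWilcoxExact <- function(a, b) {
  la <- length(a)
  pooled <- c(a, b)
  r <- rank(pooled)
  uObs <- sum(r[seq_len(la)]) - la * (la + 1) / 2
  splits <- utils::combn(length(pooled), la)
  us <- apply(splits, 2L, function(idx) sum(r[idx]) - la * (la + 1) / 2)
  pLow <- mean(us <= uObs)
  pHigh <- mean(us >= uObs)
  list(stat = uObs, p = min(1, 2 * min(pLow, pHigh)))
}

# logistic ML by direct minimization of the negative log-likelihood
oracleLogisticML <- function(X, y) {
  negll <- function(beta) {
    eta <- as.vector(X %*% beta)
    -sum(y * eta - log1p(exp(eta)))
  }
  grad <- function(beta) {
    eta <- as.vector(X %*% beta)
    -as.vector(t(X) %*% (y - stats::plogis(eta)))
  }
  fit <- stats::optim(rep(0, ncol(X)), negll, grad, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-14))
  fit$par
}

# Efron negative log partial likelihood, minimized directly
oracleCoxNegPL <- function(beta, time, event, X) {
  eta <- as.vector(X %*% beta)
  w <- exp(eta)
  nll <- 0
  for (t in unique(sort(time[event == 1]))) {
    d <- which(time == t & event == 1)
    risk <- which(time >= t)
    sumR <- sum(w[risk])
    sumD <- sum(w[d])
    m <- length(d)
    nll <- nll - sum(eta[d]) +
      sum(log(sumR - (seq_len(m) - 1) / m * sumD))
  }
  nll
}

oracleCoxML <- function(time, event, X) {
  X <- as.matrix(X)
  fit <- stats::optim(rep(0, ncol(X)), oracleCoxNegPL, time = time,
                      event = event, X = X, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-14))
  fit$par
}

# two-group log-rank from the observed/expected table with hypergeometric
# variance
oracleLogrank2 <- function(time, event, group) {
  g <- as.integer(factor(group))
  stopifnot(length(unique(g)) == 2L)
  o1 <- 0; e1 <- 0; v <- 0
  for (t in unique(sort(time[event == 1]))) {
    atRisk <- time >= t
    n <- sum(atRisk)
    n1 <- sum(atRisk & g == 1L)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == 1L)
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi2 <- (o1 - e1)^2 / v
  list(chi2 = chi2, p = stats::pchisq(chi2, 1, lower.tail = FALSE))
}

# tie-corrected Kruskal-Wallis H from the rank formula
oracleKW <- function(groups) {
  values <- unlist(groups, use.names = FALSE)
  N <- length(values)
  r <- rank(values)
  sizes <- vapply(groups, length, 1L)
  idx <- split(seq_len(N), rep(seq_along(groups), sizes))
  H <- 12 / (N * (N + 1)) *
    sum(vapply(idx, function(i) length(i) * (mean(r[i]) - (N + 1) / 2)^2, 1.0))
  ties <- table(values)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# Yates chi-square closed form with the clamped correction
oracleYates <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum(pmax(0, abs(tab - E) - 0.5)^2 / E)
}

# upper hypergeometric tail by direct summation
oracleHyperTail <- function(overlap, nCat, nUniverse, nHits) {
  sum(stats::dhyper(overlap:min(nCat, nHits), nCat, nUniverse - nCat, nHits))
}
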