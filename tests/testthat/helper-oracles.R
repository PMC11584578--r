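# Independent brute-force oracles used to validate the package's
# statistical machinery. These deliberately avoid the code paths they check.

# Benjamini-Hochberg by the textbook definition: q_i = min over j with
# p_(j) >= p_(i) of p_(j) * m / j
bruteBH <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# exact two-sided rank-sum p-value by full enumeration of group assignments
exactWilcoxP <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- utils::combn(nx + ny, nx)
  us <- apply(combos, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  min(1, 2 * min(mean(us <= u), mean(us >= u)))
}

# beta-binomial upper tail by numerical integration of the binomial tail
# against the beta mixing density (independent of the lbeta/lchoose path)
bbTailIntegrate <- function(k, n, alpha, beta) {
  if (k <= 0) return(1)
  f <- function(p) stats::dbeta(p, alpha, beta) *
    stats::pbinom(k - 1, n, p, lower.tail = FALSE)
  stats::integrate(f, 0, 1, rel.tol = 1e-10)$value
}

# joint NB log-likelihood maximized directly with a gradient-based
# optimizer, for the spline LRT oracle; design X includes the intercept
# column. log-theta is box-constrained at log(1e6), the same dispersion
# floor the implementation documents.
nbLogLikOpt <- function(y, X, off) {
  nll <- function(par) {
    beta <- par[-length(par)]
    theta <- exp(par[length(par)])
    mu <- exp(as.vector(X %*% beta) + off)
    -sum(stats::dnbinom(y, size = theta, mu = mu, log = TRUE))
  }
  grad <- function(par) {
    beta <- par[-length(par)]
    theta <- exp(par[length(par)])
    mu <- exp(as.vector(X %*% beta) + off)
    gb <- -as.vector(crossprod(X, y - (y + theta) * mu / (mu + theta)))
    gt <- -theta * sum(digamma(y + theta) - digamma(theta) +
                         log(theta) + 1 - log(mu + theta) -
                         (y + theta) / (mu + theta))
    c(gb, gt)
  }
  start <- c(log(mean(y) + 0.5) - mean(off), rep(0, ncol(X) - 1), log(10))
  lower <- rep(-Inf, length(start))
  upper <- c(rep(Inf, ncol(X)), log(1e6))
  fit <- stats::optim(start, nll, grad, method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = list(maxit = 2000, factr = 1))
  fit2 <- stats::optim(fit$par, nll, grad, method = "L-BFGS-B",
                       lower = lower, upper = upper,
                       control = list(maxit = 2000, factr = 1))
  -min(fit$value, fit2$value)
}

# gene-by-cell aggregation of edited UMIs over exonic significant sites,
# written as plain loops
bruteAggregate <- function(k, siteGene, siteExonic, genes, cells) {
  out <- matrix(0, length(genes), length(cells),
                dimnames = list(genes, cells))
  for (i in seq_len(nrow(k))) {
    if (!siteExonic[i]) next
    g <- siteGene[i]
    for (j in seq_len(ncol(k))) out[g, j] <- out[g, j] + k[i, j]
  }
  out
}

# four-part site filter as plain loops over pooled counts
bruteFilter <- function(fdr, k, n, fdrMax = 0.01, lo = 0.05, hi = 0.95,
                       minK = 2, minN = 10) {
  keep <- logical(length(fdr))
  for (i in seq_along(fdr)) {
    f <- if (n[i] > 0) k[i] / n[i] else NA
    keep[i] <- !is.na(f) && fdr[i] < fdrMax && f >= lo && f <= hi &&
      k[i] > minK && n[i] > minN
  }
  keep
}

# brute-force motif scan: test the consensus at every offset, expanding
# IUPAC codes by hand
bruteMotifHit <- function(seq, motif) {
  iupac <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
                Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
                K = c("G", "T"), M = c("A", "C"),
                B = c("C", "G", "T"), D = c("A", "G", "T"),
                H = c("A", "C", "T"), V = c("A", "C", "G"),
                N = c("A", "C", "G", "T"))
  s <- strsplit(seq, "")[[1]]
  m <- strsplit(gsub("U", "T", toupper(motif)), "")[[1]]
  L <- length(m)
  if (length(s) < L) return(FALSE)
  for (off in 0:(length(s) - L)) {
    ok <- TRUE
    for (j in seq_len(L)) {
      if (!s[off + j] %in% iupac[[m[j]]]) { ok <- FALSE; break }
    }
    if (ok) return(TRUE)
  }
  FALSE
}

randomSeqs <- function(n, len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = ""), character(1))
}

dinucCounts <- function(s) {
  ch <- strsplit(s, "")[[1]]
  table(paste0(ch[-length(ch)], ch[-1]))
}
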