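#' Beta-binomial density and tail probability
#'
#' The background editing model: `k ~ BetaBinomial(n, alpha, beta)`, i.e. a
#' binomial whose success probability is Beta-distributed, capturing the
#' extra-binomial dispersion of editing frequencies across sites. The
#' parameterization `mu = alpha/(alpha+beta)`, `rho = 1/(alpha+beta+1)` is
#' used throughout; `rho = 0` degenerates to `Binomial(n, mu)`.
#'
#' @param k,n edited and total counts (vectorized)
#' @param alpha,beta positive shape parameters
#' @param log return log density
#' @return `dbetabinom` the (log-)density; `pbetabinomUpper` the one-sided
#'   tail probability `P(K >= k)`.
#' @export
dbetabinom <- function(k, n, alpha, beta, log = FALSE) {
  ll <- lchoose(n, k) + lbeta(k + alpha, n - k + beta) - lbeta(alpha, beta)
  if (log) ll else exp(ll)
}

#' @rdname dbetabinom
#' @export
pbetabinomUpper <- function(k, n, alpha, beta) {
  mapply(function(ki, ni) {
    if (ni <= 0) return(1)
    ki <- max(0, ki)
    if (ki <= 0) return(1)
    # sum the shorter tail for accuracy and speed
    if (ki - 1 < ni - ki) {
      p <- 1 - sum(dbetabinom(0:(ki - 1), ni, alpha, beta))
      max(p, 0)
    } else {
      sum(dbetabinom(ki:ni, ni, alpha, beta))
    }
  }, k, n)
}

muRhoToAlphaBeta <- function(mu, rho) {
  s <- (1 - rho) / rho
  c(alpha = mu * s, beta = (1 - mu) * s)
}

#' Fit the background editing model on ADAR-only control counts
#'
#' Estimates the beta-binomial parameters of background editing from the
#' control sample: the pooled mean by weighted moments, the overdispersion
#' by a moment start refined by maximum likelihood. When the control shows
#' no extra-binomial dispersion (pooled chi-square dispersion statistic not
#' exceeding its 95% null quantile) the model falls back to a binomial at
#' the pooled rate. A configurable rate floor guards against an all-zero
#' control. With `pooling = "per_site"` a table of per-site means (sharing
#' the global overdispersion) is kept; the site test uses a site's own mean
#' when the control covers it sufficiently and the pooled model otherwise.
#'
#' @param control a calibrated [SiteExperiment-class] of the control sample,
#'   or a data.frame with columns `k` and `n` (rownames used as site keys).
#' @param pooling `"global"` (one model) or `"per_site"`.
#' @param rateFloor minimum admissible mean rate.
#' @param perSiteMinCoverage control coverage above which a site gets its
#'   own background mean.
#' @return a [BackgroundModel-class].
#' @export
fitBackground <- function(control, pooling = c("global", "per_site"),
                          rateFloor = 1e-4, perSiteMinCoverage = 10) {
  pooling <- match.arg(pooling)
  df <- controlCounts(control)
  if (!nrow(df)) stop("empty control table")
  k <- df$k; n <- df$n
  keep <- n > 0
  k <- k[keep]; n <- n[keep]; sites <- rownames(df)[keep]
  if (!length(k)) stop("control has no covered sites")

  mu <- sum(k) / sum(n)
  if (mu <= 0) {
    warning("all-zero control; background set to the rate floor")
    model <- new("BackgroundModel", mu = rateFloor, rho = 0,
                 alpha = Inf, beta = Inf, method = "binomial",
                 rateFloor = rateFloor, pooling = pooling)
    return(addPerSite(model, sites, k, n, perSiteMinCoverage, pooling))
  }
  mu <- max(mu, rateFloor)

  # pooled chi-square dispersion statistic vs its binomial null
  x2 <- sum((k - n * mu)^2 / (n * mu * (1 - mu)))
  m <- length(k)
  overdispersed <- m > 1 && x2 > stats::qchisq(0.95, m - 1)

  if (!overdispersed) {
    model <- new("BackgroundModel", mu = mu, rho = 0, alpha = Inf,
                 beta = Inf, method = "binomial", rateFloor = rateFloor,
                 pooling = pooling)
    return(addPerSite(model, sites, k, n, perSiteMinCoverage, pooling))
  }

  # moment start for rho (equal-n formula applied with mean n), ML refine
  p <- k / n
  s2 <- stats::var(p)
  nbar <- mean(n)
  rho0 <- (nbar * s2 / (mu * (1 - mu)) - 1) / (nbar - 1)
  rho0 <- min(max(rho0, 1e-6), 0.5)

  nll <- function(par) {
    muI <- stats::plogis(par[1]); rhoI <- stats::plogis(par[2])
    ab <- muRhoToAlphaBeta(muI, rhoI)
    -sum(dbetabinom(k, n, ab["alpha"], ab["beta"], log = TRUE))
  }
  fit <- stats::optim(c(stats::qlogis(mu), stats::qlogis(rho0)), nll,
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
  muHat <- max(stats::plogis(fit$par[1]), rateFloor)
  rhoHat <- stats::plogis(fit$par[2])
  ab <- muRhoToAlphaBeta(muHat, rhoHat)
  model <- new("BackgroundModel", mu = muHat, rho = rhoHat,
               alpha = unname(ab["alpha"]), beta = unname(ab["beta"]),
               method = "mom+ml", rateFloor = rateFloor, pooling = pooling)
  addPerSite(model, sites, k, n, perSiteMinCoverage, pooling)
}

controlCounts <- function(control) {
  if (is(control, "SiteExperiment")) {
    k <- Matrix::rowSums(assay(control, "edited"))
    n <- Matrix::rowSums(assay(control, "coverage"))
    data.frame(k = as.vector(k), n = as.vector(n),
               row.names = rownames(control))
  } else {
    stopifnot(all(c("k", "n") %in% colnames(control)))
    as.data.frame(control)
  }
}

addPerSite <- function(model, sites, k, n, minCov, pooling) {
  if (pooling != "per_site") return(model)
  keep <- n > minCov
  model@perSite <- DataFrame(
    site = sites[keep],
    mu = pmax(k[keep] / n[keep], model@rateFloor),
    n = n[keep])
  model
}

#' Test experimental sites against the background model
#'
#' Computes, per site, the one-sided probability that the experimental
#' edited count is at least as large as observed under the control
#' background (beta-binomial upper tail, or binomial when the model carries
#' no overdispersion), pooling counts across columns (replicates or cells).
#' With a per-site model, sites present in the per-site table use their own
#' background mean; all other sites use the pooled model. Benjamini-Hochberg
#' FDR is computed across all tested sites.
#'
#' @param se a calibrated [SiteExperiment-class] of the experimental sample
#' @param model a [BackgroundModel-class] from [fitBackground()]
#' @return `se` with `k`, `n`, `f`, `p`, and `fdr` columns in `rowData`.
#' @export
testSites <- function(se, model) {
  k <- as.vector(Matrix::rowSums(assay(se, "edited")))
  n <- as.vector(Matrix::rowSums(assay(se, "coverage")))
  mu <- rep(model@mu, nrow(se))
  if (model@pooling == "per_site" && nrow(model@perSite)) {
    hit <- match(rownames(se), model@perSite$site)
    mu[!is.na(hit)] <- model@perSite$mu[hit[!is.na(hit)]]
  }
  p <- numeric(nrow(se))
  for (i in seq_len(nrow(se))) {
    if (n[i] == 0) { p[i] <- 1; next }
    if (model@rho > 0) {
      ab <- muRhoToAlphaBeta(mu[i], model@rho)
      p[i] <- pbetabinomUpper(k[i], n[i], ab["alpha"], ab["beta"])
    } else {
      p[i] <- stats::pbinom(k[i] - 1, n[i], mu[i], lower.tail = FALSE)
    }
  }
  rowData(se)$k <- k
  rowData(se)$n <- n
  rowData(se)$f <- ifelse(n > 0, k / n, NA_real_)
  rowData(se)$p <- p
  rowData(se)$fdr <- stats::p.adjust(p, method = "BH")
  se
}
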