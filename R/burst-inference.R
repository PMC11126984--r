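#' Negative-binomial log pmf in the bursting parameterization
#'
#' Log probability mass of the negative binomial stationary law of the
#' bursting model, with size parameter `kon` (burst frequency) and mean
#' `mu`. Writing `b = mu/kon` for the mean burst size,
#' `P(X = x) = Gamma(x + kon) / (Gamma(kon) x!) * (b/(1+b))^x * (1/(1+b))^kon`.
#' Evaluated entirely in log space via `lgamma`, so it does not overflow
#' for counts up to 1e6 and beyond.
#'
#' @param x nonnegative integer count(s).
#' @param mu mean expression (> 0).
#' @param kon burst frequency (> 0).
#' @return Log probability, vectorized over `x`.
#' @examples
#' nb_log_pmf(0, mu = 1, kon = 1)  # log(0.5)
#' @export
nb_log_pmf <- function(x, mu, kon) {
  if (!is.numeric(mu) || !is.numeric(kon) || any(mu <= 0) || any(kon <= 0)) {
    stop("mu and kon must be strictly positive")
  }
  if (any(x < 0) || any(x != round(x))) {
    stop("x must be a nonnegative integer")
  }
  lb <- log(mu) - log(kon)          # log burst size
  l1pb <- log1p(mu / kon)           # log(1 + b)
  lgamma(x + kon) - lgamma(kon) - lgamma(x + 1) + x * (lb - l1pb) - kon * l1pb
}

# Log prior: independent log-uniform on mu and kon over [box_lo, box_hi].
# Uniform in (log mu, log kon), i.e. constant inside the box, -Inf outside.
.prior_box <- c(lo = 1e-4, hi = 1e4)

# Sufficient-statistic form of the NB log likelihood for a whole count
# vector: counts are tabulated once, after which each evaluation costs
# O(#unique values). `const` carries the parameter-free -sum(lgamma(x+1)).
.make_loglik <- function(counts) {
  tab <- table(counts)
  u <- as.numeric(names(tab))
  w <- as.numeric(tab)
  n <- length(counts)
  S <- sum(counts)
  const <- -sum(w * lgamma(u + 1))
  function(lmu, lkon) {
    kon <- exp(lkon)
    l1pb <- log1p(exp(lmu - lkon))
    sum(w * lgamma(u + kon)) - n * lgamma(kon) + const +
      S * (lmu - lkon - l1pb) - n * kon * l1pb
  }
}

#' Fit the bursting model to one gene by Metropolis MCMC
#'
#' Random-walk Metropolis sampling of the posterior of `(log mu, log kon)`
#' under the negative-binomial likelihood ([nb_log_pmf()]) and independent
#' log-uniform priors on `mu` and `kon` over `[1e-4, 1e4]`. Proposals are
#' isotropic Gaussian in log space; the step size is adapted during the
#' first quarter of the chain (targeting ~25 percent acceptance) and then
#' frozen, and the first quarter is discarded as burn-in. The posterior
#' means of `mu`, `kon` and of `CV^2 = 1/mu + 1/kon` over the retained
#' samples are reported, together with the derived burst size
#' `CV^2 * mu - 1`.
#'
#' @param counts raw integer UMI counts of one gene across the QC-passed
#'   cells of one sample; must contain at least one nonzero count.
#' @param n_steps total MCMC steps (default 100000).
#' @param seed optional integer seed; fixed seeds give identical traces.
#' @param keep_trace keep the full chain (log mu, log kon, log posterior,
#'   acceptance indicator)? Default `FALSE` to bound memory across genes.
#' @return List with `estimate` (data frame: mu, kon, cv2, burst_size,
#'   acceptance_rate, n_steps) and, if requested, `trace` (data frame:
#'   log_mu, log_kon, log_post, accepted).
#' @examples
#' x <- sample_nb_counts(mu = 5, kon = 1, n_cells = 500, seed = 1)
#' fit <- fit_gene_mcmc(x, n_steps = 2000, seed = 1)
#' fit$estimate
#' @export
fit_gene_mcmc <- function(counts, n_steps = 1e5, seed = NULL,
                          keep_trace = FALSE) {
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be nonnegative integers")
  }
  if (all(counts == 0)) {
    stop("all-zero gene: bursting inference refused (flag the gene unfit)")
  }
  if (n_steps < 100) stop("n_steps must be at least 100")
  if (!is.null(seed)) set.seed(seed)

  loglik <- .make_loglik(counts)
  box <- log(.prior_box)

  # moment-based start: mu from the sample mean, kon from CV^2 - 1/mu
  mu0 <- mean(counts)
  cv2_hat <- stats::var(counts) / mu0^2
  kon0 <- 1 / max(cv2_hat - 1 / mu0, 1e-2)
  cur <- pmin(pmax(c(log(mu0), log(kon0)), box["lo"] + 1e-8), box["hi"] - 1e-8)
  ll_cur <- loglik(cur[1], cur[2])

  n_adapt <- floor(n_steps / 4)
  n_burn <- floor(n_steps / 4)
  sigma <- 0.5
  adapt_block <- 100L
  block_acc <- 0L

  lmu <- numeric(n_steps); lkon <- numeric(n_steps)
  lpost <- numeric(n_steps); acc <- logical(n_steps)
  for (i in seq_len(n_steps)) {
    prop <- cur + stats::rnorm(2, 0, sigma)
    inside <- prop[1] >= box["lo"] && prop[1] <= box["hi"] &&
      prop[2] >= box["lo"] && prop[2] <= box["hi"]
    if (inside) {
      ll_prop <- loglik(prop[1], prop[2])
      if (log(stats::runif(1)) < ll_prop - ll_cur) {
        cur <- prop; ll_cur <- ll_prop
        acc[i] <- TRUE; block_acc <- block_acc + 1L
      }
    } else {
      stats::runif(1)  # keep the random stream aligned across proposals
    }
    lmu[i] <- cur[1]; lkon[i] <- cur[2]; lpost[i] <- ll_cur
    if (i <= n_adapt && i %% adapt_block == 0L) {
      rate <- block_acc / adapt_block
      sigma <- sigma * exp(rate - 0.25)
      block_acc <- 0L
    }
  }

  keep <- seq.int(n_burn + 1L, n_steps)
  mu_hat <- mean(exp(lmu[keep]))
  kon_hat <- mean(exp(lkon[keep]))
  cv2_hat_post <- mean(exp(-lmu[keep]) + exp(-lkon[keep]))
  acc_rate <- mean(acc[keep])
  est <- data.frame(
    mu = mu_hat, kon = kon_hat, cv2 = cv2_hat_post,
    burst_size = cv2_hat_post * mu_hat - 1,
    acceptance_rate = acc_rate,
    chain_ok = acc_rate >= 0.1 & acc_rate <= 0.6,  # health flag after adaptation
    n_steps = as.integer(n_steps)
  )
  out <- list(estimate = est)
  if (keep_trace) {
    out$trace <- data.frame(log_mu = lmu, log_kon = lkon,
                            log_post = lpost, accepted = acc)
  }
  out
}

#' Fit the bursting model to every gene of a sample
#'
#' Runs [fit_gene_mcmc()] on the raw counts of each gene over the QC-passed
#' cells of one sample. All-zero genes are skipped and reported as unfit
#' (no estimate row). Per-gene fits are independent; gene order in the
#' output is the gene order of the matrix, so results do not depend on
#' scheduling. Per-gene seeds are derived deterministically from `seed`.
#'
#' @param x a [count_matrix()] (QC-passed cells), or an integer matrix with
#'   gene ids as rownames.
#' @param sample sample label to fit; `NULL` fits all cells of `x` as one
#'   sample (using its first label).
#' @param n_steps MCMC steps per gene (default 100000; at least 10000 is
#'   recommended for desk-scale runs).
#' @param seed base integer seed.
#' @param cv2_max poor-fit exclusion threshold applied via
#'   [exclude_poor_fits()] (default 2000).
#' @param mu_min optional reporting filter: drop estimates with `mu`
#'   below this value (default `NULL`, no filter; 0.01 mirrors the
#'   cross-dataset comparison convention).
#' @return Data frame of kinetic estimates: gene, sample, mu, kon, cv2,
#'   burst_size, excluded, acceptance_rate, n_steps. Unfit (all-zero)
#'   genes are listed in the `unfit` attribute.
#' @export
fit_sample <- function(x, sample = NULL, n_steps = 1e5, seed = 1,
                       cv2_max = 2000, mu_min = NULL) {
  if (inherits(x, "count_matrix")) {
    if (!is.null(sample)) {
      keep <- x$sample == sample
      if (!any(keep)) stop(sprintf("no cells with sample label '%s'", sample))
      m <- x$counts[, keep, drop = FALSE]
    } else {
      sample <- x$sample[1]
      m <- x$counts
    }
    genes <- x$gene_ids
  } else {
    m <- x
    genes <- rownames(m)
    if (is.null(genes)) genes <- sprintf("G%d", seq_len(nrow(m)))
    if (is.null(sample)) sample <- "S1"
  }
  m <- as.matrix(m)
  rows <- vector("list", nrow(m))
  unfit <- character(0)
  for (g in seq_len(nrow(m))) {
    cnt <- m[g, ]
    if (all(cnt == 0)) {
      unfit <- c(unfit, genes[g])
      next
    }
    gene_seed <- (seed + 7919L * g) %% .Machine$integer.max
    fit <- fit_gene_mcmc(cnt, n_steps = n_steps, seed = gene_seed)
    rows[[g]] <- cbind(data.frame(gene = genes[g], sample = sample,
                                  stringsAsFactors = FALSE),
                       fit$estimate)
  }
  est <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(est) <- NULL
  est <- exclude_poor_fits(est, cv2_max = cv2_max)
  if (!is.null(mu_min)) est <- est[est$mu >= mu_min, , drop = FALSE]
  attr(est, "unfit") <- unfit
  est
}

#' Burst size from a kinetic estimate
#'
#' The average burst size `alpha/k_off` under the negative-binomial
#' approximation: `CV^2 * mu - 1`. For an internally consistent NB estimate
#' this equals `mu / kon` exactly, since `CV^2 = 1/mu + 1/kon`.
#'
#' @param estimate data frame with columns `mu` and `cv2` (e.g. a row of
#'   [fit_sample()] output).
#' @return Numeric burst size(s).
#' @examples
#' derive_burst_size(data.frame(mu = 10, cv2 = 0.6))  # 5
#' @export
derive_burst_size <- function(estimate) {
  estimate$cv2 * estimate$mu - 1
}

#' Flag poor MCMC fits by their noise estimate
#'
#' Genes whose posterior-mean `CV^2` exceeds `cv2_max` are flagged
#' `excluded` (strict inequality: a gene at exactly the threshold is
#' retained). Excluded genes drop out of all downstream statistics.
#'
#' @param estimates kinetic-estimate data frame with a `cv2` column.
#' @param cv2_max exclusion threshold (default 2000).
#' @return The input with a logical `excluded` column (re)set.
#' @export
exclude_poor_fits <- function(estimates, cv2_max = 2000) {
  estimates$excluded <- estimates$cv2 > cv2_max
  estimates
}
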