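#' Mean burst frequency of a sample
#'
#' Arithmetic mean of the fitted burst frequency `kon` over the
#' non-excluded genes of one sample; this defines the reference noise curve
#' `CV^2 = 1/mu + 1/kbar_on`.
#'
#' @param estimates kinetic-estimate data frame for one sample (columns
#'   `kon` and optionally `excluded`).
#' @return Scalar mean burst frequency.
#' @export
mean_burst_frequency <- function(estimates) {
  if (!is.null(estimates$excluded)) {
    estimates <- estimates[!estimates$excluded, , drop = FALSE]
  }
  if (nrow(estimates) == 0) stop("no non-excluded estimates")
  mean(estimates$kon)
}

#' Expression-level-corrected noise distance
#'
#' The vertical distance, on natural-log scale, of a gene's `CV^2` from the
#' reference curve `CV^2 = 1/mu + 1/kbar_on`:
#' `nu = ln(cv2) - ln(1/mu + 1/kbar_on)`. A gene on the curve has `nu = 0`;
#' multiplying `cv2` by `c` shifts `nu` by `ln(c)`. Removing the
#' expression-level trend makes `nu` comparable across genes.
#'
#' @param mu mean expression (> 0), vectorized.
#' @param cv2 squared coefficient of variation (> 0), vectorized.
#' @param kbar_on sample mean burst frequency (> 0).
#' @return Numeric `nu` values.
#' @examples
#' noise_distance(mu = 1, cv2 = 4, kbar_on = 1)  # log(2)
#' @export
noise_distance <- function(mu, cv2, kbar_on) {
  if (any(mu <= 0) || any(cv2 <= 0) || any(kbar_on <= 0)) {
    stop("mu, cv2 and kbar_on must be strictly positive")
  }
  log(cv2) - log(1 / mu + 1 / kbar_on)
}

#' Split genes into three equal noise groups
#'
#' Ranks genes by `nu` and assigns tertiles of equal size (within one):
#' `low` holds the smallest `nu`. Ties and the ordering are made
#' deterministic by a stable sort on `(nu, gene id)`; when the gene count
#' is not divisible by three the remainder goes to the lower groups first
#' (10 genes split 4/3/3).
#'
#' @param nu numeric noise distances (length >= 3).
#' @param gene_ids optional ids used as the tie-break key (defaults to
#'   input order).
#' @return Factor with levels `low`, `medium`, `high`, aligned to the
#'   input order.
#' @export
assign_noise_groups <- function(nu, gene_ids = NULL) {
  n <- length(nu)
  if (n < 3) stop("need at least 3 genes to form noise groups")
  if (is.null(gene_ids)) gene_ids <- seq_len(n)
  ord <- order(nu, gene_ids)
  base <- n %/% 3
  rem <- n %% 3
  sizes <- c(low = base + (rem >= 1), medium = base + (rem >= 2), high = base)
  lab <- rep(c("low", "medium", "high"), times = sizes)
  out <- character(n)
  out[ord] <- lab
  factor(out, levels = c("low", "medium", "high"))
}

#' Per-sample noise summary
#'
#' Joins kinetic estimates with the noise distance `nu` (against the
#' sample's, or optionally a global, mean burst frequency) and the tertile
#' noise group. Excluded genes are dropped.
#'
#' @param estimates kinetic-estimate data frame (possibly several samples).
#' @param global_kbar use one `kbar_on` computed across all samples instead
#'   of one per sample? Default `FALSE`.
#' @return Data frame: the non-excluded estimate rows plus `kbar_on`, `nu`
#'   and `noise_group`.
#' @export
noise_summary <- function(estimates, global_kbar = FALSE) {
  est <- estimates[!estimates$excluded, , drop = FALSE]
  if (nrow(est) == 0) stop("no non-excluded estimates")
  kbar_all <- mean(est$kon)
  parts <- lapply(split(est, est$sample), function(es) {
    kbar <- if (global_kbar) kbar_all else mean(es$kon)
    es$kbar_on <- kbar
    es$nu <- noise_distance(es$mu, es$cv2, kbar)
    es$noise_group <- assign_noise_groups(es$nu, es$gene)
    es
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}
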