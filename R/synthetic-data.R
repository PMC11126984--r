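#' Telegraph model rate parameters
#'
#' Container for the rates of the two-state (telegraph) gene model: a
#' promoter switches on at rate `k_on`, off at rate `k_off`, transcribes at
#' rate `alpha` while on, and each mRNA decays at rate `d`. The degradation
#' rate sets the time unit; with `d = 1` all rates are expressed per mean
#' mRNA lifetime, which is the only scale the stationary distribution can
#' resolve.
#'
#' @param k_on promoter activation rate (> 0), per mean mRNA lifetime.
#' @param k_off promoter deactivation rate (> 0).
#' @param alpha transcription rate while the promoter is on (>= 0).
#' @param d mRNA degradation rate (> 0, default 1; reference time scale).
#' @return An object of class `telegraph_params`.
#' @examples
#' telegraph_params(k_on = 0.5, k_off = 50, alpha = 250)
#' @export
telegraph_params <- function(k_on, k_off, alpha, d = 1) {
  stopifnot(is.numeric(k_on), is.numeric(k_off), is.numeric(alpha), is.numeric(d))
  if (k_on <= 0 || k_off < 0 || alpha < 0 || d <= 0) {
    stop("telegraph rates must be positive (k_off and alpha may be zero only in limiting checks)")
  }
  structure(list(k_on = k_on, k_off = k_off, alpha = alpha, d = d),
            class = "telegraph_params")
}

#' @export
print.telegraph_params <- function(x, ...) {
  cat(sprintf("telegraph_params: k_on=%g k_off=%g alpha=%g d=%g (burst size alpha/k_off=%g)\n",
              x$k_on, x$k_off, x$alpha, x$d,
              if (x$k_off > 0) x$alpha / x$k_off else NA_real_))
  invisible(x)
}

#' Sample UMI counts from the negative-binomial bursting law
#'
#' Draws per-cell mRNA copy numbers from the negative binomial distribution
#' that arises as the stationary law of the telegraph model in the bursting
#' limit: size parameter `kon` (burst frequency per mRNA lifetime) and mean
#' `mu`, so that `E[X] = mu` and `Var[X] = mu * (1 + mu/kon)`, i.e.
#' `CV^2 = 1/mu + 1/kon`. This is the generative twin of the model fitted by
#' [fit_gene_mcmc()].
#'
#' Values of `kon` above `1e6` are capped there; at that size the law is
#' numerically indistinguishable from Poisson(`mu`).
#'
#' @param mu mean expression (> 0), counts per cell.
#' @param kon burst frequency (> 0), per mean mRNA lifetime.
#' @param n_cells number of cells to draw (>= 1).
#' @param seed optional integer seed for reproducibility.
#' @return Integer vector of length `n_cells`.
#' @examples
#' x <- sample_nb_counts(mu = 10, kon = 2, n_cells = 1000, seed = 1)
#' mean(x)                      # ~ 10
#' var(x) / mean(x)^2           # ~ 1/10 + 1/2
#' @export
sample_nb_counts <- function(mu, kon, n_cells, seed = NULL) {
  if (!is.numeric(mu) || !is.numeric(kon) || mu <= 0 || kon <= 0) {
    stop("mu and kon must be strictly positive")
  }
  if (n_cells < 1) stop("n_cells must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  kon <- min(kon, 1e6)
  as.integer(stats::rnbinom(n_cells, size = kon, mu = mu))
}

#' Exact stochastic simulation of the telegraph model
#'
#' Event-driven (Gillespie) simulation of the two-state gene: one
#' independent trajectory per cell, started with the promoter off and zero
#' mRNA, run for `burn_in_time` and sampled once at the end. With
#' `burn_in_time` large compared to both `1/d` and `1/k_on` the draws are
#' stationary. Serves as the exact oracle for the negative-binomial
#' approximation used throughout.
#'
#' @param params a [telegraph_params()] object.
#' @param n_cells number of cells (independent trajectories).
#' @param burn_in_time simulated time before the single draw; default `20/d`.
#' @param seed optional integer seed.
#' @return Integer vector of stationary mRNA copy numbers, one per cell.
#' @examples
#' p <- telegraph_params(k_on = 0.5, k_off = 50, alpha = 250)
#' x <- simulate_telegraph(p, n_cells = 200, seed = 1)
#' @export
simulate_telegraph <- function(params, n_cells, burn_in_time = 20 / params$d,
                               seed = NULL) {
  stopifnot(inherits(params, "telegraph_params"))
  if (burn_in_time <= 0) stop("burn_in_time must be positive")
  if (n_cells < 1) stop("n_cells must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  k_on <- params$k_on; k_off <- params$k_off
  alpha <- params$alpha; d <- params$d
  out <- integer(n_cells)
  for (cell in seq_len(n_cells)) {
    t <- 0; on <- FALSE; m <- 0L
    repeat {
      r_switch <- if (on) k_off else k_on
      r_birth <- if (on) alpha else 0
      r_death <- d * m
      r_tot <- r_switch + r_birth + r_death
      if (r_tot <= 0) break  # absorbing (e.g. alpha = 0, m = 0, k_on = 0)
      t <- t + stats::rexp(1, r_tot)
      if (t > burn_in_time) break
      u <- stats::runif(1) * r_tot
      if (u < r_switch) {
        on <- !on
      } else if (u < r_switch + r_birth) {
        m <- m + 1L
      } else {
        m <- m - 1L
      }
    }
    out[cell] <- m
  }
  out
}

#' Configuration for a synthetic bursting study
#'
#' Describes a multi-sample synthetic scRNA-seq study with known bursting
#' kinetics: per-gene means and burst frequencies drawn log-uniformly,
#' mitochondrial genes, sparsely detected tag genes, a sub-population of
#' damaged cells, and optional planted kinetic shifts between samples.
#'
#' Effects are a list of entries `list(sample =, genes =, parameter =
#' c("burst_size", "kon"), factor =)`. A burst-size shift multiplies the
#' true mean by `factor` at fixed `kon` (burst size `mu/kon` scales by
#' `factor`); a `kon` shift multiplies both `kon` and `mu` by `factor`
#' (burst size fixed).
#'
#' @param n_samples number of samples (cell lines).
#' @param cells_per_sample cells per sample.
#' @param n_genes number of ordinary genes (tag genes are added on top).
#' @param mu_range log-uniform bounds for true mean expression.
#' @param kon_range log-uniform bounds for true burst frequency.
#' @param frac_mito_genes fraction of genes given an `MT-` name.
#' @param frac_damaged_cells fraction of cells per sample that are damaged.
#' @param tag_detection_rate probability a cell of the tag's sample group
#'   has nonzero tag counts (default 0.075, i.e. ~7--8 percent).
#' @param tag_genes names of the tag genes; each tag is expressed only in
#'   its sample group (samples split between tags in order).
#' @param effects list of planted kinetic shifts (see Details).
#' @param seed integer seed controlling every random choice.
#' @return An object of class `study_config`.
#' @export
study_config <- function(n_samples = 2, cells_per_sample = 500, n_genes = 200,
                         mu_range = c(0.05, 50), kon_range = c(0.1, 5),
                         frac_mito_genes = 0.05, frac_damaged_cells = 0.05,
                         tag_detection_rate = 0.075,
                         tag_genes = c("Dendra2", "HaloTag"),
                         effects = list(), seed = 1L) {
  stopifnot(n_samples >= 1, cells_per_sample >= 1, n_genes >= 1)
  if (frac_mito_genes < 0 || frac_mito_genes > 1 ||
      frac_damaged_cells < 0 || frac_damaged_cells > 1 ||
      tag_detection_rate < 0 || tag_detection_rate > 1) {
    stop("fractions must lie in [0, 1]")
  }
  for (rng in list(mu_range, kon_range)) {
    if (length(rng) != 2 || any(rng <= 0) || rng[1] > rng[2]) {
      stop("ranges must be positive and ordered")
    }
  }
  cfg <- structure(list(
    n_samples = as.integer(n_samples),
    cells_per_sample = as.integer(cells_per_sample),
    n_genes = as.integer(n_genes),
    mu_range = mu_range, kon_range = kon_range,
    frac_mito_genes = frac_mito_genes,
    frac_damaged_cells = frac_damaged_cells,
    tag_detection_rate = tag_detection_rate,
    tag_genes = tag_genes,
    effects = effects, seed = as.integer(seed)
  ), class = "study_config")
  validate_effects(cfg)
  cfg
}

validate_effects <- function(cfg) {
  for (eff in cfg$effects) {
    if (is.null(eff$sample) || is.null(eff$factor)) {
      stop("effect spec needs 'sample' and 'factor'")
    }
    if (any(eff$sample < 1) || any(eff$sample > cfg$n_samples)) {
      stop("effect spec references a sample index out of range")
    }
    genes <- if (is.null(eff$genes)) seq_len(cfg$n_genes) else eff$genes
    if (any(genes < 1) || any(genes > cfg$n_genes)) {
      stop("effect spec references a gene index out of range")
    }
    par <- if (is.null(eff$parameter)) "burst_size" else eff$parameter
    if (!par %in% c("burst_size", "kon")) {
      stop("effect parameter must be 'burst_size' or 'kon'")
    }
  }
  invisible(cfg)
}

# Expected mito fraction of healthy cells; damaged cells are pushed past the
# 25% QC rule deterministically (see below).
.healthy_mito_target <- 0.08
.damaged_mito_target <- 0.40
.damaged_thinning <- 0.15

#' Generate a synthetic multi-sample bursting study
#'
#' Draws per-gene true kinetics (log-uniform `mu` and `kon`), applies the
#' configured kinetic shifts, and samples a UMI count matrix per sample from
#' the negative-binomial bursting law via [sample_nb_counts()]. Adds
#' mitochondrial genes (names prefixed `MT-`, scaled so healthy cells carry
#' roughly 8 percent mitochondrial counts), one tag gene per tag type
#' expressed only in its sample group and zeroed by a Bernoulli detection
#' mask, and a fraction of damaged cells built from healthy cells by global
#' binomial downsampling (reducing detected genes) plus inflation of the
#' `MT-` counts past the 25 percent rule.
#'
#' @param config a [study_config()].
#' @return A list with elements `matrix` (a [count_matrix()]) and `truth`
#'   (data frame: gene, sample, mu_true, kon_true, burst_size_true) plus
#'   `cell_truth` (data frame: barcode, sample, damaged).
#' @examples
#' st <- generate_study(study_config(n_samples = 2, cells_per_sample = 50,
#'                                   n_genes = 30, seed = 7))
#' dim(st$matrix$counts)
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  validate_effects(config)
  set.seed(config$seed)
  n_g <- config$n_genes
  n_s <- config$n_samples
  n_c <- config$cells_per_sample

  n_mito <- round(config$frac_mito_genes * n_g)
  gene_ids <- sprintf("GENE%04d", seq_len(n_g))
  if (n_mito > 0) {
    mito_idx <- seq_len(n_mito)  # first block: deterministic bookkeeping
    gene_ids[mito_idx] <- sprintf("MT-%03d", seq_len(n_mito))
  } else {
    mito_idx <- integer(0)
  }

  lu <- function(n, rng) exp(stats::runif(n, log(rng[1]), log(rng[2])))
  mu_base <- lu(n_g, config$mu_range)
  kon_base <- lu(n_g, config$kon_range)

  # Mitochondrial transcripts are abundant and steadily expressed: rescale
  # their means so healthy cells carry ~.healthy_mito_target mitochondrial
  # counts, and give them a high burst frequency (near-Poisson counts).
  if (n_mito > 0) {
    tot_other <- sum(mu_base[-mito_idx])
    target <- .healthy_mito_target / (1 - .healthy_mito_target) * tot_other
    mu_base[mito_idx] <- mu_base[mito_idx] * target / sum(mu_base[mito_idx])
    kon_base[mito_idx] <- 10
  }

  # per-sample truth after planted effects
  mu_true <- matrix(mu_base, n_g, n_s)
  kon_true <- matrix(kon_base, n_g, n_s)
  for (eff in config$effects) {
    genes <- if (is.null(eff$genes)) seq_len(n_g) else eff$genes
    par <- if (is.null(eff$parameter)) "burst_size" else eff$parameter
    for (s in eff$sample) {
      if (par == "burst_size") {
        mu_true[genes, s] <- mu_true[genes, s] * eff$factor
      } else {
        kon_true[genes, s] <- kon_true[genes, s] * eff$factor
        mu_true[genes, s] <- mu_true[genes, s] * eff$factor
      }
    }
  }

  # tag genes: one per tag type, sample groups split in order
  tags <- config$tag_genes
  n_tag <- length(tags)
  # sample s carries tag number tag_of_sample[s]; with fewer samples than
  # tags the surplus tag genes stay all-zero
  tag_of_sample <- if (n_tag > 0) sort(rep_len(seq_len(n_tag), n_s)) else integer(0)

  n_damaged <- round(config$frac_damaged_cells * n_c)
  counts <- vector("list", n_s)
  sample_ids <- sprintf("S%d", seq_len(n_s))
  cell_truth <- list()
  for (s in seq_len(n_s)) {
    m <- matrix(0L, n_g + n_tag, n_c)
    for (g in seq_len(n_g)) {
      m[g, ] <- sample_nb_counts(mu_true[g, s], kon_true[g, s], n_c)
    }
    for (ti in seq_len(n_tag)) {
      if (tag_of_sample[s] == ti) {
        # highly expressed NB gene under a Bernoulli detection mask, so the
        # nonzero-cell fraction tracks tag_detection_rate
        base <- sample_nb_counts(20, 5, n_c)
        mask <- stats::rbinom(n_c, 1, config$tag_detection_rate)
        m[n_g + ti, ] <- as.integer(base * mask)
      }
    }
    damaged <- rep(FALSE, n_c)
    if (n_damaged > 0) {
      dmg <- seq_len(n_damaged)  # first cells of each sample: bookkeeping
      damaged[dmg] <- TRUE
      for (cell in dmg) {
        v <- m[, cell]
        v <- stats::rbinom(length(v), v, .damaged_thinning)  # global downsampling
        if (length(mito_idx) > 0) {
          tot_other <- sum(v[-mito_idx])
          need <- ceiling(.damaged_mito_target / (1 - .damaged_mito_target) * max(tot_other, 1))
          cur <- sum(v[mito_idx])
          if (cur < need) {
            add <- stats::rmultinom(1, need - cur, rep(1, length(mito_idx)))[, 1]
            v[mito_idx] <- v[mito_idx] + add
          }
        }
        m[, cell] <- as.integer(v)
      }
    }
    counts[[s]] <- m
    cell_truth[[s]] <- data.frame(
      barcode = sprintf("%s_CELL%04d", sample_ids[s], seq_len(n_c)),
      sample = sample_ids[s], damaged = damaged,
      stringsAsFactors = FALSE
    )
  }

  all_counts <- do.call(cbind, counts)
  cell_truth <- do.call(rbind, cell_truth)
  rownames(cell_truth) <- NULL
  all_ids <- c(gene_ids, tags)
  cm <- count_matrix(
    counts = all_counts,
    gene_ids = all_ids,
    barcodes = cell_truth$barcode,
    sample = cell_truth$sample,
    tag_genes = tags
  )

  truth <- data.frame(
    gene = rep(gene_ids, n_s),
    sample = rep(sample_ids, each = n_g),
    mu_true = as.vector(mu_true),
    kon_true = as.vector(kon_true),
    stringsAsFactors = FALSE
  )
  truth$burst_size_true <- truth$mu_true / truth$kon_true

  list(matrix = cm, truth = truth, cell_truth = cell_truth)
}

#' Write a synthetic study to disk
#'
#' Writes the count matrix in 10x-style Matrix Market triplet form (plus a
#' dense CSV copy) and the ground-truth tables as TSV.
#'
#' @param study result of [generate_study()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_count_matrix(study$matrix, file.path(dir, "counts"), format = "mtx")
  write_count_matrix(study$matrix, file.path(dir, "counts.csv"), format = "csv")
  utils::write.table(study$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(study$cell_truth, file.path(dir, "cell_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
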