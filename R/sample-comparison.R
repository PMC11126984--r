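#' Kruskal-Wallis test across kinetic classes
#'
#' Rank-based H test of whether several groups of a kinetic parameter
#' (e.g. CTD-length classes) come from the same distribution, with tie
#' correction and a chi-squared approximation on `groups - 1` degrees of
#' freedom. The fully degenerate case (every value identical) is reported
#' as `H = 0, p = 1` rather than an indeterminate statistic.
#'
#' @param values numeric parameter values.
#' @param groups group label per value (>= 2 nonempty groups).
#' @return List with `H`, `p`, and `df`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2) stop("need at least 2 nonempty groups")
  if (any(table(droplevels(groups)) < 1)) stop("every group needs >= 1 value")
  if (length(unique(values)) == 1) {
    return(list(H = 0, p = 1, df = nlevels(droplevels(groups)) - 1L))
  }
  kt <- stats::kruskal.test(values, groups)
  list(H = unname(kt$statistic), p = kt$p.value,
       df = unname(kt$parameter))
}

#' Pairwise Wilcoxon rank-sum comparison
#'
#' Two-sided Mann-Whitney U test between the per-gene parameter values of
#' two samples: exact enumeration for small tie-free inputs, normal
#' approximation with tie correction otherwise (the `stats::wilcox.test`
#' switching rule). Rank-based, hence invariant under strictly monotone
#' transformations of the values.
#'
#' @param values_a,values_b numeric vectors (both nonempty).
#' @return List with `W` (rank-sum statistic for the first sample) and
#'   two-sided `p`.
#' @export
pairwise_wilcoxon <- function(values_a, values_b) {
  if (length(values_a) == 0 || length(values_b) == 0) {
    stop("both samples must be nonempty")
  }
  wt <- suppressWarnings(stats::wilcox.test(values_a, values_b))
  list(W = unname(wt$statistic), p = wt$p.value)
}

#' All pairwise tests of the kinetic parameters
#'
#' Runs [pairwise_wilcoxon()] for every unordered sample pair and every
#' kinetic parameter. No multiplicity adjustment is applied: each pairwise
#' comparison yields a single p value, so standard corrections do not
#' apply; raw p values are reported with that caveat recorded in the
#' `note` attribute.
#'
#' @param estimates noise-summary data frame (non-excluded genes with
#'   columns `mu`, `kon`, `cv2`, `nu`, `burst_size`, `sample`).
#' @param parameters which parameters to compare.
#' @return Long data frame: parameter, sample_a, sample_b, W, p.
#' @export
compare_samples <- function(estimates,
                            parameters = c("mu", "kon", "cv2", "nu",
                                           "burst_size")) {
  samples <- sort(unique(estimates$sample))
  if (length(samples) < 2) stop("need at least 2 samples")
  rows <- list()
  for (par in parameters) {
    for (i in seq_along(samples)) {
      for (j in seq_along(samples)) {
        if (j <= i) next
        a <- estimates[estimates$sample == samples[i], par]
        b <- estimates[estimates$sample == samples[j], par]
        tst <- pairwise_wilcoxon(a, b)
        rows[[length(rows) + 1]] <- data.frame(
          parameter = par, sample_a = samples[i], sample_b = samples[j],
          W = tst$W, p = tst$p, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "note") <-
    "raw p values; one value per pairwise comparison, no multiplicity adjustment"
  out
}

#' Tournament ordering of samples by a kinetic parameter
#'
#' For every unordered sample pair, counts the genes on which each sample
#' has the strictly higher parameter value (genes tied on the value are
#' discarded from that pair; only genes with a non-excluded estimate in
#' both samples count). The pair's winner is the sample with the larger
#' count; an equal count is split 0.5/0.5. Pair outcomes are compiled into
#' per-sample win totals (Copeland score) and a ranking, descending by
#' wins with sample name as the deterministic tie-break.
#'
#' @param estimates noise-summary data frame across samples.
#' @param parameter column to compare (e.g. `"burst_size"`).
#' @return List with `pairs` (data frame: sample_a, sample_b, a_higher,
#'   b_higher, ties, shared_genes, winner) and `ranking` (data frame:
#'   sample, wins, rank). Pairs without shared genes are reported with
#'   `winner = NA` and skipped in the compilation.
#' @export
tournament_ordering <- function(estimates, parameter) {
  if (!parameter %in% names(estimates)) {
    stop(sprintf("unknown parameter '%s'", parameter))
  }
  if (!is.null(estimates$excluded)) {
    estimates <- estimates[!estimates$excluded, , drop = FALSE]
  }
  samples <- sort(unique(estimates$sample))
  if (length(samples) < 2) stop("need at least 2 samples")
  wide <- split(estimates, estimates$sample)
  wins <- stats::setNames(numeric(length(samples)), samples)
  rows <- list()
  for (i in seq_along(samples)) {
    for (j in seq_along(samples)) {
      if (j <= i) next
      sa <- wide[[samples[i]]]; sb <- wide[[samples[j]]]
      shared <- intersect(sa$gene, sb$gene)
      if (length(shared) == 0) {
        rows[[length(rows) + 1]] <- data.frame(
          sample_a = samples[i], sample_b = samples[j],
          a_higher = NA_integer_, b_higher = NA_integer_,
          ties = NA_integer_, shared_genes = 0L, winner = NA_character_,
          stringsAsFactors = FALSE)
        next
      }
      va <- sa[[parameter]][match(shared, sa$gene)]
      vb <- sb[[parameter]][match(shared, sb$gene)]
      a_hi <- sum(va > vb); b_hi <- sum(vb > va); tie <- sum(va == vb)
      if (a_hi > b_hi) {
        winner <- samples[i]; wins[samples[i]] <- wins[samples[i]] + 1
      } else if (b_hi > a_hi) {
        winner <- samples[j]; wins[samples[j]] <- wins[samples[j]] + 1
      } else {
        winner <- "tie"
        wins[samples[i]] <- wins[samples[i]] + 0.5
        wins[samples[j]] <- wins[samples[j]] + 0.5
      }
      rows[[length(rows) + 1]] <- data.frame(
        sample_a = samples[i], sample_b = samples[j],
        a_higher = a_hi, b_higher = b_hi, ties = tie,
        shared_genes = length(shared), winner = winner,
        stringsAsFactors = FALSE)
    }
  }
  ranking <- data.frame(sample = names(wins), wins = unname(wins),
                        stringsAsFactors = FALSE)
  ranking <- ranking[order(-ranking$wins, ranking$sample), , drop = FALSE]
  ranking$rank <- seq_len(nrow(ranking))
  rownames(ranking) <- NULL
  list(pairs = do.call(rbind, rows), ranking = ranking,
       parameter = parameter)
}
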