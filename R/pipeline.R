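#' Build a pipeline configuration
#'
#' Assembles and validates the configuration driving [run_pipeline()]:
#' either a simulation recipe (a [study_config()]) or an input directory of
#' per-sample matrices, QC thresholds, MCMC settings, the sample-to-class
#' map used by the Kruskal-Wallis stage, tag gene names, and contrast
#' definitions for differential expression. Contrasts are named lists
#' `list(a = <samples>, b = <samples>)`.
#'
#' @param simulate a [study_config()], or `NULL` when `input_dir` is given.
#' @param input_dir directory of per-sample MTX triplets (one subdirectory
#'   per sample), used when `simulate` is `NULL`.
#' @param min_genes,max_mito QC thresholds (defaults 1250 and 0.25).
#' @param n_steps,seed,cv2_max,mu_min MCMC settings for [fit_sample()].
#' @param classes named vector mapping sample to class (e.g. CTD length);
#'   `NULL` disables the Kruskal-Wallis stage.
#' @param tag_genes tag gene names for the association stage.
#' @param contrasts named list of DE contrasts (see Details).
#' @param llps_file optional plain-text gene-set file for enrichment.
#' @param global_kbar single global mean burst frequency instead of one per
#'   sample (default `FALSE`).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = NULL, input_dir = NULL,
                            min_genes = 1250, max_mito = 0.25,
                            n_steps = 1e5, seed = 1, cv2_max = 2000,
                            mu_min = NULL, classes = NULL,
                            tag_genes = c("Dendra2", "HaloTag"),
                            contrasts = list(), llps_file = NULL,
                            global_kbar = FALSE) {
  if (is.null(simulate) && is.null(input_dir)) {
    stop("either a simulation recipe or an input directory is required")
  }
  cfg <- structure(list(
    simulate = simulate, input_dir = input_dir,
    min_genes = min_genes, max_mito = max_mito,
    n_steps = n_steps, seed = as.integer(seed), cv2_max = cv2_max,
    mu_min = mu_min, classes = classes, tag_genes = tag_genes,
    contrasts = contrasts, llps_file = llps_file,
    global_kbar = global_kbar
  ), class = "pipeline_config")
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  known <- NULL
  if (!is.null(cfg$simulate)) {
    stopifnot(inherits(cfg$simulate, "study_config"))
    known <- sprintf("S%d", seq_len(cfg$simulate$n_samples))
  }
  check <- function(samples, what) {
    if (!is.null(known)) {
      bad <- setdiff(samples, known)
      if (length(bad) > 0) {
        stop(sprintf("%s references undefined sample '%s'", what, bad[1]))
      }
    }
  }
  for (nm in names(cfg$contrasts)) {
    ct <- cfg$contrasts[[nm]]
    if (is.null(ct$a) || is.null(ct$b)) {
      stop(sprintf("contrast '%s' needs groups 'a' and 'b'", nm))
    }
    check(c(ct$a, ct$b), sprintf("contrast '%s'", nm))
  }
  if (!is.null(cfg$classes)) check(names(cfg$classes), "class map")
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Flat YAML rendering of [pipeline_config()]; the `simulate` block maps
#' onto [study_config()] fields, `contrasts` onto named `a`/`b` lists. See
#' the package vignette for an annotated example.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- if (!is.null(y$simulate)) do.call(study_config, y$simulate) else NULL
  classes <- if (!is.null(y$classes)) unlist(y$classes) else NULL
  args <- y[setdiff(names(y), c("simulate", "classes"))]
  do.call(pipeline_config, c(list(simulate = sim, classes = classes), args))
}

.stage_done <- function(dir, files) all(file.exists(file.path(dir, files)))

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the bursting analysis pipeline
#'
#' Orchestrates simulate -> qc -> fit -> noise -> compare -> assoc into a
#' run directory. Every stage writes TSV outputs plus a `manifest.json`
#' recording the configuration hash, seeds, stage status and row counts at
#' every filter. With `resume = TRUE` a stage whose outputs already exist
#' is skipped, so deleting one stage's files recomputes only that stage and
#' its descendants. All randomness flows from the configured seeds; reruns
#' with an identical configuration are bit-identical for the deterministic
#' stages.
#'
#' @param config a [pipeline_config()].
#' @param out_dir run directory (created if needed).
#' @param resume skip stages with existing outputs? Default `TRUE`.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, out_dir, resume = TRUE) {
  config <- validate_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_file <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(unclass(config), cfg_file)
  manifest <- list(config_hash = unname(tools::md5sum(cfg_file)),
                   seed = config$seed, stages = list(),
                   package_version = as.character(utils::packageVersion("burstline")))
  log_stage <- function(name, info) {
    manifest$stages[[name]] <<- c(list(status = "done"), info)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         force = TRUE)
  }

  # -- simulate / ingest -------------------------------------------------
  sim_dir <- file.path(out_dir, "simulate")
  if (!is.null(config$simulate)) {
    if (!(resume && .stage_done(sim_dir, "truth.tsv"))) {
      write_study(generate_study(config$simulate), sim_dir)
    }
    cm <- read_count_matrix(file.path(sim_dir, "counts"), format = "mtx",
                            tag_genes = config$tag_genes)
    cell_truth <- utils::read.table(file.path(sim_dir, "cell_truth.tsv"),
                                    sep = "\t", header = TRUE,
                                    stringsAsFactors = FALSE)
    cm$sample <- cell_truth$sample[match(cm$barcodes, cell_truth$barcode)]
    log_stage("simulate", list(n_genes = nrow(cm$counts),
                               n_cells = ncol(cm$counts)))
  } else {
    subdirs <- list.dirs(config$input_dir, recursive = FALSE)
    if (length(subdirs) == 0) stop("input_dir contains no sample directories")
    mats <- lapply(subdirs, function(d) {
      read_count_matrix(d, format = "mtx", sample = basename(d),
                        tag_genes = config$tag_genes)
    })
    counts <- do.call(cbind, lapply(mats, function(m) m$counts))
    cm <- count_matrix(counts, gene_ids = mats[[1]]$gene_ids,
                       barcodes = unlist(lapply(mats, `[[`, "barcodes")),
                       sample = unlist(lapply(mats, `[[`, "sample")),
                       tag_genes = config$tag_genes)
    log_stage("ingest", list(n_samples = length(mats),
                             n_cells = ncol(cm$counts)))
  }

  # -- qc ----------------------------------------------------------------
  qc_dir <- file.path(out_dir, "qc")
  dir.create(qc_dir, showWarnings = FALSE)
  qc <- compute_cell_qc(cm)
  filtered <- filter_cells(cm, qc, min_genes = config$min_genes,
                           max_mito = config$max_mito)
  qc$kept <- qc$barcode %in% filtered$barcodes
  .write_tsv(qc, file.path(qc_dir, "qc_report.tsv"))
  log_stage("qc", list(cells_in = nrow(qc), cells_kept = sum(qc$kept),
                       removed_per_sample = as.list(attr(filtered, "removed"))))

  # -- fit ---------------------------------------------------------------
  fit_dir <- file.path(out_dir, "fit")
  fit_file <- file.path(fit_dir, "estimates.tsv")
  if (resume && file.exists(fit_file)) {
    est <- utils::read.table(fit_file, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
  } else {
    dir.create(fit_dir, showWarnings = FALSE)
    est <- do.call(rbind, lapply(sort(unique(filtered$sample)), function(s) {
      fit_sample(filtered, sample = s, n_steps = config$n_steps,
                 seed = config$seed, cv2_max = config$cv2_max,
                 mu_min = config$mu_min)
    }))
    .write_tsv(est, fit_file)
  }
  log_stage("fit", list(n_estimates = nrow(est),
                        n_excluded = sum(est$excluded)))

  # -- noise -------------------------------------------------------------
  noise_dir <- file.path(out_dir, "noise")
  dir.create(noise_dir, showWarnings = FALSE)
  ns <- noise_summary(est, global_kbar = config$global_kbar)
  .write_tsv(ns, file.path(noise_dir, "noise_summary.tsv"))
  log_stage("noise", list(n_genes = nrow(ns)))

  # -- compare -----------------------------------------------------------
  cmp_dir <- file.path(out_dir, "compare")
  dir.create(cmp_dir, showWarnings = FALSE)
  n_samples <- length(unique(ns$sample))
  if (n_samples >= 2) {
    tests <- compare_samples(ns)
    .write_tsv(tests, file.path(cmp_dir, "pairwise_tests.tsv"))
    ords <- do.call(rbind, lapply(c("mu", "kon", "cv2", "nu", "burst_size"),
      function(par) {
        tr <- tournament_ordering(ns, par)
        cbind(parameter = par, tr$ranking)
      }))
    .write_tsv(ords, file.path(cmp_dir, "ordering.tsv"))
    if (!is.null(config$classes)) {
      kw <- do.call(rbind, lapply(c("mu", "kon", "cv2", "nu", "burst_size"),
        function(par) {
          cls <- config$classes[ns$sample]
          res <- kruskal_wallis(ns[[par]], cls)
          data.frame(parameter = par, H = res$H, p = res$p, df = res$df)
        }))
      .write_tsv(kw, file.path(cmp_dir, "kruskal_wallis.tsv"))
    }
    log_stage("compare", list(n_pairs = n_samples * (n_samples - 1) / 2))
  } else {
    log_stage("compare", list(skipped = "fewer than 2 samples"))
  }

  # -- assoc -------------------------------------------------------------
  assoc_dir <- file.path(out_dir, "assoc")
  dir.create(assoc_dir, showWarnings = FALSE)
  norm <- normalize_counts(filtered)
  assoc_info <- list()
  present_tags <- intersect(config$tag_genes, filtered$gene_ids)
  for (tg in present_tags) {
    res <- tryCatch(tag_correlation(norm, tg), error = function(e) NULL)
    if (!is.null(res)) {
      .write_tsv(res, file.path(assoc_dir, sprintf("correlation_%s.tsv", tg)))
      assoc_info[[sprintf("correlated_%s", tg)]] <- sum(res$significant)
    }
  }
  llps <- if (!is.null(config$llps_file)) read_gene_set(config$llps_file) else NULL
  n_contrasts <- length(config$contrasts)
  for (nm in names(config$contrasts)) {
    ct <- config$contrasts[[nm]]
    de <- differential_expression(norm,
                                  filtered$barcodes[filtered$sample %in% ct$a],
                                  filtered$barcodes[filtered$sample %in% ct$b])
    .write_tsv(de, file.path(assoc_dir, sprintf("de_%s.tsv", nm)))
    assoc_info[[sprintf("de_significant_%s", nm)]] <- sum(de$significant)
    if (!is.null(llps)) {
      enr <- llps_enrichment(de$gene[de$significant & de$direction == "up"],
                             llps, de$gene, n_contrasts = n_contrasts)
      .write_tsv(data.frame(contrast = nm, odds_ratio = enr$odds_ratio,
                            p = enr$p, p_adj = enr$p_adj),
                 file.path(assoc_dir, sprintf("enrichment_%s.tsv", nm)))
    }
  }
  log_stage("assoc", assoc_info)

  invisible(manifest)
}
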