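# Pipeline orchestration: a declarative config, input validation, the
# end-to-end driver, and a small subcommand CLI.

#' Build a pipeline configuration
#'
#' All thresholds default to the analysis' stated constants: screen FDR
#' 0.05, distal-link FDR 0.01, 500 kbp distance horizon, promoter window
#' 1000-100 bp upstream of the TSS, epithelial high/low cutoff 0.5.
#'
#' @param cohort,masks,peaks,accessibility,expression,genes,copy_number,gmt,survival
#'   input paths (`cohort` a TSV, or `masks` a directory of label masks;
#'   `copy_number`, `gmt`, `survival` optional).
#' @param out_dir output directory.
#' @param alpha screen FDR threshold.
#' @param distal_fdr distal-link FDR threshold.
#' @param max_dist distal distance horizon in bp.
#' @param promoter_upstream,promoter_proximal promoter window in bp.
#' @param cutoff epithelial high/low boundary.
#' @param p_method screen p-value method.
#' @param cnv_attenuation CNV-filter threshold.
#' @param rho_cut optional extra |rho| threshold for the screen (NULL = off).
#' @param seed master seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = NULL, masks = NULL, peaks = NULL,
                            accessibility = NULL, expression = NULL,
                            genes = NULL, copy_number = NULL, gmt = NULL,
                            survival = NULL, out_dir = "epistroma_out",
                            alpha = 0.05, distal_fdr = 0.01,
                            max_dist = 500000L, promoter_upstream = 1000L,
                            promoter_proximal = 100L, cutoff = 0.5,
                            p_method = "auto", cnv_attenuation = 0.5,
                            rho_cut = NULL, seed = 1L) {
  check_scalar_number(alpha, "alpha", 0, 1)
  check_scalar_number(distal_fdr, "distal_fdr", 0, 1)
  check_scalar_number(max_dist, "max_dist", 0, Inf, strict_lower = TRUE)
  check_scalar_number(cutoff, "cutoff", 0, 1)
  check_scalar_number(cnv_attenuation, "cnv_attenuation", 0, 1)
  if (promoter_proximal >= promoter_upstream) {
    stop_invalid("promoter_proximal must be smaller than promoter_upstream")
  }
  structure(list(
    cohort = cohort, masks = masks, peaks = peaks,
    accessibility = accessibility, expression = expression, genes = genes,
    copy_number = copy_number, gmt = gmt, survival = survival,
    out_dir = out_dir, alpha = alpha, distal_fdr = distal_fdr,
    max_dist = max_dist, promoter_upstream = promoter_upstream,
    promoter_proximal = promoter_proximal, cutoff = cutoff,
    p_method = p_method, cnv_attenuation = cnv_attenuation,
    rho_cut = rho_cut, seed = seed
  ), class = "pipeline_config")
}

#' Validate pipeline inputs
#'
#' Checks file existence, coordinate sanity, label encodings, and sample
#' overlaps, returning findings rather than stopping; `level = "fatal"`
#' findings would make [run_all()] fail.
#'
#' @param config a [pipeline_config()].
#' @return data.frame with columns `level` (`"warning"`/`"fatal"`) and
#'   `message`; zero rows mean a clean bundle.
#' @export
validate_inputs <- function(config) {
  findings <- list()
  add <- function(level, msg) {
    findings[[length(findings) + 1L]] <<- data.frame(
      level = level, message = msg, stringsAsFactors = FALSE)
  }
  need <- c("peaks", "accessibility")
  for (f in need) {
    if (is.null(config[[f]])) add("fatal", sprintf("missing input: %s", f))
    else if (!file.exists(config[[f]])) {
      add("fatal", sprintf("%s file not found: %s", f, config[[f]]))
    }
  }
  if (is.null(config$cohort) && is.null(config$masks)) {
    add("fatal", "neither a cohort TSV nor a mask directory given")
  }
  peaks <- NULL
  if (!is.null(config$peaks) && file.exists(config$peaks)) {
    peaks <- tryCatch(read_peaks(config$peaks), error = function(e) {
      add("fatal", sprintf("peaks: %s", conditionMessage(e)))
      NULL
    })
  }
  cohort <- NULL
  if (!is.null(config$cohort) && file.exists(config$cohort)) {
    cohort <- tryCatch(read_cohort(config$cohort, config$cutoff),
                       error = function(e) {
                         add("fatal", sprintf("cohort: %s", conditionMessage(e)))
                         NULL
                       })
  }
  if (!is.null(config$masks)) {
    for (f in list.files(config$masks, pattern = "\\.tsv$",
                         full.names = TRUE)) {
      m <- read_mask(f)
      bad <- setdiff(unique(as.integer(m)), 0:2)
      if (length(bad) > 0) {
        add("fatal", sprintf("mask %s has unknown labels: %s", basename(f),
                             paste(bad, collapse = ",")))
      }
    }
  }
  if (!is.null(config$accessibility) && file.exists(config$accessibility) &&
      !is.null(cohort)) {
    acc <- read_matrix_tsv(config$accessibility)
    miss <- setdiff(cohort$sample_id, colnames(acc))
    if (length(miss) > 0) {
      add("warning",
          sprintf("%d cohort sample(s) missing from accessibility; inner join will be used",
                  length(miss)))
    }
    if (length(intersect(colnames(acc), cohort$sample_id)) < 3L) {
      add("fatal", "fewer than 3 shared samples between accessibility and cohort")
    }
    if (!is.null(peaks)) {
      unknown <- setdiff(rownames(acc), peaks$peak_id)
      if (length(unknown) > 0) {
        add("warning", sprintf("%d accessibility row(s) absent from the peak atlas",
                               length(unknown)))
      }
    }
  }
  if (length(findings) == 0L) {
    return(data.frame(level = character(0), message = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, findings)
}

#' Run the full integrative pipeline
#'
#' Executes image quantification, the peak-phenotype screen, peak-to-gene
#' linking, optional enrichment, and survival analysis; writes per-stage
#' TSVs, the resolved configuration, and a JSON run report with the stage
#' funnel counts.
#'
#' @param config a [pipeline_config()].
#' @return the run report (a list), invisibly; also written as
#'   `report.json` in `out_dir`.
#' @export
run_all <- function(config) {
  findings <- validate_inputs(config)
  if (any(findings$level == "fatal")) {
    stop(paste0("input validation failed:\n  ",
                paste(findings$message[findings$level == "fatal"],
                      collapse = "\n  ")), call. = FALSE)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  outp <- function(f) file.path(config$out_dir, f)

  # stage 1: cohort / image quantification
  cohort <- if (!is.null(config$cohort)) {
    read_cohort(config$cohort, config$cutoff)
  } else {
    quantify_masks(config$masks, config$cutoff)
  }
  write_cohort(cohort, outp("cohort.tsv"))
  summ <- cohort_summary(cohort, config$cutoff)

  # stage 2: peak-phenotype screen
  peaks <- read_peaks(config$peaks)
  acc <- read_matrix_tsv(config$accessibility)
  screen <- screen_peaks(acc, cohort, alpha = config$alpha,
                         method = config$p_method, rho_cut = config$rho_cut,
                         peaks = peaks, seed = config$seed)
  counts <- attr(screen, "counts")
  data.table::fwrite(screen, outp("screen_results.tsv"), sep = "\t")
  sig_ids <- screen$peak_id[screen$significant]

  # stage 3: peak-to-gene linking
  promoter_links <- NULL
  distal <- NULL
  targets <- NULL
  expr <- NULL
  if (!is.null(config$genes) && !is.null(config$expression)) {
    genes <- read_genes(config$genes)
    expr <- read_matrix_tsv(config$expression)
    cn <- if (!is.null(config$copy_number)) {
      read_matrix_tsv(config$copy_number)
    } else NULL
    sig_peaks <- peaks[peaks$peak_id %in% sig_ids, , drop = FALSE]
    promoter_links <- assign_promoter_peaks(
      sig_peaks, genes, config$promoter_upstream, config$promoter_proximal)
    distal <- link_peaks_to_genes(
      peaks, genes, sig_ids, acc, expr, cn = cn,
      fdr_cut = config$distal_fdr, max_dist = config$max_dist,
      attenuation = config$cnv_attenuation,
      upstream = config$promoter_upstream,
      proximal_gap = config$promoter_proximal)
    np <- nrow(promoter_links)
    links_out <- rbind(
      data.frame(promoter_links, rho = rep(NA_real_, np),
                 fdr = rep(NA_real_, np), cnv_driven = rep(FALSE, np),
                 promoter_overlap = rep(FALSE, np),
                 surviving = rep(TRUE, np)),
      distal[, c("peak_id", "gene_id", "kind", "distance", "rho", "fdr",
                 "cnv_driven", "promoter_overlap", "surviving")]
    )
    data.table::fwrite(links_out, outp("links.tsv"), sep = "\t")
    targets <- collapse_targets(promoter_links, distal, expr, cohort)
    data.table::fwrite(targets, outp("target_genes.tsv"), sep = "\t")
  }

  # stage 4: enrichment (optional)
  enrich <- NULL
  if (!is.null(config$gmt) && !is.null(targets) && nrow(targets) > 0) {
    sets <- read_gmt(config$gmt)
    enrich <- tryCatch(
      enrich_by_sign(targets, sets, universe = rownames(expr)),
      error = function(e) {
        warning(sprintf("enrichment skipped: %s", conditionMessage(e)),
                call. = FALSE)
        NULL
      })
    if (!is.null(enrich)) {
      data.table::fwrite(enrich, outp("enrichment.tsv"), sep = "\t")
    }
  }

  # stage 5: survival
  univariate <- NULL
  multi_p <- NULL
  if (!is.null(config$survival) && !is.null(targets) && nrow(targets) > 0 &&
      !is.null(expr)) {
    surv <- read_survival(config$survival)
    feat <- expr[intersect(targets$gene_id, rownames(expr)), , drop = FALSE]
    univariate <- univariate_screen(feat, surv, cohort = cohort)
    data.table::fwrite(univariate, outp("univariate.tsv"), sep = "\t")
    sig_feat <- setdiff(univariate$feature[univariate$significant],
                        "proportion_epi")
    if (length(sig_feat) >= 1L) {
      prop_row <- matrix(cohort$proportion, 1L,
                         dimnames = list("proportion_epi", cohort$sample_id))
      fm <- rbind(feat[sig_feat, , drop = FALSE],
                  prop_row[, colnames(feat), drop = FALSE])
      ms <- tryCatch(multivariate_stratify(fm, surv, seed = config$seed),
                     error = function(e) NULL)
      if (!is.null(ms)) {
        multi_p <- ms$p
        data.table::fwrite(ms$grouping, outp("multivariate_groups.tsv"),
                           sep = "\t")
      }
    }
  }

  report <- list(
    n_samples = nrow(cohort),
    n_low = summ$n_low, n_high = summ$n_high,
    low_fraction = summ$low_fraction,
    n_peaks = counts$n_peaks, n_peaks_tested = counts$n_tested,
    n_significant = counts$n_significant,
    n_positive = counts$n_positive, n_negative = counts$n_negative,
    n_promoter_links = if (is.null(promoter_links)) NA else nrow(promoter_links),
    n_distal_links = if (is.null(distal)) NA else sum(distal$surviving),
    n_target_genes = if (is.null(targets)) NA else nrow(targets),
    n_univariate_significant = if (is.null(univariate)) NA
      else sum(univariate$significant),
    multivariate_logrank_p = multi_p %||% NA,
    seed = config$seed
  )
  jsonlite::write_json(report, outp("report.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  cfg <- config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, outp("resolved_config.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(report)
}

# ---------------------------------------------------------------------------
# command-line interface

parse_cli_args <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      if (grepl("=", key, fixed = TRUE)) {
        kv <- strsplit(key, "=", fixed = TRUE)[[1]]
        out[[kv[1]]] <- paste(kv[-1], collapse = "=")
        i <- i + 1L
      } else {
        if (i == length(args)) stop_invalid("flag --%s lacks a value", key)
        out[[key]] <- args[i + 1L]
        i <- i + 2L
      }
    } else {
      stop_invalid("unexpected argument: %s", a)
    }
  }
  out
}

cli_num <- function(x, default) if (is.null(x)) default else as.numeric(x)

#' Command-line entry point
#'
#' Subcommands: `simulate`, `quantify-image`, `screen`, `link`, `enrich`,
#' `survive`, `run-all`. Each takes `--key value` flags mirroring the
#' corresponding function's arguments; `run-all` takes `--config` pointing
#' at a JSON file of [pipeline_config()] fields (flags override it). Exit
#' status: 0 ok, 2 validation failure, 3 stage error.
#'
#' @param args character vector of arguments (default: the command line).
#' @return integer exit status, invisibly.
#' @export
epistroma_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L) {
    cat("usage: epistroma <simulate|quantify-image|screen|link|enrich|survive|run-all> [--flag value ...]\n")
    return(invisible(2L))
  }
  cmd <- args[1]
  status <- tryCatch({
    opts <- parse_cli_args(args[-1])
    switch(cmd,
      "simulate" = {
        n_peaks <- cli_num(opts$n_peaks, 2000)
        simulate_study(
          n_samples = cli_num(opts$n_samples, 54),
          low_fraction = cli_num(opts$low_fraction, 0.87),
          n_peaks = n_peaks,
          n_genes = cli_num(opts$n_genes, 200),
          n_planted = cli_num(opts$n_planted, min(50, n_peaks %/% 4)),
          n_promoter_links = cli_num(opts$n_promoter_links, 5),
          n_distal_links = cli_num(opts$n_distal_links, 5),
          n_cn_links = cli_num(opts$n_cn_links, 3),
          seed = cli_num(opts$seed, 1),
          out_dir = opts$out %||% "synthetic_study")
        0L
      },
      "quantify-image" = {
        cohort <- if (!is.null(opts$masks)) {
          quantify_masks(opts$masks, cli_num(opts$cutoff, 0.5))
        } else {
          read_cohort(opts$proportions, cli_num(opts$cutoff, 0.5))
        }
        write_cohort(cohort, opts$out %||% "cohort.tsv")
        s <- cohort_summary(cohort, cli_num(opts$cutoff, 0.5))
        cat(sprintf("%d samples: %d low, %d high (low fraction %.3f)\n",
                    nrow(cohort), s$n_low, s$n_high, s$low_fraction))
        0L
      },
      "screen" = {
        acc <- read_matrix_tsv(opts$accessibility)
        cohort <- read_cohort(opts$cohort)
        peaks <- if (!is.null(opts$peaks)) read_peaks(opts$peaks) else NULL
        res <- screen_peaks(acc, cohort, alpha = cli_num(opts$alpha, 0.05),
                            peaks = peaks)
        data.table::fwrite(res, opts$out %||% "screen_results.tsv",
                           sep = "\t")
        cnt <- attr(res, "counts")
        cat(sprintf("%d tested, %d significant (%d positive, %d negative)\n",
                    cnt$n_tested, cnt$n_significant, cnt$n_positive,
                    cnt$n_negative))
        0L
      },
      "link" = {
        peaks <- read_peaks(opts$peaks)
        genes <- read_genes(opts$genes)
        acc <- read_matrix_tsv(opts$accessibility)
        expr <- read_matrix_tsv(opts$expression)
        cn <- if (!is.null(opts$copy_number)) read_matrix_tsv(opts$copy_number)
        screen <- data.table::fread(opts$screen, data.table = FALSE)
        sig <- screen$peak_id[as.logical(screen$significant)]
        prom <- assign_promoter_peaks(peaks[peaks$peak_id %in% sig, ], genes)
        dist <- link_peaks_to_genes(peaks, genes, sig, acc, expr, cn = cn,
                                    fdr_cut = cli_num(opts$fdr, 0.01),
                                    max_dist = cli_num(opts$max_dist, 5e5))
        cohort <- read_cohort(opts$cohort)
        targets <- collapse_targets(prom, dist, expr, cohort)
        data.table::fwrite(targets, opts$out %||% "target_genes.tsv",
                           sep = "\t")
        cat(sprintf("%d promoter links, %d distal links, %d target genes\n",
                    nrow(prom), sum(dist$surviving), nrow(targets)))
        0L
      },
      "enrich" = {
        targets <- data.table::fread(opts$targets, data.table = FALSE)
        sets <- read_gmt(opts$gmt)
        expr <- if (!is.null(opts$expression)) read_matrix_tsv(opts$expression)
        res <- enrich_by_sign(targets, sets,
                              universe = if (!is.null(expr)) rownames(expr))
        data.table::fwrite(res, opts$out %||% "enrichment.tsv", sep = "\t")
        0L
      },
      "survive" = {
        expr <- read_matrix_tsv(opts$expression)
        surv <- read_survival(opts$survival)
        cohort <- if (!is.null(opts$cohort)) read_cohort(opts$cohort)
        res <- univariate_screen(expr, surv, cohort = cohort)
        data.table::fwrite(res, opts$out %||% "univariate.tsv", sep = "\t")
        cat(sprintf("%d / %d features significant at 0.05\n",
                    sum(res$significant), nrow(res)))
        0L
      },
      "run-all" = {
        fields <- if (!is.null(opts$config)) {
          jsonlite::read_json(opts$config, simplifyVector = TRUE)
        } else list()
        fields[names(opts)[names(opts) != "config"]] <-
          opts[names(opts) != "config"]
        numeric_fields <- c("alpha", "distal_fdr", "max_dist",
                            "promoter_upstream", "promoter_proximal",
                            "cutoff", "cnv_attenuation", "rho_cut", "seed")
        for (nf in intersect(names(fields), numeric_fields)) {
          fields[[nf]] <- as.numeric(fields[[nf]])
        }
        cfg <- do.call(pipeline_config, fields)
        findings <- validate_inputs(cfg)
        if (any(findings$level == "fatal")) {
          cat("validation failed:\n")
          cat(sprintf("  [%s] %s\n", findings$level, findings$message))
          return(invisible(2L))
        }
        run_all(cfg)
        0L
      },
      {
        cat(sprintf("unknown subcommand: %s\n", cmd))
        2L
      })
  }, error = function(e) {
    cat(sprintf("error in %s: %s\n", cmd, conditionMessage(e)))
    3L
  })
  invisible(status)
}
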