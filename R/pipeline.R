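# Pipeline orchestration: validated configuration, staged execution and a
# machine-readable run report.

pipeline_defaults <- function() {
  list(
    counts_tsv = NULL, metadata_tsv = NULL, kraken2_reports = NULL,
    annotation_tsv = NULL, phenotype_tsv = NULL,
    out_dir = NULL,
    simulate = FALSE,
    min_total_reads = 100L,
    ra_threshold = 0.005, count_threshold = 10L, presence_rule = "both",
    min_batch_size = 100L, prev_threshold = 0.25, fold = 2,
    rho_threshold = 0.7, min_max_reads = 100L, zero_factor = 0.65,
    excluded_variables = "library_prep_kit",
    filters = c("prevalence", "correlation", "batch", "read_count"),
    n_iter = 1000L,
    network_thresholds = c(0.05, 0.2, 0.3),
    network_cohort_exclude = character(0),
    pooled_network_all_cohorts = TRUE,
    pre_decontam_networks = FALSE,
    sparcc_n_draws = 20L, sparcc_exclusion_iters = 10L,
    sparcc_exclusion_threshold = 0.1, sparcc_pseudocount = 1,
    min_present = 50L,
    min_assigned_reads = 1000L, ptr_threshold = 1.1,
    run_enrichment = TRUE, run_networks = TRUE, run_assoc = TRUE,
    seed = 1L
  )
}

check_range <- function(cfg, key, lo, hi, errs) {
  v <- cfg[[key]]
  if (!is.null(v) && is.numeric(v) && any(v < lo | v > hi)) {
    errs <- c(errs, sprintf("%s must lie in [%g, %g]", key, lo, hi))
  }
  errs
}

#' Validate a pipeline configuration
#'
#' Reads a YAML file (or takes a named list), rejects unknown keys, checks
#' ranges, and fills defaults. Every default matches the method's standard
#' thresholds (presence at RA > 0.005 and reads > 10; sample QC at 100
#' reads; prevalence filter at 25% and twofold with 100-sample batches;
#' correlation at rho 0.7; read-count floor 100; 1000 randomization
#' iterations; network thresholds 0.05/0.2/0.3; association screen at 50
#' present samples; replication eligibility at 1000 reads).
#'
#' @param config Path to a YAML file, or a named list of overrides (an
#'   empty/missing file yields all defaults).
#' @return Validated configuration list.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defaults))
  errs <- character(0)
  if (length(unknown) > 0L) {
    errs <- c(errs, paste("unknown config key(s):", paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(defaults, config[setdiff(names(config), unknown)])
  errs <- check_range(cfg, "ra_threshold", 0, 1, errs)
  errs <- check_range(cfg, "prev_threshold", 0, 1, errs)
  errs <- check_range(cfg, "rho_threshold", 0, 1, errs)
  errs <- check_range(cfg, "network_thresholds", 0, 1 - 1e-12, errs)
  errs <- check_range(cfg, "zero_factor", 1e-12, 1, errs)
  for (key in c("count_threshold", "min_total_reads", "min_batch_size",
                "min_max_reads", "n_iter", "min_present",
                "min_assigned_reads")) {
    if (!is.numeric(cfg[[key]]) || cfg[[key]] < 0) {
      errs <- c(errs, sprintf("%s must be a non-negative number", key))
    }
  }
  if (!cfg$presence_rule %in% c("both", "either")) {
    errs <- c(errs, "presence_rule must be 'both' or 'either'")
  }
  if (length(errs) > 0L) stop("invalid configuration:\n  ",
                              paste(errs, collapse = "\n  "))
  cfg
}

log_stage <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full analysis pipeline
#'
#' Executes ingestion/QC, presence calling, decontamination, annotation
#' enrichment (when an annotation table is given), co-occurrence networks,
#' and the phenotype association screen (when phenotypes are given),
#' writing artifacts under `config$out_dir` and returning a run report.
#' Given identical inputs, configuration and seed, the report (and its JSON
#' serialization) is identical between runs.
#'
#' @param config Validated configuration (see [validate_config()]). Inputs
#'   come either from files (`counts_tsv`, `metadata_tsv`, ...) or, with
#'   `simulate = TRUE`, from [simulate_cohort_counts()] under the
#'   configured seed.
#' @param counts,meta,pheno,annotation_db Optional in-memory inputs that
#'   take precedence over file paths.
#' @return A `run_report` list; also written as `run_report.json` when
#'   `out_dir` is set.
#' @export
run_pipeline <- function(config = validate_config(), counts = NULL,
                         meta = NULL, pheno = NULL, annotation_db = NULL) {
  cfg <- config
  truth <- NULL
  if (is.null(counts)) {
    if (isTRUE(cfg$simulate)) {
      sim <- simulate_cohort_counts(simulation_config(seed = cfg$seed))
      counts <- sim$counts; meta <- sim$meta; truth <- sim$truth
    } else if (!is.null(cfg$counts_tsv)) {
      counts <- read_count_matrix_tsv(cfg$counts_tsv)
    } else if (!is.null(cfg$kraken2_reports)) {
      counts <- build_count_matrix(lapply(cfg$kraken2_reports, parse_kraken2_report))
    } else {
      stop("stage ingest: no counts input (counts_tsv, kraken2_reports or simulate)")
    }
  }
  if (is.null(meta)) {
    if (is.null(cfg$metadata_tsv)) stop("stage ingest: no batch metadata")
    meta <- read_batch_metadata(cfg$metadata_tsv)
  }
  report <- list(config = cfg[order(names(cfg))], seed = cfg$seed,
                 tool = "bloodsift",
                 version = as.character(utils::packageVersion("bloodsift")))

  # QC
  n0 <- nrow(counts)
  counts <- qc_samples(counts, cfg$min_total_reads)
  if (nrow(counts) == 0L) stop("stage qc: no samples survive QC")
  report$qc <- list(samples_in = n0, samples_kept = nrow(counts),
                    species = ncol(counts))
  log_stage("qc", "%d/%d samples kept, %d species", nrow(counts), n0, ncol(counts))

  # presence
  presence <- call_presence(counts, cfg$ra_threshold, cfg$count_threshold,
                            cfg$presence_rule)
  report$presence <- list(present_entries = sum(presence$present),
                          species_detected = sum(colSums(presence$present) > 0))
  log_stage("presence", "%d present entries", sum(presence$present))

  # decontamination
  dconf <- decontam_config(excluded_variables = cfg$excluded_variables,
                           min_batch_size = cfg$min_batch_size,
                           prev_threshold = cfg$prev_threshold, fold = cfg$fold,
                           rho_threshold = cfg$rho_threshold,
                           min_max_reads = cfg$min_max_reads,
                           zero_factor = cfg$zero_factor,
                           filters = cfg$filters)
  decon <- run_decontamination(presence, meta, dconf)
  report$decontamination <- list(
    species_before = decon$species_before,
    species_after_each_filter = as.list(decon$species_after_each_filter),
    n_calls = nrow(decon$calls),
    n_survivors = length(decon$survivors))
  log_stage("decontam", "%d -> %d species (%d calls)", decon$species_before,
            length(decon$survivors), nrow(decon$calls))

  # enrichment
  if (isTRUE(cfg$run_enrichment)) {
    if (is.null(annotation_db) && !is.null(cfg$annotation_tsv)) {
      annotation_db <- read_annotation_db(cfg$annotation_tsv)
    }
    if (!is.null(annotation_db) && length(decon$survivors) > 0L) {
      pre <- colnames(presence$present)
      enr <- lapply(
        list(c("likely_contaminant", "less"),
             c("in_blood_culture", "greater"),
             c("human_associated", "greater")),
        function(cd) {
          rt <- randomization_test(pre, decon$survivors, annotation_db,
                                   cd[1L], cd[2L], n_iter = cfg$n_iter,
                                   seed = derive_seed(cfg$seed, 11L))
          list(category = cd[1L], direction = cd[2L],
               observed = rt$observed_proportion,
               null_mean = mean(rt$null_proportions), p = rt$p_value)
        })
      report$enrichment <- enr
      log_stage("enrich", "%d randomization tests (%d iterations)", length(enr),
                cfg$n_iter)
    }
  }

  # networks
  if (isTRUE(cfg$run_networks) && length(decon$survivors) >= 4L) {
    nets <- tryCatch({
      net_counts <- select_network_samples(presence, decon$survivors)
      corr <- sparcc(net_counts, cfg$sparcc_exclusion_iters,
                     cfg$sparcc_exclusion_threshold, cfg$sparcc_pseudocount,
                     cfg$sparcc_n_draws, seed = derive_seed(cfg$seed, 21L))
      lapply(cfg$network_thresholds, function(th) build_network(corr, th))
    }, error = function(e) {
      log_stage("network", "skipped: %s", conditionMessage(e))
      NULL
    })
    if (!is.null(nets)) {
      report$networks <- lapply(seq_along(nets), function(i) {
        list(threshold = cfg$network_thresholds[i], n_edges = nrow(nets[[i]]$edges))
      })
      log_stage("network", "edge counts: %s",
                paste(vapply(nets, function(nw) nrow(nw$edges), integer(1)),
                      collapse = ", "))
    }
  }

  # associations
  if (isTRUE(cfg$run_assoc)) {
    if (is.null(pheno) && !is.null(cfg$phenotype_tsv)) {
      if (!file.exists(cfg$phenotype_tsv)) {
        stop("stage assoc: phenotype file not found: ", cfg$phenotype_tsv)
      }
      pheno <- read_phenotypes(cfg$phenotype_tsv)
    }
    if (!is.null(pheno) && length(decon$survivors) > 0L) {
      scr <- run_association_screen(presence, pheno,
                                    species = decon$survivors,
                                    min_present = cfg$min_present,
                                    seed = derive_seed(cfg$seed, 31L))
      n_sig <- sum(!is.na(scr$results$p_adjusted) & scr$results$p_adjusted < 0.05)
      report$associations <- list(n_tests = nrow(scr$results),
                                  n_significant = n_sig,
                                  n_skipped = nrow(scr$skipped))
      log_stage("assoc", "%d tests, %d significant", nrow(scr$results), n_sig)
    } else if (!is.null(cfg$phenotype_tsv) || !is.null(pheno)) {
      report$associations <- list(n_tests = 0L, n_significant = 0L)
    }
  }

  class(report) <- "run_report"
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_matrix_tsv(presence$zeroed_counts,
                     file.path(cfg$out_dir, "zeroed_counts.tsv"))
    write_matrix_tsv(presence$present, file.path(cfg$out_dir, "presence.tsv"))
    write_decontam_report(decon,
                          json_path = file.path(cfg$out_dir, "decontam.json"),
                          tsv_path = file.path(cfg$out_dir, "contaminant_calls.tsv"))
    if (!is.null(truth)) write_truth(truth, file.path(cfg$out_dir, "truth.json"))
    removed <- attr(counts, "qc_removed")
    if (!is.null(removed)) {
      utils::write.table(removed, file.path(cfg$out_dir, "qc_removed.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(unclass(report),
                         file.path(cfg$out_dir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("bloodsift run report\n")
  cat(sprintf("  samples: %d kept of %d; species: %d\n",
              x$qc$samples_kept, x$qc$samples_in, x$qc$species))
  if (!is.null(x$decontamination)) {
    cat(sprintf("  decontamination: %d -> %d species\n",
                x$decontamination$species_before, x$decontamination$n_survivors))
  }
  if (!is.null(x$associations)) {
    cat(sprintf("  associations: %d tests, %d significant\n",
                x$associations$n_tests, x$associations$n_significant))
  }
  invisible(x)
}
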