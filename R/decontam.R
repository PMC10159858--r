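# Batch-aware decontamination: four sequential filters over a
# presence-called count matrix (batch prevalence, within-batch CLR
# correlation, multi-batch detection, maximum read count).

new_call <- function(species, filter, batch_variable = NA_character_,
                     batch_label = NA_character_, evidence = list()) {
  list(species = species, filter = filter, batch_variable = batch_variable,
       batch_label = batch_label, evidence = evidence)
}

calls_to_df <- function(calls) {
  if (length(calls) == 0L) {
    return(data.frame(species = character(0), filter = character(0),
                      batch_variable = character(0), batch_label = character(0),
                      evidence = character(0), stringsAsFactors = FALSE))
  }
  data.frame(
    species = vapply(calls, `[[`, character(1), "species"),
    filter = vapply(calls, `[[`, character(1), "filter"),
    batch_variable = vapply(calls, `[[`, character(1), "batch_variable"),
    batch_label = vapply(calls, `[[`, character(1), "batch_label"),
    evidence = vapply(calls, function(cl) {
      ev <- cl$evidence
      paste(sprintf("%s=%s", names(ev),
                    vapply(ev, function(v) paste(format(v, digits = 6), collapse = ","),
                           character(1))),
            collapse = ";")
    }, character(1)),
    stringsAsFactors = FALSE
  )
}

#' Species prevalence within each batch of a metadata variable
#'
#' @param presence A `presence_matrix` (see [call_presence()]).
#' @param meta Batch metadata data.frame with a `sample_id` column.
#' @param variable Name of the batch variable.
#' @return data.frame of (species, batch_label, prevalence, n_samples),
#'   listing every batch even when prevalence is zero.
#' @export
prevalence_by_batch <- function(presence, meta, variable) {
  pm <- presence$present
  meta <- align_metadata(meta, rownames(pm))
  if (!variable %in% names(meta)) {
    stop("unknown batch variable: ", variable)
  }
  labels <- as.character(meta[[variable]])
  if (any(!nzchar(labels)) || anyNA(labels)) {
    stop("empty batch labels for variable ", variable)
  }
  batches <- sort(unique(labels))
  res <- lapply(batches, function(b) {
    rows <- labels == b
    data.frame(species = colnames(pm),
               batch_label = b,
               prevalence = colMeans(pm[rows, , drop = FALSE]),
               n_samples = sum(rows),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, res)
}

#' Batch-prevalence contaminant filter
#'
#' A species is called a contaminant specific to a batch when it is present
#' at greater than `prev_threshold` prevalence in that batch and its
#' prevalence there is more than `fold` times its prevalence in every other
#' eligible batch of the same variable. Batches with fewer than
#' `min_batch_size` samples are excluded from both sides of the comparison.
#'
#' @param presence A `presence_matrix`.
#' @param meta Batch metadata.
#' @param variables Character vector of batch variables to scan.
#' @param min_batch_size Minimum batch size for eligibility (default 100).
#' @param prev_threshold Prevalence a contaminant must exceed in its home
#'   batch (default 0.25).
#' @param fold Required fold-change over every other batch (default 2; a
#'   positive prevalence always exceeds `fold` times a zero prevalence).
#' @param candidates Optional subset of species to evaluate.
#' @return List of contaminant calls with evidence
#'   (prevalence_in_batch, max_other_prevalence, n_samples).
#' @export
prevalence_filter <- function(presence, meta, variables,
                              min_batch_size = 100L, prev_threshold = 0.25,
                              fold = 2, candidates = NULL) {
  if (min_batch_size < 1L) stop("min_batch_size must be >= 1")
  pm <- presence$present
  if (!is.null(candidates)) pm <- pm[, candidates, drop = FALSE]
  meta <- align_metadata(meta, rownames(pm))
  calls <- list()
  any_eligible <- FALSE
  for (v in variables) {
    tab <- table(as.character(meta[[v]]))
    eligible <- names(tab)[tab >= min_batch_size]
    if (length(eligible) < 2L) {
      warning(sprintf("variable '%s': fewer than 2 batches with >= %d samples; skipped",
                      v, min_batch_size))
      next
    }
    any_eligible <- TRUE
    labels <- as.character(meta[[v]])
    prev <- vapply(eligible, function(b) colMeans(pm[labels == b, , drop = FALSE]),
                   numeric(ncol(pm)))
    if (ncol(pm) == 1L) prev <- matrix(prev, nrow = 1L, dimnames = list(colnames(pm), eligible))
    # prev: species x eligible batches
    for (bi in seq_along(eligible)) {
      others <- prev[, -bi, drop = FALSE]
      max_other <- apply(others, 1L, max)
      hit <- prev[, bi] > prev_threshold & prev[, bi] > fold * max_other
      for (s in colnames(pm)[hit]) {
        calls[[length(calls) + 1L]] <- new_call(
          s, "prevalence", v, eligible[bi],
          evidence = list(prevalence_in_batch = unname(prev[s, bi]),
                          max_other_prevalence = unname(max_other[s]),
                          n_samples = unname(sum(labels == eligible[bi]))))
      }
    }
  }
  if (!any_eligible) {
    warning("no batch variable had >= 2 eligible batches; no prevalence calls made")
  }
  calls
}

#' Centred log-ratio transform of relative abundances
#'
#' Zeros are replaced before taking logs; the default multiplicative simple
#' replacement substitutes `zero_factor` times the smallest nonzero relative
#' abundance in the matrix.
#'
#' @param abund samples x species relative abundance matrix.
#' @param zero_factor Multiplier applied to the smallest nonzero abundance
#'   to replace zeros (default 0.65).
#' @return Matrix of CLR values; every row sums to zero.
#' @export
clr_transform <- function(abund, zero_factor = 0.65) {
  if (ncol(abund) < 2L) stop("CLR transform needs at least 2 species")
  if (any(rowSums(abund) == 0)) {
    stop("cannot CLR-transform rows that are entirely zero")
  }
  nz <- abund[abund > 0]
  repl <- zero_factor * min(nz)
  x <- abund
  x[x == 0] <- repl
  lx <- log(x)
  lx - rowMeans(lx)
}

#' Within-batch correlation contaminant filter
#'
#' A species is called a contaminant when its CLR-transformed abundances
#' have Spearman's rho above `rho_threshold` with any prevalence-filter
#' contaminant, computed over the samples of that contaminant's batch only.
#'
#' @param abund samples x species relative abundance matrix.
#' @param meta Batch metadata.
#' @param seed_calls Contaminant calls from [prevalence_filter()].
#' @param rho_threshold Spearman correlation a candidate must exceed
#'   (strictly) to be called (default 0.7).
#' @param candidates Species to evaluate (default: all species in `abund`
#'   not among the seeds).
#' @param zero_factor Passed to [clr_transform()].
#' @return List of contaminant calls with evidence (rho, partner_species).
#' @export
correlation_filter <- function(abund, meta, seed_calls, rho_threshold = 0.7,
                               candidates = NULL, zero_factor = 0.65) {
  seed_df <- calls_to_df(seed_calls)
  seed_species <- unique(seed_df$species)
  if (is.null(candidates)) {
    candidates <- setdiff(colnames(abund), seed_species)
  } else {
    candidates <- setdiff(candidates, seed_species)
  }
  if (length(candidates) == 0L || length(seed_calls) == 0L) return(list())
  meta <- align_metadata(meta, rownames(abund))
  clr <- clr_transform(abund, zero_factor = zero_factor)
  calls <- list()
  called <- character(0)
  groups <- unique(seed_df[, c("batch_variable", "batch_label")])
  for (g in seq_len(nrow(groups))) {
    v <- groups$batch_variable[g]
    b <- groups$batch_label[g]
    rows <- as.character(meta[[v]]) == b
    seeds_here <- unique(seed_df$species[seed_df$batch_variable == v &
                                           seed_df$batch_label == b])
    if (sum(rows) < 3L) {
      warning(sprintf("batch %s=%s has < 3 samples; correlation filter skipped there", v, b))
      next
    }
    cand <- setdiff(candidates, called)
    if (length(cand) == 0L) break
    rho <- stats::cor(clr[rows, cand, drop = FALSE],
                      clr[rows, seeds_here, drop = FALSE],
                      method = "spearman")
    for (s in cand) {
      j <- which.max(rho[s, ])
      if (!is.na(rho[s, j]) && rho[s, j] > rho_threshold) {
        calls[[length(calls) + 1L]] <- new_call(
          s, "correlation", v, b,
          evidence = list(rho = unname(rho[s, j]),
                          partner_species = seeds_here[j]))
        called <- c(called, s)
      }
    }
  }
  calls
}

#' Multi-batch detection filter
#'
#' A genuine species must be detected in samples spanning at least two
#' batches of every (non-excluded) batch variable; a species whose
#' detections all fall in a single batch of any variable is called a
#' contaminant. Species detected in zero samples are called as the
#' degenerate single-batch case.
#'
#' @param presence A `presence_matrix`.
#' @param meta Batch metadata.
#' @param variables Batch variables to require multi-batch detection for.
#' @param excluded_variables Variables to leave out of the requirement
#'   (e.g. a library preparation kit used for most samples).
#' @param candidates Species to evaluate (default all).
#' @return List of contaminant calls with evidence (n_batches_detected).
#' @export
batch_filter <- function(presence, meta, variables,
                         excluded_variables = character(0), candidates = NULL) {
  vars <- setdiff(variables, excluded_variables)
  if (length(vars) == 0L) stop("all batch variables are excluded")
  pm <- presence$present
  if (!is.null(candidates)) pm <- pm[, candidates, drop = FALSE]
  meta <- align_metadata(meta, rownames(pm))
  calls <- list()
  n_present <- colSums(pm)
  for (s in colnames(pm)) {
    if (n_present[s] == 0L) {
      calls[[length(calls) + 1L]] <- new_call(
        s, "batch", evidence = list(n_batches_detected = 0,
                                    note = "not detected in any sample"))
      next
    }
    rows <- pm[, s]
    for (v in vars) {
      labs <- unique(as.character(meta[[v]][rows]))
      if (length(labs) <= 1L) {
        calls[[length(calls) + 1L]] <- new_call(
          s, "batch", v, labs[1L],
          evidence = list(n_batches_detected = length(labs)))
        break
      }
    }
  }
  calls
}

#' Maximum read-count artifact filter
#'
#' Species never assigned at least `min_max_reads` read pairs in any single
#' sample are called artifacts.
#'
#' @param zeroed_counts Count matrix with absent entries zeroed
#'   (from [call_presence()]).
#' @param min_max_reads Minimum per-sample read count a species must reach
#'   at least once (default 100, inclusive).
#' @param candidates Species to evaluate (default all).
#' @return List of contaminant calls with evidence (max_reads).
#' @export
read_count_filter <- function(zeroed_counts, min_max_reads = 100L,
                              candidates = NULL) {
  m <- zeroed_counts
  if (!is.null(candidates)) m <- m[, candidates, drop = FALSE]
  mx <- apply(m, 2L, max)
  lapply(names(mx)[mx < min_max_reads], function(s) {
    new_call(s, "read_count", evidence = list(max_reads = unname(mx[s])))
  })
}

#' Default decontamination configuration
#'
#' @param variables Batch variables used by the prevalence and batch
#'   filters (default: all metadata columns except `sample_id`).
#' @param excluded_variables Variables exempt from the multi-batch
#'   requirement (default `"library_prep_kit"`).
#' @param min_batch_size,prev_threshold,fold,rho_threshold,min_max_reads,zero_factor
#'   Filter parameters; see the individual filters.
#' @param filters Character vector of stages to run, in order.
#' @return A named list of settings for [run_decontamination()].
#' @export
decontam_config <- function(variables = NULL,
                            excluded_variables = "library_prep_kit",
                            min_batch_size = 100L, prev_threshold = 0.25,
                            fold = 2, rho_threshold = 0.7,
                            min_max_reads = 100L, zero_factor = 0.65,
                            filters = c("prevalence", "correlation", "batch",
                                        "read_count")) {
  list(variables = variables, excluded_variables = excluded_variables,
       min_batch_size = min_batch_size, prev_threshold = prev_threshold,
       fold = fold, rho_threshold = rho_threshold,
       min_max_reads = min_max_reads, zero_factor = zero_factor,
       filters = filters)
}

#' Run the four decontamination filters in sequence
#'
#' Stages run in the order prevalence, correlation, batch, read count; each
#' stage evaluates only the survivors of the previous one, and a species
#' called anywhere is removed globally.
#'
#' @param presence A `presence_matrix`.
#' @param meta Batch metadata.
#' @param config Settings from [decontam_config()].
#' @return A `decontam_report`: list with `calls` (data.frame), `survivors`,
#'   `species_before`, `species_after_each_filter` (named, one entry per
#'   stage run), and the config used.
#' @export
run_decontamination <- function(presence, meta, config = decontam_config()) {
  variables <- config$variables
  if (is.null(variables)) variables <- setdiff(names(meta), "sample_id")
  species <- colnames(presence$present)
  survivors <- species
  all_calls <- list()
  after <- integer(0)
  seed_calls <- list()
  for (f in config$filters) {
    calls <- switch(
      f,
      prevalence = {
        seed_calls <- prevalence_filter(
          presence, meta, variables,
          min_batch_size = config$min_batch_size,
          prev_threshold = config$prev_threshold,
          fold = config$fold, candidates = survivors)
        seed_calls
      },
      correlation = correlation_filter(
        presence$abundance, meta, seed_calls,
        rho_threshold = config$rho_threshold,
        candidates = survivors, zero_factor = config$zero_factor),
      batch = batch_filter(
        presence, meta, variables,
        excluded_variables = config$excluded_variables,
        candidates = survivors),
      read_count = read_count_filter(
        presence$zeroed_counts, min_max_reads = config$min_max_reads,
        candidates = survivors),
      stop("unknown filter: ", f)
    )
    flagged <- unique(vapply(calls, `[[`, character(1), "species"))
    survivors <- setdiff(survivors, flagged)
    after[f] <- length(survivors)
    all_calls <- c(all_calls, calls)
  }
  structure(list(calls = calls_to_df(all_calls),
                 calls_raw = all_calls,
                 species_before = length(species),
                 species_after_each_filter = after,
                 survivors = survivors,
                 config = config),
            class = "decontam_report")
}

#' @export
print.decontam_report <- function(x, ...) {
  cat(sprintf("decontam_report: %d species before filtering\n", x$species_before))
  for (f in names(x$species_after_each_filter)) {
    cat(sprintf("  after %-11s: %d species\n", f, x$species_after_each_filter[[f]]))
  }
  cat(sprintf("  %d contaminant calls, %d survivors\n",
              nrow(x$calls), length(x$survivors)))
  invisible(x)
}

#' Write a decontamination report to disk
#'
#' Serializes the report as JSON (calls, per-stage counts, survivors) and
#' the calls as a flat TSV.
#'
#' @param report A `decontam_report`.
#' @param json_path,tsv_path Output paths (either may be `NULL` to skip).
#' @export
write_decontam_report <- function(report, json_path = NULL, tsv_path = NULL) {
  if (!is.null(json_path)) {
    obj <- list(species_before = report$species_before,
                species_after_each_filter = as.list(report$species_after_each_filter),
                survivors = report$survivors,
                calls = report$calls)
    jsonlite::write_json(obj, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  if (!is.null(tsv_path)) {
    utils::write.table(report$calls, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(report)
}
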