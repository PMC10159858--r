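# Ingestion of taxonomic profiles, sample QC, relative abundance and
# presence calling.

#' Parse a Kraken2 report into a species-level sample profile
#'
#' Reads a standard 6-column Kraken2 report (percentage, clade read count,
#' direct read count, rank code, taxid, name; 8-column reports with
#' minimizer data are also accepted) and extracts species-level counts.
#' Species counts use the clade-level column so that reads assigned to
#' subspecies/strain nodes roll up to their parent species.
#'
#' @param path Path to a Kraken2 report file.
#' @param sample_id Sample identifier; defaults to the file name without
#'   extension.
#' @return A list with elements `sample_id` and `counts`, the latter a named
#'   integer vector (species name -> clade read pairs). An empty file yields
#'   an empty profile.
#' @export
parse_kraken2_report <- function(path, sample_id = NULL) {
  if (is.null(sample_id)) {
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(list(sample_id = sample_id, counts = integer(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(!(nf %in% c(6L, 8L)))
  if (length(bad) > 0L) {
    stop(sprintf("malformed Kraken2 report '%s': expected 6 or 8 columns, got %d on line %d",
                 path, nf[bad[1L]], bad[1L]))
  }
  counts <- integer(0)
  nms <- character(0)
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    n <- length(f)
    rank <- f[n - 2L]
    if (identical(rank, "S")) {
      clade <- suppressWarnings(as.integer(f[2L]))
      if (is.na(clade)) {
        stop(sprintf("malformed Kraken2 report '%s': non-integer clade count on line %d",
                     path, i))
      }
      counts <- c(counts, clade)
      nms <- c(nms, trimws(f[n], which = "left"))
    }
  }
  names(counts) <- nms
  if (anyDuplicated(nms)) {
    stop(sprintf("duplicate species names in report '%s'", path))
  }
  list(sample_id = sample_id, counts = counts)
}

#' Assemble sample profiles into a samples x species count matrix
#'
#' @param profiles A list of profiles as returned by
#'   [parse_kraken2_report()].
#' @return An integer matrix with samples as rows and species as columns
#'   (the union of species over all profiles); entries missing from a
#'   profile are zero.
#' @export
build_count_matrix <- function(profiles) {
  ids <- vapply(profiles, function(p) p$sample_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate sample_id in profiles: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  species <- sort(unique(unlist(lapply(profiles, function(p) names(p$counts)))))
  mat <- matrix(0L, nrow = length(ids), ncol = length(species),
                dimnames = list(ids, species))
  for (p in profiles) {
    if (length(p$counts) > 0L) {
      mat[p$sample_id, names(p$counts)] <- as.integer(p$counts)
    }
  }
  mat
}

#' Per-sample total microbial read pairs
#'
#' @param counts samples x species count matrix.
#' @return Named numeric vector of row sums.
#' @export
total_reads <- function(counts) {
  rowSums(counts)
}

#' Remove samples with too few microbial reads
#'
#' Samples with fewer than `min_total` microbial read pairs are dropped.
#' Species columns that become all-zero are retained; downstream filters
#' deal with them.
#'
#' @param counts samples x species count matrix.
#' @param min_total Minimum total microbial read pairs for a sample to be
#'   kept (default 100; samples with exactly `min_total` reads are kept).
#' @return The filtered count matrix, with a `qc_removed` attribute naming
#'   the removed samples and their totals.
#' @export
qc_samples <- function(counts, min_total = 100L) {
  tot <- rowSums(counts)
  keep <- tot >= min_total
  out <- counts[keep, , drop = FALSE]
  removed <- data.frame(sample_id = rownames(counts)[!keep],
                        total_reads = unname(tot[!keep]),
                        reason = rep(sprintf("fewer than %d microbial read pairs", min_total),
                                     sum(!keep)),
                        stringsAsFactors = FALSE)
  attr(out, "qc_removed") <- removed
  out
}

#' Relative abundances from counts
#'
#' Divides each species count by the sample's total microbial read count.
#'
#' @param counts samples x species count matrix with strictly positive row
#'   totals (run [qc_samples()] first).
#' @return Numeric matrix of relative abundances; rows sum to 1.
#' @export
relative_abundance <- function(counts) {
  tot <- rowSums(counts)
  if (any(tot == 0)) {
    stop("sample(s) with zero total microbial reads: ",
         paste(utils::head(rownames(counts)[tot == 0], 5), collapse = ", "),
         " (run qc_samples first)")
  }
  counts / tot
}

#' Call species presence per sample
#'
#' A species is counted as absent in a sample when its abundance falls at or
#' below the thresholds; with the default conjunctive rule it is present
#' only if BOTH its read-pair count exceeds `count_threshold` AND its
#' relative abundance exceeds `ra_threshold`. Relative abundances are
#' computed once from the input counts and are not recomputed after
#' zeroing, so the denominator stays the sample's original microbial total.
#'
#' @param counts samples x species count matrix (post-QC).
#' @param ra_threshold Relative abundance at or below which a species is
#'   absent (default 0.005).
#' @param count_threshold Read-pair count at or below which a species is
#'   absent (default 10).
#' @param rule `"both"` (default): presence requires both thresholds to be
#'   exceeded. `"either"`: presence requires either threshold to be
#'   exceeded (absence only when both fail).
#' @return An object of class `presence_matrix`: a list with `present`
#'   (logical matrix), `zeroed_counts` (counts with absent entries set to
#'   0), `abundance` (pre-zeroing relative abundances), `totals`, and the
#'   thresholds used.
#' @export
call_presence <- function(counts, ra_threshold = 0.005, count_threshold = 10L,
                          rule = c("both", "either")) {
  rule <- match.arg(rule)
  if (ra_threshold < 0 || count_threshold < 0) {
    stop("presence thresholds must be non-negative")
  }
  abund <- relative_abundance(counts)
  pass_reads <- counts > count_threshold
  pass_ra <- abund > ra_threshold
  present <- if (rule == "both") pass_reads & pass_ra else pass_reads | pass_ra
  zeroed <- counts
  zeroed[!present] <- 0L
  structure(list(present = present,
                 zeroed_counts = zeroed,
                 abundance = abund,
                 totals = rowSums(counts),
                 ra_threshold = ra_threshold,
                 count_threshold = count_threshold,
                 rule = rule),
            class = "presence_matrix")
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat(sprintf("presence_matrix: %d samples x %d species\n",
              nrow(x$present), ncol(x$present)))
  cat(sprintf("  thresholds: reads > %d AND/OR RA > %g (rule = %s)\n",
              x$count_threshold, x$ra_threshold, x$rule))
  cat(sprintf("  present entries: %d (%.2f%% of matrix)\n",
              sum(x$present), 100 * mean(x$present)))
  invisible(x)
}

#' Read a samples x species count matrix from TSV
#'
#' Expects a header row of species names and a first column of sample
#' identifiers.
#'
#' @param path Path to the TSV file.
#' @return Integer count matrix.
#' @export
read_count_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) stop("duplicate sample identifiers in ", path)
  mat <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(mat)) stop("non-numeric counts in ", path)
  if (any(mat < 0)) stop("negative counts in ", path)
  storage.mode(mat) <- "integer"
  rownames(mat) <- ids
  mat
}

#' Write a count (or presence) matrix to TSV
#'
#' @param mat Matrix with sample rownames and species colnames; logical
#'   matrices are written as 0/1.
#' @param path Output path.
#' @export
write_matrix_tsv <- function(mat, path) {
  m <- mat
  if (is.logical(m)) {
    storage.mode(m) <- "integer"
  }
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-sample batch metadata
#'
#' @param path TSV with a `sample_id` column plus one column per batch
#'   variable (e.g. cohort, extraction kit, flow cell).
#' @return data.frame with `sample_id` as character and one column per
#'   batch variable.
#' @export
read_batch_metadata <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!"sample_id" %in% names(df)) stop("metadata must have a sample_id column")
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in metadata")
  df
}

# Align metadata rows to the sample order of a matrix; error when samples
# lack metadata.
align_metadata <- function(meta, sample_ids) {
  idx <- match(sample_ids, meta$sample_id)
  if (anyNA(idx)) {
    stop("samples missing from batch metadata: ",
         paste(utils::head(sample_ids[is.na(idx)], 5), collapse = ", "))
  }
  meta[idx, , drop = FALSE]
}
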