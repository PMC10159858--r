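# Coverage breadth, peak-to-trough replication-ratio estimation with
# Ori/Ter localization, and cumulative GC-skew cross-validation.

#' Construct a coverage track
#'
#' @param depth Non-negative depth values, one per position (or per bin when
#'   `bin_size > 1`).
#' @param genome_id Genome identifier.
#' @param bin_size Width in bp represented by each depth value (1 for
#'   per-position tracks).
#' @param length Genome length in bp (default `length(depth) * bin_size`).
#' @param circular Whether the genome is circular (default `TRUE`).
#' @return A `coverage_track` object.
#' @export
coverage_track <- function(depth, genome_id = "genome", bin_size = 1L,
                           length = base::length(depth) * bin_size,
                           circular = TRUE) {
  if (any(depth < 0)) stop("depth must be non-negative")
  structure(list(genome_id = genome_id, length = length,
                 depth = as.numeric(depth), bin_size = as.integer(bin_size),
                 circular = circular),
            class = "coverage_track")
}

#' Read a coverage track from bedGraph or position/depth TSV
#'
#' Accepts 2-column (1-based position, depth), 3-column (start, end, depth)
#' or 4-column bedGraph (chrom, 0-based start, end, depth) text files;
#' interval forms are expanded to per-position depth.
#'
#' @param path Input file.
#' @param genome_id Genome identifier (default: file name; for bedGraph the
#'   chrom field is used).
#' @return A `coverage_track` with `bin_size = 1`.
#' @export
read_coverage <- function(path, genome_id = NULL) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          comment.char = "#")
  if (is.character(df[[1L]]) && tolower(df[1L, 1L]) %in% c("position", "pos", "chrom")) {
    df <- df[-1L, , drop = FALSE]
    for (j in seq_along(df)) {
      sup <- suppressWarnings(as.numeric(df[[j]]))
      if (!all(is.na(sup))) df[[j]] <- sup
    }
  }
  if (ncol(df) == 2L) {
    pos <- as.integer(df[[1L]]); dep <- as.numeric(df[[2L]])
    gl <- max(pos)
    depth <- numeric(gl)
    depth[pos] <- dep
    gid <- if (is.null(genome_id)) sub("\\.[^.]*$", "", basename(path)) else genome_id
  } else if (ncol(df) %in% c(3L, 4L)) {
    off <- ncol(df) - 3L   # bedGraph has a leading chrom column
    start <- as.integer(df[[off + 1L]])
    end <- as.integer(df[[off + 2L]])
    dep <- as.numeric(df[[off + 3L]])
    zero_based <- ncol(df) == 4L
    gl <- max(end)
    depth <- numeric(gl)
    for (i in seq_len(nrow(df))) {
      from <- if (zero_based) start[i] + 1L else start[i]
      depth[from:end[i]] <- dep[i]
    }
    gid <- if (!is.null(genome_id)) genome_id
           else if (ncol(df) == 4L) as.character(df[1L, 1L])
           else sub("\\.[^.]*$", "", basename(path))
  } else {
    stop("unrecognized coverage format (expected 2, 3 or 4 columns): ", path)
  }
  coverage_track(depth, genome_id = gid)
}

#' Fraction of genome positions covered by at least one read
#'
#' @param track A per-position `coverage_track`.
#' @return Coverage breadth in `[0, 1]`.
#' @export
coverage_breadth <- function(track) {
  if (length(track$depth) == 0L) stop("empty coverage track")
  if (track$bin_size != 1L) {
    stop("coverage breadth needs a per-position track (bin_size = 1)")
  }
  mean(track$depth >= 1)
}

# Circular running median over a numeric vector.
circular_runmed <- function(x, window) {
  n <- length(x)
  half <- window %/% 2L
  padded <- c(x[(n - half + 1L):n], x, x[1L:half])
  vapply(seq_len(n), function(i) stats::median(padded[i:(i + window - 1L)]),
         numeric(1))
}

#' Bin a coverage track and smooth with a circular running median
#'
#' Depth is averaged within `bin_size` windows and the per-bin means are
#' median-smoothed with a window that wraps around the origin, preserving
#' the sinusoidal replication signal while suppressing local spikes.
#'
#' @param track A `coverage_track` (per-position, or pre-binned with a
#'   bin size that divides `bin_size`).
#' @param bin_size Bin width in bp (default 10000).
#' @param median_window_bins Circular running-median window in bins
#'   (default 11, must be odd).
#' @return A `coverage_track` with `bin_size = bin_size` holding the
#'   smoothed per-bin depths.
#' @export
bin_and_smooth <- function(track, bin_size = 10000L, median_window_bins = 11L) {
  if (median_window_bins %% 2L == 0L) stop("median_window_bins must be odd")
  if (track$length < 2 * bin_size * median_window_bins) {
    stop(sprintf("genome too short (%d bp) for bin_size %d and window %d; use smaller bins",
                 track$length, bin_size, median_window_bins))
  }
  if (bin_size %% track$bin_size != 0L) {
    stop("bin_size must be a multiple of the track's existing bin size")
  }
  fold <- bin_size %/% track$bin_size
  n_bins <- length(track$depth) %/% fold
  trimmed <- track$depth[seq_len(n_bins * fold)]
  binned <- colMeans(matrix(trimmed, nrow = fold))
  smoothed <- circular_runmed(binned, median_window_bins)
  coverage_track(smoothed, genome_id = track$genome_id, bin_size = bin_size,
                 length = track$length, circular = track$circular)
}

# Piecewise-linear log2 coverage expected under bidirectional replication:
# log2 depth is maximal at ori, minimal at ter, linear in circular distance
# along both arcs.
ptr_expected_log2 <- function(positions, ori, ter, log2_peak, log2_trough,
                              genome_length) {
  arc1 <- (ter - ori) %% genome_length            # ori -> ter forward
  arc2 <- genome_length - arc1                    # ter -> ori forward
  dfo <- (positions - ori) %% genome_length       # forward distance from ori
  frac <- ifelse(dfo <= arc1, dfo / arc1, (genome_length - dfo) / arc2)
  log2_peak + frac * (log2_trough - log2_peak)
}

#' Estimate the coverage peak-to-trough ratio and Ori/Ter positions
#'
#' The replication origin is placed at the maximum of the smoothed track
#' and the terminus at its minimum; PTR is their ratio. A fit-quality score
#' (R-squared of the piecewise-linear log2-coverage model between Ori and
#' Ter on the circle) is attached so poor sinusoidal fits can be rejected.
#'
#' @param binned A smoothed `coverage_track` from [bin_and_smooth()].
#' @return A `ptr_result`: list with `ptr`, `ori_position`, `ter_position`
#'   (bin midpoints in bp), `peak_coverage`, `trough_coverage`,
#'   `r_squared`, and a `degenerate` flag (set when all bins are equal, in
#'   which case `ptr` is exactly 1).
#' @export
estimate_ptr <- function(binned) {
  x <- binned$depth
  if (min(x) == 0) stop("trough coverage is zero; insufficient coverage for PTR")
  n <- length(x)
  mids <- (seq_len(n) - 0.5) * binned$bin_size
  if (max(x) == min(x)) {
    return(structure(list(genome_id = binned$genome_id, ptr = 1,
                          ori_position = mids[1L], ter_position = mids[which.min(x)],
                          peak_coverage = max(x), trough_coverage = min(x),
                          r_squared = NA_real_, degenerate = TRUE,
                          eligible = NA, replicating = NA),
                     class = "ptr_result"))
  }
  i_peak <- which.max(x)
  i_trough <- which.min(x)
  l2 <- log2(x)
  pred <- ptr_expected_log2(mids, mids[i_peak], mids[i_trough],
                            l2[i_peak], l2[i_trough], binned$length)
  r2 <- 1 - sum((l2 - pred)^2) / sum((l2 - mean(l2))^2)
  structure(list(genome_id = binned$genome_id,
                 ptr = max(x) / min(x),
                 ori_position = mids[i_peak], ter_position = mids[i_trough],
                 peak_coverage = max(x), trough_coverage = min(x),
                 r_squared = r2, degenerate = FALSE,
                 eligible = NA, replicating = NA),
            class = "ptr_result")
}

#' @export
print.ptr_result <- function(x, ...) {
  cat(sprintf("ptr_result [%s]: PTR %.3f (peak %.2f @ %d bp, trough %.2f @ %d bp)\n",
              x$genome_id, x$ptr, x$peak_coverage, round(x$ori_position),
              x$trough_coverage, round(x$ter_position)))
  if (isTRUE(x$degenerate)) cat("  flat coverage: degenerate Ori/Ter\n")
  if (!is.na(x$replicating)) {
    cat(sprintf("  eligible: %s, replicating: %s\n", x$eligible, x$replicating))
  }
  invisible(x)
}

#' Locate Ori/Ter from the cumulative GC skew of a genome sequence
#'
#' Computes per-window GC skew `(G - C) / (G + C)`, accumulates it along
#' the genome, removes the linear trend implied by circularity (the line
#' through the cumulative series' endpoints), and places the origin at the
#' cumulative minimum and the terminus at the maximum. Replication-coupled
#' strand bias makes the cumulative skew fall towards Ori and rise towards
#' Ter, in anti-phase with the sinusoidal coverage of a replicating
#' population.
#'
#' @param genome Genome sequence: a character string or a
#'   `Biostrings::DNAString`. Non-ACGT letters are ignored in the counts.
#' @param window Window size in bp (default 10000).
#' @param noise_sd_multiple Degeneracy guard: the detrended cumulative
#'   range must exceed this multiple of the per-window skew standard
#'   deviation times `sqrt(n_windows)` (the scale of a random GC-skew walk)
#'   or the result is flagged unreliable (default 5).
#' @return A `skew_result`: list with `ori_position`, `ter_position`
#'   (window midpoints in bp), `cumulative_skew` (detrended, per window),
#'   `window_skew` and a `degenerate` flag.
#' @export
gc_skew_ori_ter <- function(genome, window = 10000L, noise_sd_multiple = 5) {
  s <- if (inherits(genome, "DNAString")) as.character(genome) else as.character(genome)
  n <- nchar(s)
  if (n < window) stop("sequence shorter than one window")
  n_win <- n %/% window
  dna <- Biostrings::DNAString(s)
  starts <- (seq_len(n_win) - 1L) * window + 1L
  v <- Biostrings::Views(dna, start = starts, width = window)
  freq <- Biostrings::letterFrequency(v, letters = c("G", "C"))
  gc <- freq[, "G"] + freq[, "C"]
  skew <- ifelse(gc == 0, 0, (freq[, "G"] - freq[, "C"]) / gc)
  cum <- cumsum(skew)
  detrended <- cum - seq_len(n_win) / n_win * cum[n_win]
  mids <- (seq_len(n_win) - 0.5) * window
  rng <- max(detrended) - min(detrended)
  # noise scale from circular first differences: replication-coupled skew is
  # piecewise-constant, so differencing isolates the sampling noise
  noise_sd <- stats::mad(diff(c(skew, skew[1L]))) / sqrt(2)
  floor_scale <- noise_sd * sqrt(n_win)
  degenerate <- !is.finite(floor_scale) || floor_scale == 0 ||
    rng < noise_sd_multiple * floor_scale
  structure(list(genome_id = "genome", window = window,
                 ori_position = mids[which.min(detrended)],
                 ter_position = mids[which.max(detrended)],
                 cumulative_skew = detrended, window_skew = skew,
                 degenerate = degenerate),
            class = "skew_result")
}

#' Flag a PTR result as eligible and replicating
#'
#' A genome is eligible for a replication call when the species received at
#' least `min_assigned_reads` read pairs in the sample and the coverage was
#' not degenerate; it is called replicating when additionally
#' `ptr > ptr_threshold`. The default threshold carries a small guard band
#' above 1 because noisy flat coverage yields ratios marginally above 1;
#' set `ptr_threshold = 1` for the literal peak-over-trough rule.
#'
#' @param ptr_result A `ptr_result` from [estimate_ptr()].
#' @param assigned_reads Read pairs assigned to the species in this sample.
#' @param min_assigned_reads Eligibility floor (default 1000).
#' @param ptr_threshold Replication call threshold (default 1.1).
#' @return The `ptr_result` with `eligible` and `replicating` set and the
#'   inputs recorded.
#' @export
call_replicating <- function(ptr_result, assigned_reads,
                             min_assigned_reads = 1000L, ptr_threshold = 1.1) {
  ptr_result$assigned_reads <- assigned_reads
  ptr_result$eligible <- assigned_reads >= min_assigned_reads &&
    !isTRUE(ptr_result$degenerate)
  ptr_result$replicating <- ptr_result$eligible && ptr_result$ptr > ptr_threshold
  ptr_result
}

#' Write a PTR result as JSON and the smoothed coverage as TSV
#'
#' @param ptr_result A `ptr_result`.
#' @param binned Optional smoothed `coverage_track` to write alongside.
#' @param json_path,coverage_tsv_path Output paths (`NULL` to skip).
#' @export
write_ptr_result <- function(ptr_result, binned = NULL, json_path = NULL,
                             coverage_tsv_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(unclass(ptr_result), json_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  if (!is.null(coverage_tsv_path) && !is.null(binned)) {
    df <- data.frame(bin_mid = (seq_along(binned$depth) - 0.5) * binned$bin_size,
                     depth = binned$depth)
    utils::write.table(df, coverage_tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(ptr_result)
}
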