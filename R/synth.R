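# Synthetic-data generators with planted truth: batch-structured
# contaminated count matrices, phenotypes with optional planted effects,
# and circular-genome coverage/sequence with planted replication and skew.

#' Configuration for the synthetic cohort generator
#'
#' Defaults describe a multi-cohort population processed in laboratory
#' batches: correlated batch-specific contaminants, sporadic low-prevalence
#' genuine taxa, log-normal per-sample microbial read totals with median
#' near 6,000, low-count misclassification noise species, and a pool of
#' ubiquitous background contaminants that absorbs the remaining reads
#' (uniform "kitome" signal that batch-aware heuristics cannot, and should
#' not, remove).
#'
#' @param n_samples Total samples (default 2000).
#' @param n_cohorts Cohorts of equal size; the cohort is also a batch
#'   variable (default 4).
#' @param batch_variables Names of the non-cohort batch variables (default
#'   extraction kit, library preparation kit, SBS lot, flow cell).
#' @param n_batches Batches per variable (default 4).
#' @param assignment `"blocked"` assigns each variable in contiguous blocks
#'   with a variable-specific offset, producing the nested/confounded
#'   structure of real processing runs; `"independent"` randomizes labels.
#' @param n_genuine_species Sporadic genuine taxa (default 20).
#' @param genuine_prevalence_range True prevalence range for genuine taxa
#'   (default 0.001 to 0.05).
#' @param n_contaminant_species Batch contaminants (default 30).
#' @param contaminant_home_prevalence Presence probability in the home
#'   batch (default 0.4).
#' @param contaminant_background_prevalence Presence probability elsewhere
#'   (default 0.05).
#' @param within_batch_correlation Gaussian-copula correlation between
#'   co-resident contaminants in their home batch, shared by the presence
#'   and abundance layers (default 0.8).
#' @param total_reads_meanlog,total_reads_sdlog Log-normal parameters of
#'   per-sample microbial totals (default median 6000, sigma 1).
#' @param ra_meanlog,ra_sdlog Log-normal parameters of the relative
#'   abundance a planted species takes when present (default median 0.03,
#'   sigma 0.6, comfortably above the 0.005 presence threshold).
#' @param n_noise_species Misclassification-noise species that only ever
#'   receive at most 10 reads (default 30).
#' @param noise_sample_fraction Fraction of samples hit by each noise
#'   species (default 0.01).
#' @param n_background_species Ubiquitous background contaminants sharing
#'   the reads not taken by planted species (default 15).
#' @param seed Master seed.
#' @return Named list of settings for [simulate_cohort_counts()].
#' @export
simulation_config <- function(n_samples = 2000L, n_cohorts = 4L,
                              batch_variables = c("extraction_kit",
                                                  "library_prep_kit",
                                                  "sbs_lot", "flow_cell"),
                              n_batches = 4L,
                              assignment = c("blocked", "independent"),
                              n_genuine_species = 20L,
                              genuine_prevalence_range = c(0.001, 0.05),
                              n_contaminant_species = 30L,
                              contaminant_home_prevalence = 0.4,
                              contaminant_background_prevalence = 0.05,
                              within_batch_correlation = 0.8,
                              total_reads_meanlog = log(6000),
                              total_reads_sdlog = 1,
                              ra_meanlog = log(0.03), ra_sdlog = 0.6,
                              n_noise_species = 30L,
                              noise_sample_fraction = 0.01,
                              n_background_species = 15L,
                              seed = 1L) {
  assignment <- match.arg(assignment)
  stopifnot(n_samples >= n_cohorts, n_batches >= 2L,
            all(genuine_prevalence_range >= 0),
            all(genuine_prevalence_range <= 1),
            contaminant_home_prevalence > 0,
            contaminant_home_prevalence <= 1,
            contaminant_background_prevalence >= 0,
            within_batch_correlation >= 0, within_batch_correlation <= 1)
  as.list(environment())
}

assign_batches <- function(n, k, mode) {
  block <- ceiling(n / k)
  base_lab <- rep(seq_len(k), each = block)[seq_len(n)]
  if (mode == "independent") {
    sample(base_lab)
  } else {
    offset <- sample.int(n, 1L)
    base_lab[((seq_len(n) - 1L + offset) %% n) + 1L]
  }
}

#' Simulate a batch-structured contaminated count matrix
#'
#' Per sample, a log-normal microbial read total is drawn. Genuine taxa are
#' present independently at their planted prevalence; each contaminant has
#' a home (variable, batch) where its presence and abundance are driven by
#' a shared per-sample latent factor (Gaussian copula), producing the
#' within-batch co-occurrence that the correlation filter exploits, with a
#' low background prevalence elsewhere. Noise species receive at most 10
#' reads in a small fraction of samples. Reads not taken by planted species
#' are allocated to a pool of ubiquitous background contaminants so row
#' totals match the drawn totals.
#'
#' @param config From [simulation_config()].
#' @return List with `counts` (samples x species integer matrix), `meta`
#'   (batch metadata data.frame) and `truth` (a `synthetic_truth` list:
#'   contaminant homes, genuine prevalences, noise and background species).
#' @export
simulate_cohort_counts <- function(config = simulation_config()) {
  cfg <- config
  n <- cfg$n_samples
  n_species_total <- cfg$n_genuine_species + cfg$n_contaminant_species +
    cfg$n_noise_species + cfg$n_background_species
  if (n_species_total < 1L) stop("infeasible config: no species to simulate")
  rng <- local_rng(cfg$seed)
  on.exit(rng$restore())

  sample_ids <- sprintf("S%04d", seq_len(n))
  cohort <- paste0("COH", assign_batches(n, cfg$n_cohorts, "blocked"))
  meta <- data.frame(sample_id = sample_ids, cohort = cohort,
                     stringsAsFactors = FALSE)
  for (v in cfg$batch_variables) {
    meta[[v]] <- paste0(toupper(substr(v, 1L, 2L)),
                        assign_batches(n, cfg$n_batches, cfg$assignment))
  }

  totals <- pmax(1, round(stats::rlnorm(n, cfg$total_reads_meanlog,
                                        cfg$total_reads_sdlog)))

  genuine <- sprintf("Genuinebacter species_%02d", seq_len(cfg$n_genuine_species))
  contam <- sprintf("Kitomonas contaminans_%02d", seq_len(cfg$n_contaminant_species))
  noise <- sprintf("Misclassia spuria_%02d", seq_len(cfg$n_noise_species))
  background <- sprintf("Ubiquibacter reagentis_%02d", seq_len(cfg$n_background_species))
  species <- c(genuine, contam, noise, background)
  counts <- matrix(0L, n, length(species), dimnames = list(sample_ids, species))

  reads_when_present <- function(idx) {
    ra <- stats::rlnorm(length(idx), cfg$ra_meanlog, cfg$ra_sdlog)
    pmax(1L, as.integer(round(ra * totals[idx])))
  }

  # genuine sporadic taxa
  genuine_prev <- stats::runif(cfg$n_genuine_species,
                               cfg$genuine_prevalence_range[1L],
                               cfg$genuine_prevalence_range[2L])
  for (g in seq_len(cfg$n_genuine_species)) {
    hit <- which(stats::runif(n) < genuine_prev[g])
    if (length(hit) > 0L) counts[hit, genuine[g]] <- reads_when_present(hit)
  }

  # batch contaminants with a shared latent factor in the home batch
  all_vars <- c("cohort", cfg$batch_variables)
  ci_seq <- seq_along(contam)
  homes <- data.frame(species = contam,
                      home_variable = all_vars[((ci_seq - 1L) %% length(all_vars)) + 1L],
                      stringsAsFactors = FALSE)
  # cycle home batches so several contaminants co-reside in each home
  homes$home_batch <- vapply(ci_seq, function(ci) {
    v <- homes$home_variable[ci]
    labs <- sort(unique(meta[[v]]))
    labs[(((ci - 1L) %/% length(all_vars)) %% length(labs)) + 1L]
  }, character(1))
  latent <- matrix(stats::rnorm(n * length(all_vars)), n, length(all_vars),
                   dimnames = list(NULL, all_vars))  # one factor per variable's home batches
  w <- cfg$within_batch_correlation
  thr_home <- stats::qnorm(1 - cfg$contaminant_home_prevalence)
  for (ci in seq_along(contam)) {
    v <- homes$home_variable[ci]
    b <- homes$home_batch[ci]
    in_home <- meta[[v]] == b
    eps <- stats::rnorm(n)
    z <- sqrt(w) * latent[, v] + sqrt(1 - w) * eps
    present <- logical(n)
    present[in_home] <- z[in_home] > thr_home
    present[!in_home] <- stats::runif(sum(!in_home)) <
      cfg$contaminant_background_prevalence
    hit <- which(present)
    if (length(hit) > 0L) {
      # abundance shares the latent factor so co-resident contaminants
      # rank-correlate within the home batch
      lra <- cfg$ra_meanlog + cfg$ra_sdlog *
        (sqrt(w) * latent[hit, v] + sqrt(1 - w) * stats::rnorm(length(hit)))
      counts[hit, contam[ci]] <- pmax(1L, as.integer(round(exp(lra) * totals[hit])))
    }
  }

  # misclassification noise: always <= 10 reads
  for (nz in noise) {
    hit <- which(stats::runif(n) < cfg$noise_sample_fraction)
    if (length(hit) > 0L) counts[hit, nz] <- sample.int(10L, length(hit), replace = TRUE)
  }

  # background pool absorbs the remaining reads
  if (cfg$n_background_species > 0L) {
    planted <- rowSums(counts)
    remaining <- pmax(0, totals - planted)
    base_w <- stats::rlnorm(cfg$n_background_species, 0, 0.5)
    for (i in which(remaining > 0)) {
      counts[i, background] <- as.integer(stats::rmultinom(1L, remaining[i],
                                                           prob = base_w))
    }
  }

  truth <- structure(list(contaminants = homes,
                          genuine = data.frame(species = genuine,
                                               prevalence = genuine_prev,
                                               stringsAsFactors = FALSE),
                          noise_species = noise,
                          background_species = background,
                          seed = cfg$seed),
                     class = "synthetic_truth")
  list(counts = counts, meta = meta, truth = truth)
}

#' Simulate host phenotypes, optionally planting species effects
#'
#' Phenotypes are drawn from plausible adult marginals (age uniform 21-80;
#' BMI normal(24, 4) truncated above 14; TC normal(5.2, 1); TG normal(1.5,
#' 0.8) truncated above 0.2; SBP normal(125, 15); DBP normal(75, 10); sex
#' balanced; four ancestry groups). A planted effect shifts the log-odds of
#' a species' presence for samples satisfying a phenotype condition, and
#' the species' presence column is redrawn accordingly.
#'
#' @param meta Batch metadata (provides `sample_id` and `cohort`).
#' @param presence Optional logical presence matrix to replant when
#'   `effects` are given.
#' @param effects Optional list of effects, each a list with `species`,
#'   `condition` (a function of the phenotype data.frame returning a
#'   logical vector) and `log_odds`.
#' @param missing_fraction Fraction of each numeric phenotype set missing
#'   (default 0.02).
#' @param seed Seed.
#' @return List with `phenotypes` (data.frame) and `presence` (modified
#'   copy when effects were planted, otherwise the input).
#' @export
simulate_phenotypes <- function(meta, presence = NULL, effects = NULL,
                                missing_fraction = 0.02, seed = 1L) {
  n <- nrow(meta)
  rng <- local_rng(seed)
  on.exit(rng$restore())
  pheno <- data.frame(
    sample_id = meta$sample_id,
    cohort = meta$cohort,
    sex = sample(c("F", "M"), n, replace = TRUE),
    ancestry = sample(c("Chinese", "Malay", "Indian", "Others"), n,
                      replace = TRUE, prob = c(0.6, 0.2, 0.15, 0.05)),
    age = stats::runif(n, 21, 80),
    bmi = pmax(14, stats::rnorm(n, 24, 4)),
    tc = pmax(1, stats::rnorm(n, 5.2, 1)),
    tg = pmax(0.2, stats::rnorm(n, 1.5, 0.8)),
    sbp = pmax(70, stats::rnorm(n, 125, 15)),
    dbp = pmax(40, stats::rnorm(n, 75, 10)),
    stringsAsFactors = FALSE)
  for (col in c("age", "bmi", "tc", "tg", "sbp", "dbp")) {
    miss <- stats::runif(n) < missing_fraction
    pheno[[col]][miss] <- NA_real_
  }
  if (!is.null(effects)) {
    if (is.null(presence)) stop("presence matrix required to plant effects")
    presence <- presence
    for (ef in effects) {
      if (!ef$species %in% colnames(presence)) {
        stop("planted effect references unknown species: ", ef$species)
      }
      p0 <- mean(presence[, ef$species])
      if (p0 == 0 || p0 == 1) stop("cannot plant an effect on a degenerate species")
      cond <- ef$condition(pheno)
      cond[is.na(cond)] <- FALSE
      logit0 <- log(p0 / (1 - p0))
      pvec <- stats::plogis(logit0 + ef$log_odds * cond)
      presence[, ef$species] <- stats::runif(n) < pvec
    }
  }
  list(phenotypes = pheno, presence = presence)
}

#' Simulate circular-genome coverage with a planted replication signature
#'
#' Expected log2 depth is piecewise linear on the circle, maximal at `ori`
#' and minimal at `ter` with `log2(peak/trough) = log2(ptr)`, scaled so the
#' mean expected depth equals `mean_depth`. Observed per-bin depth is
#' Poisson: `rpois(expected * bin_size) / bin_size`.
#'
#' @param length Genome length in bp.
#' @param ptr Planted peak-to-trough ratio (>= 1).
#' @param ori,ter Planted origin/terminus positions in bp.
#' @param mean_depth Mean per-position depth.
#' @param bin_size Bin width in bp (default 10000).
#' @param seed Seed.
#' @return A binned `coverage_track` with attributes `planted_ptr`,
#'   `planted_ori`, `planted_ter`.
#' @export
simulate_coverage <- function(length, ptr, ori, ter, mean_depth,
                              bin_size = 10000L, seed = 1L) {
  if (ptr < 1) stop("ptr must be >= 1")
  if (ori == ter) stop("ori and ter must differ")
  n_bins <- length %/% bin_size
  mids <- (seq_len(n_bins) - 0.5) * bin_size
  l2 <- ptr_expected_log2(mids, ori, ter, log2(ptr), 0, length)
  expected <- 2^l2
  expected <- expected * mean_depth / mean(expected)
  rng <- local_rng(seed)
  on.exit(rng$restore())
  depth <- stats::rpois(n_bins, expected * bin_size) / bin_size
  track <- coverage_track(depth, genome_id = sprintf("sim_ptr%.2f", ptr),
                          bin_size = bin_size, length = n_bins * bin_size)
  attr(track, "planted_ptr") <- ptr
  attr(track, "planted_ori") <- ori
  attr(track, "planted_ter") <- ter
  track
}

#' Simulate a circular genome sequence with planted GC-skew switch points
#'
#' Positions carry G or C with probability `gc_content`; within GC
#' positions the G:C balance is biased by `+skew_amplitude` on the forward
#' ori-to-ter segment (leading strand) and `-skew_amplitude` elsewhere, so
#' the detrended cumulative GC skew attains its minimum at `ori` and its
#' maximum at `ter`.
#'
#' @param length Genome length in bp.
#' @param ori,ter Planted switch positions in bp.
#' @param skew_amplitude Strand bias within GC positions, in (0, 1] (0
#'   yields an unbiased null genome).
#' @param gc_content Overall GC content (default 0.5).
#' @param seed Seed.
#' @return Character string of length `length` over ACGT.
#' @export
simulate_genome_with_skew <- function(length, ori, ter, skew_amplitude,
                                      gc_content = 0.5, seed = 1L) {
  if (skew_amplitude < 0 || skew_amplitude > 1) {
    stop("skew_amplitude must lie in [0, 1]")
  }
  rng <- local_rng(seed)
  on.exit(rng$restore())
  pos <- seq_len(length)
  forward <- if (ori < ter) pos > ori & pos <= ter else pos > ori | pos <= ter
  is_gc <- stats::runif(length) < gc_content
  p_g <- ifelse(forward, (1 + skew_amplitude) / 2, (1 - skew_amplitude) / 2)
  g <- stats::runif(length) < p_g
  at_a <- stats::runif(length) < 0.5
  chars <- ifelse(is_gc, ifelse(g, "G", "C"), ifelse(at_a, "A", "T"))
  paste(chars, collapse = "")
}

#' Serialize synthetic truth to JSON (and read it back)
#'
#' @param truth A `synthetic_truth` object.
#' @param path Output path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(contaminants = as.data.frame(obj$contaminants,
                                              stringsAsFactors = FALSE),
                 genuine = as.data.frame(obj$genuine, stringsAsFactors = FALSE),
                 noise_species = obj$noise_species,
                 background_species = obj$background_species,
                 seed = obj$seed),
            class = "synthetic_truth")
}
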