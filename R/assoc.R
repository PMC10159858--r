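# Host-phenotype association screen: Fisher / Mann-Whitney tests per
# cohort, pooled Benjamini-Hochberg correction, derived phenotypes.

#' Fisher's exact test of presence against a categorical phenotype
#'
#' Builds the 2 x k presence-by-category table and returns the exact
#' two-sided p-value. For tables wider than 2 x 2 with large totals the
#' p-value is a seeded Monte-Carlo estimate.
#'
#' @param present Logical vector of species presence.
#' @param category Factor-like phenotype vector; `NA`s (and pairs with a
#'   missing presence value) are excluded.
#' @param mc_total_threshold Total count above which 2 x k (k > 2) tables
#'   switch to Monte-Carlo estimation (default 200).
#' @param mc_B Monte-Carlo replicates (default 2000).
#' @param seed Seed for the Monte-Carlo estimate.
#' @return List with `statistic` (`NA`; Fisher's exact test has no test
#'   statistic to report for r x c tables), `p`, `n_used`, and `skipped`
#'   with a `skip_reason` when the test cannot run.
#' @export
test_categorical <- function(present, category, mc_total_threshold = 200L,
                             mc_B = 2000L, seed = 1L) {
  category <- as.character(category)
  ok <- !is.na(present) & !is.na(category) & nzchar(category)
  pres <- present[ok]
  # fast 2 x k cross-tabulation without factor() overhead
  levels_ <- sort(unique(category[ok]))
  if (length(levels_) < 2L) {
    return(list(statistic = NA_real_, p = NA_real_, n_used = sum(ok),
                skipped = TRUE, skip_reason = "single category after missing-data removal"))
  }
  code <- match(category[ok], levels_)
  k <- length(levels_)
  tab <- rbind(tabulate(code[!pres], nbins = k),
               tabulate(code[pres], nbins = k))
  dimnames(tab) <- list(c("FALSE", "TRUE"), levels_)
  if (any(rowSums(tab) == 0)) {
    return(list(statistic = NA_real_, p = NA_real_, n_used = sum(ok),
                skipped = TRUE, skip_reason = "presence is constant in this stratum"))
  }
  if (k > 2L && sum(tab) > mc_total_threshold) {
    rng <- local_rng(seed)
    ft <- stats::fisher.test(tab, simulate.p.value = TRUE, B = mc_B)
    rng$restore()
  } else {
    ft <- stats::fisher.test(tab, workspace = 2e6)
  }
  list(statistic = NA_real_, p = unname(ft$p.value), n_used = sum(ok),
       skipped = FALSE, skip_reason = NA_character_)
}

# Exact two-sided Mann-Whitney p by complete enumeration of group-label
# assignments, using mid-ranks (valid with ties); two-sided by doubling the
# smaller tail, the usual convention for exact rank tests.
mwu_exact_enumeration <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n1 + n2, n1)
  us <- apply(combos, 2L, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  p <- min(1, 2 * min(mean(us <= u_obs + 1e-9), mean(us >= u_obs - 1e-9)))
  list(u = u_obs, p = p)
}

#' Mann-Whitney U test of a continuous phenotype against presence
#'
#' Two-sided test comparing the phenotype distribution between samples
#' where the species is present and absent. Small samples (total n at or
#' below `exact_max_n`) are handled by exact enumeration over all group
#' labelings with mid-ranks, which stays exact under ties; larger samples
#' use the continuity-corrected normal approximation with tie-corrected
#' variance.
#'
#' @param present Logical vector of species presence.
#' @param values Numeric phenotype vector; `NA`s excluded pairwise.
#' @param exact_max_n Total sample size up to which exact enumeration is
#'   used (default 10).
#' @return List with `statistic` (U for the present group), `p`, `n_used`,
#'   `skipped`/`skip_reason`.
#' @export
test_continuous <- function(present, values, exact_max_n = 10L) {
  ok <- !is.na(present) & !is.na(values)
  pres <- present[ok]
  v <- values[ok]
  x <- v[pres]; y <- v[!pres]
  if (length(x) == 0L || length(y) == 0L) {
    return(list(statistic = NA_real_, p = NA_real_, n_used = sum(ok),
                skipped = TRUE, skip_reason = "one presence group is empty"))
  }
  if (length(v) <= exact_max_n) {
    res <- mwu_exact_enumeration(x, y)
    return(list(statistic = res$u, p = res$p, n_used = sum(ok),
                skipped = FALSE, skip_reason = NA_character_))
  }
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE, correct = TRUE))
  list(statistic = unname(wt$statistic), p = unname(wt$p.value), n_used = sum(ok),
       skipped = FALSE, skip_reason = NA_character_)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values (with the usual monotonicity enforcement),
#' returned in the input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (`NA`s pass through).
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) {
  pv <- p[!is.na(p)]
  # exact-test p-values can overshoot 1 by a few ulps; tolerate and clamp
  if (any(pv < -1e-8 | pv > 1 + 1e-8)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(pmin(pmax(p, 0), 1), method = "BH")
}

#' Derive categorical health phenotypes from measured ones
#'
#' Adds indicator columns: `elderly` (age >= 65), `obese` (BMI > 30),
#' `high_tg` (TG > 2.3 mmol/l), `high_tc` (TC >= 6.3 mmol/l) and `high_bp`
#' (SBP >= 130 and DBP >= 80). Missing inputs propagate to `NA`.
#'
#' @param pheno Phenotype data.frame with columns `age`, `bmi`, `tg`, `tc`,
#'   `sbp`, `dbp` (missing columns simply yield no derived column).
#' @return `pheno` with the derived logical columns appended.
#' @export
derive_phenotypes <- function(pheno) {
  if ("age" %in% names(pheno)) pheno$elderly <- pheno$age >= 65
  if ("bmi" %in% names(pheno)) pheno$obese <- pheno$bmi > 30
  if ("tg" %in% names(pheno)) pheno$high_tg <- pheno$tg > 2.3
  if ("tc" %in% names(pheno)) pheno$high_tc <- pheno$tc >= 6.3
  if (all(c("sbp", "dbp") %in% names(pheno))) {
    pheno$high_bp <- pheno$sbp >= 130 & pheno$dbp >= 80
  }
  pheno
}

MEASURED_CATEGORICAL <- c("sex", "ancestry")
MEASURED_CONTINUOUS <- c("age", "bmi", "tc", "tg", "sbp", "dbp")
DERIVED_PHENOTYPES <- c("elderly", "obese", "high_tg", "high_tc", "high_bp")

#' Screen species presence against host phenotypes per cohort
#'
#' Within each cohort, categorical phenotypes are tested with Fisher's
#' exact test and continuous ones with the Mann-Whitney U test. Species
#' present in fewer than `min_present` samples overall are skipped.
#' Benjamini-Hochberg correction is applied once over the pooled p-values
#' of both test types and all cohorts; derived phenotypes (from
#' [derive_phenotypes()], Fisher tests) form a second family with its own
#' correction.
#'
#' @param presence A `presence_matrix`.
#' @param pheno Phenotype data.frame with `sample_id` and `cohort` columns
#'   plus phenotype columns (`sex`, `ancestry`, `age`, `bmi`, `tc`, `tg`,
#'   `sbp`, `dbp` as available).
#' @param species Species to screen (default: all columns of `presence`).
#' @param min_present Minimum total presence across all samples for a
#'   species to be tested (default 50).
#' @param include_derived Whether to run the derived-phenotype family
#'   (default `TRUE`).
#' @param seed Seed for Monte-Carlo Fisher fallbacks.
#' @return An `association_screen`: list with `results` (data.frame:
#'   species, phenotype, cohort, family, test, statistic, p, p_adjusted,
#'   n_present, n_absent, and for significant hits the number of cohorts
#'   where the same pair is significant) and `skipped` (data.frame of
#'   skipped species/tests with reasons).
#' @export
run_association_screen <- function(presence, pheno, species = NULL,
                                   min_present = 50L, include_derived = TRUE,
                                   seed = 1L) {
  pm <- presence$present
  if (is.null(species)) species <- colnames(pm)
  pheno <- align_metadata(pheno, rownames(pm))
  if (!"cohort" %in% names(pheno)) stop("phenotype table must have a cohort column")
  if (include_derived) pheno <- derive_phenotypes(pheno)

  total_present <- colSums(pm[, species, drop = FALSE])
  testable <- species[total_present >= min_present]
  low <- species[total_present < min_present]
  skipped <- data.frame(
    species = low,
    phenotype = rep(NA_character_, length(low)),
    cohort = rep(NA_character_, length(low)),
    reason = sprintf("present in %d < %d samples in total",
                     total_present[match(low, species)], min_present),
    stringsAsFactors = FALSE)

  cats <- intersect(MEASURED_CATEGORICAL, names(pheno))
  conts <- intersect(MEASURED_CONTINUOUS, names(pheno))
  deriv <- if (include_derived) intersect(DERIVED_PHENOTYPES, names(pheno)) else character(0)
  cohorts <- sort(unique(pheno$cohort))

  # accumulate plain vectors; building a data.frame per test dominates the
  # runtime of large screens otherwise
  acc <- new.env(parent = emptyenv())
  acc$species <- acc$phenotype <- acc$cohort <- acc$family <- acc$test <- character(0)
  acc$statistic <- acc$p <- numeric(0)
  acc$n_present <- acc$n_absent <- integer(0)
  sk <- list(species = skipped$species, phenotype = skipped$phenotype,
             cohort = skipped$cohort, reason = skipped$reason)
  add_row <- function(s, ph, co, family, test, res, n_pres, n_abs) {
    if (res$skipped) {
      sk$species <<- c(sk$species, s)
      sk$phenotype <<- c(sk$phenotype, ph)
      sk$cohort <<- c(sk$cohort, co)
      sk$reason <<- c(sk$reason, res$skip_reason)
    } else {
      acc$species <- c(acc$species, s)
      acc$phenotype <- c(acc$phenotype, ph)
      acc$cohort <- c(acc$cohort, co)
      acc$family <- c(acc$family, family)
      acc$test <- c(acc$test, test)
      acc$statistic <- c(acc$statistic, res$statistic)
      acc$p <- c(acc$p, res$p)
      acc$n_present <- c(acc$n_present, n_pres)
      acc$n_absent <- c(acc$n_absent, n_abs)
    }
  }

  test_id <- 0L
  for (co in cohorts) {
    rows_co <- pheno$cohort == co
    pm_co <- pm[rows_co, , drop = FALSE]
    ph_co <- pheno[rows_co, , drop = FALSE]
    ok_by_ph <- lapply(ph_co[c(cats, conts, deriv)], function(v) !is.na(v))
    for (s in testable) {
      pres <- pm_co[, s]
      for (ph in cats) {
        test_id <- test_id + 1L
        res <- test_categorical(pres, ph_co[[ph]],
                                seed = derive_seed(seed, test_id))
        add_row(s, ph, co, "measured", "fisher", res,
                sum(pres & ok_by_ph[[ph]]), sum(!pres & ok_by_ph[[ph]]))
      }
      for (ph in conts) {
        res <- test_continuous(pres, ph_co[[ph]])
        add_row(s, ph, co, "measured", "mann_whitney", res,
                sum(pres & ok_by_ph[[ph]]), sum(!pres & ok_by_ph[[ph]]))
      }
      for (ph in deriv) {
        test_id <- test_id + 1L
        res <- test_categorical(pres, ph_co[[ph]],
                                seed = derive_seed(seed, test_id))
        add_row(s, ph, co, "derived", "fisher", res,
                sum(pres & ok_by_ph[[ph]]), sum(!pres & ok_by_ph[[ph]]))
      }
    }
  }

  skipped <- data.frame(sk, stringsAsFactors = FALSE)
  results <- data.frame(species = acc$species, phenotype = acc$phenotype,
                        cohort = acc$cohort, family = acc$family,
                        test = acc$test, statistic = acc$statistic,
                        p = acc$p, n_present = acc$n_present,
                        n_absent = acc$n_absent, stringsAsFactors = FALSE)
  results$p_adjusted <- NA_real_
  for (fam in unique(results$family)) {
    idx <- results$family == fam
    results$p_adjusted[idx] <- bh_adjust(results$p[idx])
  }

  # cross-cohort replication count for significant hits
  results$n_cohorts_significant <- 0L
  sig <- !is.na(results$p_adjusted) & results$p_adjusted < 0.05
  if (any(sig)) {
    key <- paste(results$species, results$phenotype, results$family)
    tab <- table(key[sig])
    results$n_cohorts_significant[sig] <- as.integer(tab[key[sig]])
  }
  structure(list(results = results, skipped = skipped,
                 min_present = min_present, cohorts = cohorts),
            class = "association_screen")
}

#' @export
print.association_screen <- function(x, ...) {
  n_sig <- sum(!is.na(x$results$p_adjusted) & x$results$p_adjusted < 0.05)
  cat(sprintf("association_screen: %d tests across %d cohorts, %d significant (BH < 0.05), %d skipped\n",
              nrow(x$results), length(x$cohorts), n_sig, nrow(x$skipped)))
  invisible(x)
}

#' Read a phenotype table
#'
#' @param path TSV with `sample_id`, `cohort`, and phenotype columns;
#'   empty fields are missing values.
#' @return data.frame with numeric phenotype columns coerced.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("", "NA"))
  if (!"sample_id" %in% names(df)) stop("phenotype table must have a sample_id column")
  df$sample_id <- as.character(df$sample_id)
  for (col in intersect(MEASURED_CONTINUOUS, names(df))) {
    df[[col]] <- as.numeric(df[[col]])
    if (any(df[[col]] < 0, na.rm = TRUE)) stop("negative values in phenotype ", col)
  }
  df
}
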