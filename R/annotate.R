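# Species annotation joins and the randomization enrichment test used to
# validate decontamination, plus prevalence/summary helpers.

CONTAMINANT_CLASSES <- c("likely_contaminant", "mixed_evidence",
                         "pathogen_commensal", "unknown")
GROWTH_CLASSES <- c("obligate_anaerobe", "obligate_intracellular",
                    "facultative", "aerobe", "unknown")

#' Read a species annotation table
#'
#' @param path TSV with columns `species`, `contaminant_class`,
#'   `in_blood_culture` (0/1), `human_associated` (0/1), `body_sites`
#'   (semicolon-separated, may be empty) and `growth`.
#' @return data.frame with validated enum columns and logical flags.
#' @export
read_annotation_db <- function(path) {
  db <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  required <- c("species", "contaminant_class", "in_blood_culture",
                "human_associated", "body_sites", "growth")
  missing <- setdiff(required, names(db))
  if (length(missing) > 0L) {
    stop("annotation table missing column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(db$species)) stop("duplicate species in annotation table")
  bad <- setdiff(unique(db$contaminant_class), CONTAMINANT_CLASSES)
  if (length(bad) > 0L) stop("unknown contaminant_class value(s): ",
                             paste(bad, collapse = ", "))
  bad <- setdiff(unique(db$growth), GROWTH_CLASSES)
  if (length(bad) > 0L) stop("unknown growth value(s): ", paste(bad, collapse = ", "))
  db$in_blood_culture <- db$in_blood_culture %in% c("1", "TRUE", "true")
  db$human_associated <- db$human_associated %in% c("1", "TRUE", "true")
  db
}

# Logical indicator of category membership for a species vector; species
# absent from the db count as negative (and are flagged unknown).
category_indicator <- function(species, db, category) {
  idx <- match(species, db$species)
  ind <- switch(category,
                likely_contaminant = db$contaminant_class[idx] == "likely_contaminant",
                in_blood_culture = db$in_blood_culture[idx],
                human_associated = db$human_associated[idx],
                stop("unknown annotation category: ", category))
  ind[is.na(idx)] <- FALSE
  ind
}

#' Proportion of a species list falling in each annotation category
#'
#' Denominators are the full list length; species missing from the
#' annotation table count as category-negative and are reported in the
#' `n_unknown` attribute.
#'
#' @param species_list Character vector of species.
#' @param db Annotation table from [read_annotation_db()].
#' @return Named numeric vector with proportions for `likely_contaminant`,
#'   `in_blood_culture` and `human_associated`.
#' @export
classify_proportions <- function(species_list, db) {
  if (length(species_list) == 0L) stop("empty species list")
  cats <- c("likely_contaminant", "in_blood_culture", "human_associated")
  out <- vapply(cats, function(cg) mean(category_indicator(species_list, db, cg)),
                numeric(1))
  attr(out, "n_unknown") <- sum(!species_list %in% db$species)
  out
}

#' Randomization test for annotation enrichment after decontamination
#'
#' Draws `n_iter` random subsets of the pre-filter species list, each the
#' size of the post-filter list, and compares the observed post-filter
#' category proportion against the null proportions. The p-value is the
#' plain fraction of random sets at least as extreme as the observation.
#'
#' @param pre_list Species list before filtering (the sampling universe).
#' @param post_list Species list after filtering; must be a subset of
#'   `pre_list`.
#' @param db Annotation table.
#' @param category One of `"likely_contaminant"`, `"in_blood_culture"`,
#'   `"human_associated"`.
#' @param direction `"greater"` tests for enrichment, `"less"` for
#'   depletion.
#' @param n_iter Number of random draws (default 1000).
#' @param seed Integer seed; the test is deterministic given it.
#' @return An object of class `randomization_result` with the observed
#'   proportion, the null proportions, and the p-value (a p of 0 prints as
#'   `< 1/n_iter`).
#' @export
randomization_test <- function(pre_list, post_list, db, category,
                               direction = c("greater", "less"),
                               n_iter = 1000L, seed = 1L) {
  direction <- match.arg(direction)
  if (length(post_list) == 0L) stop("post_list is empty")
  if (!all(post_list %in% pre_list)) stop("post_list must be a subset of pre_list")
  observed <- mean(category_indicator(post_list, db, category))
  ind_pre <- category_indicator(pre_list, db, category)
  k <- length(post_list)
  rng <- local_rng(seed)
  nulls <- vapply(seq_len(n_iter),
                  function(i) mean(ind_pre[sample.int(length(pre_list), k)]),
                  numeric(1))
  rng$restore()
  p <- if (direction == "greater") mean(nulls >= observed) else mean(nulls <= observed)
  structure(list(category = category, observed_proportion = observed,
                 null_proportions = nulls, p_value = p, direction = direction,
                 n_iter = n_iter, seed = seed),
            class = "randomization_result")
}

#' @export
print.randomization_result <- function(x, ...) {
  ptxt <- if (x$p_value == 0) sprintf("< %g (0/%d)", 1 / x$n_iter, x$n_iter)
          else format(x$p_value, digits = 4)
  cat(sprintf("randomization test (%s, direction=%s): observed %.4f, null mean %.4f, P %s\n",
              x$category, x$direction, x$observed_proportion,
              mean(x$null_proportions), ptxt))
  invisible(x)
}

#' Prevalence of species (or species groups) across all samples
#'
#' @param presence A `presence_matrix`.
#' @param groupings Optional named character vector mapping species to a
#'   group (e.g. genus); a group counts as present in a sample when any
#'   member is present.
#' @return data.frame of (name, prevalence, n_present) sorted by decreasing
#'   prevalence.
#' @export
prevalence_table <- function(presence, groupings = NULL) {
  pm <- presence$present
  if (is.null(groupings)) {
    df <- data.frame(name = colnames(pm),
                     prevalence = colMeans(pm),
                     n_present = colSums(pm),
                     stringsAsFactors = FALSE, row.names = NULL)
  } else {
    groups <- unique(unname(groupings))
    rows <- lapply(groups, function(g) {
      members <- intersect(names(groupings)[groupings == g], colnames(pm))
      hit <- if (length(members) == 0L) rep(FALSE, nrow(pm))
             else rowSums(pm[, members, drop = FALSE]) > 0
      data.frame(name = g, prevalence = mean(hit), n_present = sum(hit),
                 stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
  }
  df[order(-df$prevalence, df$name), , drop = FALSE]
}

#' Per-sample species richness summary
#'
#' @param presence A `presence_matrix`.
#' @return List with `species_per_sample` (named integer vector),
#'   `zero_fraction` (fraction of samples with no species present) and
#'   `median_nonzero` (median species count among samples with at least
#'   one; `NA` when no sample has any).
#' @export
species_summary <- function(presence) {
  k <- rowSums(presence$present)
  nz <- k[k > 0]
  list(species_per_sample = k,
       zero_fraction = mean(k == 0),
       median_nonzero = if (length(nz) > 0) stats::median(nz) else NA_real_)
}
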