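# Decontamination filters and their orchestration.

make_presence_with_prevalence <- function(prev_by_batch, n_by_batch,
                                          species = "sp1", var = "kit") {
  # one species, presence arranged deterministically per batch
  ids <- character(0)
  pres <- logical(0)
  labs <- character(0)
  for (b in names(prev_by_batch)) {
    n <- n_by_batch[[b]]
    k <- round(prev_by_batch[[b]] * n)
    ids <- c(ids, sprintf("%s_%03d", b, seq_len(n)))
    pres <- c(pres, rep(c(TRUE, FALSE), c(k, n - k)))
    labs <- c(labs, rep(b, n))
  }
  pm <- matrix(pres, ncol = 1, dimnames = list(ids, species))
  meta <- data.frame(sample_id = ids, stringsAsFactors = FALSE)
  meta[[var]] <- labs
  list(presence = as_presence(pm), meta = meta)
}

test_that("per-batch prevalence tabulates every batch including zeros", {
  fx <- make_presence_with_prevalence(list(A = 0.4, B = 0), list(A = 10, B = 5))
  tab <- prevalence_by_batch(fx$presence, fx$meta, "kit")
  expect_identical(nrow(tab), 2L)
  expect_equal(tab$prevalence[tab$batch_label == "A"], 0.4)
  expect_equal(tab$prevalence[tab$batch_label == "B"], 0)
  expect_identical(tab$n_samples[tab$batch_label == "A"], 10L)
  expect_error(prevalence_by_batch(fx$presence, fx$meta, "nope"), "unknown")
})

test_that("prevalence filter applies the >25% and >2-fold rules", {
  cases <- list(
    list(prev = list(A = 0.40, B = 0.10), n = list(A = 200, B = 300), called = TRUE),
    list(prev = list(A = 0.30, B = 0.20), n = list(A = 200, B = 300), called = FALSE),
    list(prev = list(A = 0.26, B = 0.00), n = list(A = 200, B = 300), called = TRUE)
  )
  for (cs in cases) {
    fx <- make_presence_with_prevalence(cs$prev, cs$n)
    calls <- prevalence_filter(fx$presence, fx$meta, "kit")
    expect_identical(length(calls) == 1L, cs$called,
                     info = paste(unlist(cs$prev), collapse = "/"))
    if (cs$called) {
      expect_identical(calls[[1]]$batch_label, "A")
      expect_equal(calls[[1]]$evidence$prevalence_in_batch, cs$prev$A)
    }
  }
})

test_that("small batches are excluded from both sides of the comparison", {
  # B is under the size floor: with only one eligible batch the variable is
  # skipped, so a batch-exclusive species cannot be called
  fx <- make_presence_with_prevalence(list(A = 0.4, B = 0.0),
                                      list(A = 200, B = 50))
  w <- testthat::capture_warnings(
    calls <- prevalence_filter(fx$presence, fx$meta, "kit"))
  expect_match(w, "fewer than 2", all = FALSE)
  expect_length(calls, 0L)
  expect_error(prevalence_filter(fx$presence, fx$meta, "kit", min_batch_size = 0),
               ">= 1")
})

test_that("prevalence filter is invariant to sample order and label renaming", {
  fx <- make_presence_with_prevalence(list(A = 0.40, B = 0.10),
                                      list(A = 200, B = 300))
  base <- prevalence_filter(fx$presence, fx$meta, "kit")
  set.seed(5)
  perm <- sample(nrow(fx$presence$present))
  pres2 <- as_presence(fx$presence$present[perm, , drop = FALSE])
  meta2 <- fx$meta[perm, ]
  shuffled <- prevalence_filter(pres2, meta2, "kit")
  expect_identical(length(shuffled), length(base))
  expect_identical(shuffled[[1]]$evidence, base[[1]]$evidence)
  meta3 <- fx$meta
  meta3$kit <- ifelse(meta3$kit == "A", "zulu", "yankee")
  renamed <- prevalence_filter(fx$presence, meta3, "kit")
  expect_identical(renamed[[1]]$batch_label, "zulu")
  expect_identical(renamed[[1]]$evidence, base[[1]]$evidence)
})

test_that("CLR transform matches direct evaluation and sums to zero", {
  a <- matrix(c(0.5, 0.25, 0.25), nrow = 1,
              dimnames = list("s", c("x", "y", "z")))
  clr <- clr_transform(a)
  expect_equal(unname(clr[1, ]), c(0.46210, -0.23105, -0.23105), tolerance = 1e-4)
  expect_equal(sum(clr), 0, tolerance = 1e-6)
  u <- matrix(rep(0.25, 8), 2, 4, dimnames = list(c("a", "b"), paste0("s", 1:4)))
  expect_equal(max(abs(clr_transform(u))), 0)
  set.seed(2)
  r <- matrix(rexp(40), 4, 10, dimnames = list(paste0("r", 1:4), paste0("s", 1:10)))
  r <- r / rowSums(r)
  expect_equal(unname(rowSums(clr_transform(r))), rep(0, 4), tolerance = 1e-6)
  allzero <- matrix(c(0, 0, 1, 1), 2, 2, dimnames = list(c("z", "k"), c("a", "b")))
  allzero[1, ] <- 0
  expect_error(clr_transform(allzero / pmax(rowSums(allzero), 1)), "entirely zero")
})

test_that("correlation filter calls rank-identical partners and respects the strict threshold", {
  set.seed(8)
  n <- 60
  ids <- sprintf("s%03d", 1:n)
  meta <- data.frame(sample_id = ids, kit = rep(c("A", "B"), each = n / 2),
                     stringsAsFactors = FALSE)
  base <- rlnorm(n, 0, 1)
  abund <- cbind(seed_sp = base,
                 follower = base * 2,          # identical ranks, rho = 1
                 indep = rlnorm(n, 0, 1),
                 other = rlnorm(n, 0, 1))
  abund <- abund / rowSums(abund)
  rownames(abund) <- ids
  seed_calls <- list(list(species = "seed_sp", filter = "prevalence",
                          batch_variable = "kit", batch_label = "A",
                          evidence = list()))
  calls <- correlation_filter(abund, meta, seed_calls)
  called <- vapply(calls, `[[`, character(1), "species")
  expect_true("follower" %in% called)
  expect_false("indep" %in% called)
  ev <- calls[[which(called == "follower")]]$evidence
  expect_equal(ev$rho, 1.0)
  expect_identical(ev$partner_species, "seed_sp")
})

test_that("independent species stay uncorrelated with seeds at n = 200", {
  set.seed(13)
  n <- 200
  ids <- sprintf("s%03d", 1:n)
  meta <- data.frame(sample_id = ids, kit = rep("A", n), stringsAsFactors = FALSE)
  abund <- matrix(rlnorm(n * 20), n, 20,
                  dimnames = list(ids, c("seed_sp", paste0("ind", 1:19))))
  abund <- abund / rowSums(abund)
  seed_calls <- list(list(species = "seed_sp", filter = "prevalence",
                          batch_variable = "kit", batch_label = "A",
                          evidence = list()))
  clr <- clr_transform(abund)
  rhos <- cor(clr[, "seed_sp"], clr[, paste0("ind", 1:19)], method = "spearman")
  expect_true(all(abs(rhos) < 0.2))
  expect_length(correlation_filter(abund, meta, seed_calls), 0L)
})

test_that("a correlation exactly at the threshold is not called (strict >)", {
  # every call's recorded rho strictly exceeds the threshold, and raising
  # the threshold to a call's own rho removes that call
  set.seed(21)
  n <- 30
  ids <- sprintf("s%02d", 1:n)
  meta <- data.frame(sample_id = ids, kit = rep("A", n), stringsAsFactors = FALSE)
  abund <- matrix(rlnorm(n * 4), n, 4,
                  dimnames = list(ids, c("seed_sp", "a", "b", "c")))
  abund[, "a"] <- abund[, "seed_sp"] * exp(rnorm(n, 0, 0.1))
  abund <- abund / rowSums(abund)
  seed_calls <- list(list(species = "seed_sp", filter = "prevalence",
                          batch_variable = "kit", batch_label = "A",
                          evidence = list()))
  calls <- correlation_filter(abund, meta, seed_calls, rho_threshold = 0.7)
  for (cl in calls) expect_gt(cl$evidence$rho, 0.7)
  # raising the threshold to the observed rho of the only caught pair
  # removes the call (strict inequality)
  if (length(calls) == 1L) {
    expect_length(correlation_filter(abund, meta, seed_calls,
                                     rho_threshold = calls[[1]]$evidence$rho),
                  0L)
  }
})

test_that("batch filter flags single-batch and undetected species", {
  ids <- sprintf("s%02d", 1:12)
  meta <- data.frame(sample_id = ids,
                     flow_cell = rep(c("FC1", "FC2"), each = 6),
                     kit = rep(c("K1", "K2"), 6),
                     stringsAsFactors = FALSE)
  pm <- matrix(FALSE, 12, 3, dimnames = list(ids, c("one_fc", "spread", "ghost")))
  pm[1:4, "one_fc"] <- TRUE                    # only FC1
  pm[c(1, 8), "spread"] <- TRUE                # both FC and both kits
  pres <- as_presence(pm)
  calls <- batch_filter(pres, meta, c("flow_cell", "kit"))
  called <- vapply(calls, `[[`, character(1), "species")
  expect_true("one_fc" %in% called)
  expect_true("ghost" %in% called)
  expect_false("spread" %in% called)
  ghost_ev <- calls[[which(called == "ghost")]]$evidence
  expect_equal(ghost_ev$n_batches_detected, 0)
  # one variable single-batch suffices even if another is multi-batch
  pm2 <- pm
  pm2[, "one_fc"] <- FALSE
  pm2[c(1, 2), "one_fc"] <- TRUE  # kits K1 and K2, but flow cell only FC1
  calls2 <- batch_filter(as_presence(pm2), meta, c("flow_cell", "kit"))
  expect_true("one_fc" %in% vapply(calls2, `[[`, character(1), "species"))
  expect_error(batch_filter(pres, meta, "kit", excluded_variables = "kit"),
               "excluded")
})

test_that("read-count filter uses an inclusive 100-read floor", {
  zc <- matrix(0L, 21, 3, dimnames = list(sprintf("s%02d", 1:21),
                                          c("artifact", "edge", "ok")))
  zc[, "artifact"] <- c(rep(22L, 21))  # never above 22 reads, as for a
                                       # Kraken2 misassignment artifact
  zc[1, "edge"] <- 99L
  zc[1, "ok"] <- 100L
  called <- vapply(read_count_filter(zc), `[[`, character(1), "species")
  expect_setequal(called, c("artifact", "edge"))
})

test_that("the filter chain is monotone, auditable, and respects toggles", {
  fx <- make_batch_fixture()
  pres <- call_presence(fx$counts)
  cfg <- decontam_config(min_batch_size = 100L, excluded_variables = character(0))
  rep <- run_decontamination(pres, fx$meta, cfg)
  expect_identical(rep$species_before, ncol(fx$counts))
  expect_true(all(diff(c(rep$species_before, rep$species_after_each_filter)) <= 0))
  expect_true("contamA" %in% rep$calls$species)
  expect_true("genuineB" %in% rep$survivors)
  expect_length(intersect(rep$survivors, rep$calls$species), 0L)
  # audit: prevalence-call evidence re-satisfies the rule
  pcalls <- Filter(function(cl) cl$filter == "prevalence", rep$calls_raw)
  for (cl in pcalls) {
    expect_gt(cl$evidence$prevalence_in_batch, 0.25)
    expect_gt(cl$evidence$prevalence_in_batch, 2 * cl$evidence$max_other_prevalence)
  }
  # disabling every filter leaves the full species list
  none <- run_decontamination(pres, fx$meta,
                              decontam_config(filters = character(0)))
  expect_identical(none$survivors, colnames(fx$counts))
  # read_count alone keeps exactly the species reaching 100 reads somewhere
  rc <- run_decontamination(pres, fx$meta,
                            decontam_config(filters = "read_count"))
  expect_setequal(rc$survivors,
                  colnames(fx$counts)[apply(pres$zeroed_counts, 2, max) >= 100])
})

test_that("an empty species set yields an empty report", {
  ids <- c("a", "b")
  counts <- matrix(integer(0), nrow = 2, ncol = 0, dimnames = list(ids, NULL))
  pm <- matrix(logical(0), nrow = 2, ncol = 0, dimnames = list(ids, NULL))
  pres <- structure(list(present = pm, zeroed_counts = counts,
                         abundance = counts, totals = c(1, 1)),
                    class = "presence_matrix")
  meta <- data.frame(sample_id = ids, kit = c("A", "B"), stringsAsFactors = FALSE)
  rep <- suppressWarnings(
    run_decontamination(pres, meta, decontam_config(min_batch_size = 1L)))
  expect_identical(rep$species_before, 0L)
  expect_length(rep$survivors, 0L)
  expect_identical(nrow(rep$calls), 0L)
})

test_that("decontamination reports serialize to JSON and TSV", {
  fx <- make_batch_fixture()
  pres <- call_presence(fx$counts)
  rep <- run_decontamination(pres, fx$meta,
                             decontam_config(excluded_variables = character(0)))
  jp <- tempfile(fileext = ".json"); tp <- tempfile(fileext = ".tsv")
  write_decontam_report(rep, jp, tp)
  back <- jsonlite::read_json(jp, simplifyVector = TRUE)
  expect_identical(back$species_before, rep$species_before)
  expect_setequal(back$survivors, rep$survivors)
  tsv <- read.delim(tp)
  expect_identical(nrow(tsv), nrow(rep$calls))
})
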