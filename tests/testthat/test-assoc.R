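# Association tests, BH correction, derived phenotypes and the screen.

test_that("Fisher test matches exact enumeration on canonical 2x2 tables", {
  pres <- rep(c(TRUE, FALSE), each = 10)
  cat_ <- rep(c("a", "b"), each = 10)
  res <- test_categorical(pres, cat_)
  expect_equal(res$p, 2 / choose(20, 10), tolerance = 1e-12)
  expect_true(is.na(res$statistic))
  balanced <- test_categorical(rep(c(TRUE, FALSE), 10), rep(c("a", "b"), each = 10))
  expect_equal(balanced$p, 1.0)
})

test_that("Fisher test matches the enumeration oracle on random small tables", {
  set.seed(31)
  for (i in 1:20) {
    k <- sample(2:3, 1)
    tab <- matrix(rpois(2 * k, 3), 2, k)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    pres <- rep(rep(c(TRUE, FALSE), k), times = as.vector(t(tab)))
    cat_ <- rep(rep(letters[1:k], each = 2), times = as.vector(t(tab)))
    res <- test_categorical(pres, cat_)
    expect_equal(res$p, fisher_enum_oracle(table(factor(pres, c(TRUE, FALSE)),
                                                 cat_)),
                 tolerance = 1e-7, info = paste("table", i))
  }
})

test_that("categorical tests skip degenerate strata and exclude missing data", {
  res <- test_categorical(rep(TRUE, 10), rep(c("a", "b"), 5))
  expect_true(res$skipped)
  one_cat <- test_categorical(rep(c(TRUE, FALSE), 5), rep("a", 10))
  expect_true(one_cat$skipped)
  # missing phenotype values are excluded pairwise
  pres <- rep(c(TRUE, FALSE), each = 10)
  cat_ <- rep(c("a", "b"), each = 10)
  cat_[1:5] <- NA
  res_na <- test_categorical(pres, cat_)
  expect_identical(res_na$n_used, 15L)
})

test_that("Mann-Whitney matches documented exact cases", {
  res <- test_continuous(c(rep(TRUE, 3), rep(FALSE, 3)), c(1, 2, 3, 4, 5, 6))
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 0.1)
  same <- test_continuous(rep(c(TRUE, FALSE), each = 4), rep(c(1, 2, 3, 4), 2))
  expect_equal(same$p, 1.0)
  empty <- test_continuous(rep(TRUE, 5), 1:5)
  expect_true(empty$skipped)
})

test_that("Mann-Whitney matches full enumeration on all small inputs, ties included", {
  set.seed(57)
  for (i in 1:25) {
    n <- sample(4:8, 1)
    n1 <- sample(1:(n - 1), 1)
    vals <- sample(1:4, n, replace = TRUE)  # heavy ties on purpose
    pres <- c(rep(TRUE, n1), rep(FALSE, n - n1))
    res <- test_continuous(pres, vals)
    expect_equal(res$p, mwu_enum_oracle(vals[pres], vals[!pres]),
                 tolerance = 1e-9, info = paste("case", i))
  }
})

test_that("large-sample Mann-Whitney holds its type-I error rate", {
  set.seed(101)
  n_rep <- 2000
  rejections <- 0L
  for (i in seq_len(n_rep)) {
    pres <- rep(c(TRUE, FALSE), each = 30)
    vals <- rnorm(60)
    if (test_continuous(pres, vals)$p < 0.05) rejections <- rejections + 1L
  }
  expect_gt(rejections / n_rep, 0.04)
  expect_lt(rejections / n_rep, 0.06)
})

test_that("BH adjustment matches the step-up formula and is permutation-stable", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(0.04, 1.0)), c(0.08, 1.0))
  set.seed(77)
  for (i in 1:10) {
    p <- runif(sample(3:40, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-12) && max(adj) <= 1)
    perm <- sample(length(p))
    expect_equal(bh_adjust(p[perm]), adj[perm])
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("derived phenotypes follow the documented thresholds exactly", {
  ph <- data.frame(age = c(65, 64.9, NA), bmi = c(30, 30.1, 25),
                   tg = c(2.3, 2.4, 1), tc = c(6.3, 6.2, 5),
                   sbp = c(135, 130, 129), dbp = c(75, 80, 85))
  d <- derive_phenotypes(ph)
  expect_identical(d$elderly, c(TRUE, FALSE, NA))     # age >= 65
  expect_identical(d$obese, c(FALSE, TRUE, FALSE))    # bmi > 30, strict
  expect_identical(d$high_tg, c(FALSE, TRUE, FALSE))  # tg > 2.3, strict
  expect_identical(d$high_tc, c(TRUE, FALSE, FALSE))  # tc >= 6.3
  expect_identical(d$high_bp, c(FALSE, TRUE, FALSE))  # sbp >= 130 AND dbp >= 80
})

test_that("the screen enforces the 50-sample rule and separates BH families", {
  set.seed(9)
  n <- 400
  ids <- sprintf("s%04d", 1:n)
  pm <- matrix(FALSE, n, 2, dimnames = list(ids, c("common", "rare")))
  pm[1:80, "common"] <- TRUE
  pm[1:49, "rare"] <- TRUE     # below the 50-presence floor
  meta <- data.frame(sample_id = ids, cohort = rep(c("A", "B"), each = n / 2))
  ph <- simulate_phenotypes(meta, seed = 3)$phenotypes
  scr <- run_association_screen(as_presence(pm), ph, seed = 2)
  expect_false("rare" %in% scr$results$species)
  expect_true("rare" %in% scr$skipped$species)
  expect_match(scr$skipped$reason[scr$skipped$species == "rare"], "49 < 50")
  expect_setequal(unique(scr$results$family), c("measured", "derived"))
  # BH applied within family over all cohorts and both tests
  for (fam in c("measured", "derived")) {
    idx <- scr$results$family == fam
    expect_equal(scr$results$p_adjusted[idx], bh_oracle(scr$results$p[idx]),
                 tolerance = 1e-12)
  }
  expect_true(all(scr$results$p_adjusted >= scr$results$p - 1e-12))
  expect_true(all(scr$results$test[scr$results$phenotype %in%
                                     c("sex", "ancestry")] == "fisher"))
  expect_true(all(scr$results$test[scr$results$phenotype == "age"] ==
                    "mann_whitney"))
})

test_that("a planted presence-phenotype effect is recovered as the top hit", {
  set.seed(1)
  n <- 5000
  ids <- sprintf("s%04d", 1:n)
  pm <- matrix(runif(n * 10) < 0.1, n, 10,
               dimnames = list(ids, paste0("sp", 1:10)))
  meta <- data.frame(sample_id = ids, cohort = rep("A", n))
  sim <- simulate_phenotypes(meta, presence = pm,
                             effects = list(list(
                               species = "sp3",
                               condition = function(d) d$bmi > 30,
                               log_odds = 0.7)),
                             seed = 11)
  scr <- run_association_screen(as_presence(sim$presence), sim$phenotypes,
                                seed = 5)
  deriv <- scr$results[scr$results$family == "derived", ]
  top <- deriv[which.min(deriv$p_adjusted), ]
  expect_identical(top$species, "sp3")
  expect_identical(top$phenotype, "obese")
  expect_lt(top$p_adjusted, 0.05)
})

test_that("phenotype tables round-trip with missing values", {
  ph <- data.frame(sample_id = c("a", "b"), cohort = c("X", "X"),
                   sex = c("F", "M"), age = c(30, NA), bmi = c(22.5, 31))
  path <- tempfile(fileext = ".tsv")
  write.table(ph, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  back <- read_phenotypes(path)
  expect_identical(back$sample_id, c("a", "b"))
  expect_true(is.na(back$age[2]))
  expect_equal(back$bmi, c(22.5, 31))
})
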