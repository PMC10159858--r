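# Independent brute-force oracles and small fixture builders shared across
# the test files.

# Exact two-sided Fisher p for a 2 x k table by full enumeration of tables
# with the observed margins (multivariate hypergeometric), summing the
# probabilities of tables no more probable than the observed one.
fisher_enum_oracle <- function(tab) {
  stopifnot(nrow(tab) == 2L)
  col_tot <- colSums(tab)
  n1 <- sum(tab[1L, ])
  k <- ncol(tab)
  grids <- lapply(col_tot, function(m) 0:m)
  combos <- expand.grid(grids)
  combos <- combos[rowSums(combos) == n1, , drop = FALSE]
  log_prob <- function(a) {
    sum(lchoose(col_tot, as.numeric(a))) - lchoose(sum(col_tot), n1)
  }
  lp <- apply(combos, 1L, log_prob)
  lp_obs <- log_prob(tab[1L, ])
  sum(exp(lp[lp <= lp_obs + 1e-7]))
}

# Exact two-sided Mann-Whitney p by enumerating every assignment of group
# labels, using mid-ranks; two-sided by doubling the smaller tail.
mwu_enum_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u_of <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  u_obs <- u_of(seq_len(n1))
  us <- combn(n1 + n2, n1, u_of)
  min(1, 2 * min(mean(us <= u_obs + 1e-9), mean(us >= u_obs - 1e-9)))
}

# Step-up BH adjustment written directly from the formula.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# Direct (non-circular code path) running median with modular indexing.
runmed_circular_oracle <- function(x, window) {
  n <- length(x)
  half <- window %/% 2
  sapply(seq_len(n), function(i) {
    idx <- ((i - half - 1):(i + half - 1)) %% n + 1
    median(x[idx])
  })
}

# SparCC basis-variance linear system for a fixed log-fraction matrix,
# assembled equation by equation and solved with qr.solve (no exclusions).
sparcc_linear_oracle <- function(logx) {
  d <- ncol(logx)
  V <- cov(logx)
  tmat <- matrix(0, d, d)
  for (i in seq_len(d)) for (j in seq_len(d)) {
    tmat[i, j] <- V[i, i] + V[j, j] - 2 * V[i, j]
  }
  A <- matrix(0, d, d)
  b <- numeric(d)
  for (i in seq_len(d)) {
    # sum_j t_ij = (d - 2) w_i + sum_j w_j under the sparsity assumption
    A[i, ] <- 1
    A[i, i] <- d - 1
    b[i] <- sum(tmat[i, ])
  }
  w <- qr.solve(A, b)
  rho <- matrix(0, d, d)
  for (i in seq_len(d)) for (j in seq_len(d)) {
    rho[i, j] <- (w[i] + w[j] - tmat[i, j]) / (2 * sqrt(w[i] * w[j]))
  }
  rho <- pmin(pmax(rho, -1), 1)
  diag(rho) <- 1
  rho
}

# Small annotation table fixture.
make_annotation_db <- function(species,
                               contaminant = logical(length(species)),
                               blood = logical(length(species)),
                               human = logical(length(species))) {
  data.frame(
    species = species,
    contaminant_class = ifelse(contaminant, "likely_contaminant",
                               "pathogen_commensal"),
    in_blood_culture = blood,
    human_associated = human,
    body_sites = "",
    growth = "unknown",
    stringsAsFactors = FALSE
  )
}

# Presence object from a plain logical matrix (for functions that only need
# the presence layer).
as_presence <- function(present, counts = NULL) {
  if (is.null(counts)) {
    counts <- matrix(0L, nrow(present), ncol(present), dimnames = dimnames(present))
    counts[present] <- 1000L
  }
  structure(list(present = present, zeroed_counts = counts,
                 abundance = counts / pmax(1, rowSums(counts)),
                 totals = rowSums(counts)),
            class = "presence_matrix")
}

# Write a Kraken2-style report file; rows given as list(pct, clade, direct,
# rank, taxid, name).
write_kraken_report <- function(rows, path = tempfile(fileext = ".kreport")) {
  lines <- vapply(rows, function(r) paste(r, collapse = "\t"), character(1))
  writeLines(lines, path)
  path
}

# Counts + metadata with an obvious planted batch contaminant, small enough
# for by-hand verification.
make_batch_fixture <- function(n_per_batch = 150L, seed = 42L) {
  set.seed(seed)
  n <- 2L * n_per_batch
  ids <- sprintf("S%03d", seq_len(n))
  meta <- data.frame(sample_id = ids,
                     kit = rep(c("K1", "K2"), each = n_per_batch),
                     stringsAsFactors = FALSE)
  counts <- matrix(0L, n, 3L, dimnames = list(ids, c("contamA", "genuineB", "rareC")))
  in_k1 <- meta$kit == "K1"
  hit <- which(in_k1)[runif(n_per_batch) < 0.4]
  counts[hit, "contamA"] <- 500L
  hit_b <- which(runif(n) < 0.3)
  counts[hit_b, "genuineB"] <- 400L
  counts[, "rareC"] <- 0L
  counts <- counts + matrix(rpois(n * 3, 2), n, 3)  # background noise reads
  filler <- pmax(0L, 3000L - rowSums(counts))
  counts <- cbind(counts, filler = as.integer(filler))
  list(counts = counts, meta = meta)
}

# Circular distance between two genome positions.
circular_dist <- function(a, b, len) {
  d <- abs(a - b) %% len
  min(d, len - d)
}

# Multinomial counts over log-normal basis abundances, optionally with one
# planted correlated pair (species 1 and 2).
make_compositional_counts <- function(n, d, depth = 2000, rho_pair = NULL,
                                      seed = 1) {
  set.seed(seed)
  z <- matrix(rnorm(n * d), n, d)
  if (!is.null(rho_pair)) {
    z[, 2] <- rho_pair * z[, 1] + sqrt(1 - rho_pair^2) * z[, 2]
  }
  mu <- rnorm(d, 2, 1)
  basis <- exp(1.5 * z + matrix(rep(mu, each = n), n, d))
  frac <- basis / rowSums(basis)
  counts <- t(apply(frac, 1, function(p) rmultinom(1, depth, p)))
  colnames(counts) <- paste0("sp", seq_len(d))
  rownames(counts) <- paste0("s", seq_len(n))
  counts
}

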