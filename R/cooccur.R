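# SparCC compositional co-occurrence estimation and thresholded network
# construction/intersection.

#' Restrict a count matrix to samples usable for network inference
#'
#' Keeps samples in which at least two species are called present.
#'
#' @param presence A `presence_matrix` (post-decontamination presence is
#'   obtained by subsetting its columns to the survivor list).
#' @param species Optional species subset (e.g. decontamination survivors).
#' @return The zeroed count matrix restricted to qualifying samples (and to
#'   `species` when given).
#' @export
select_network_samples <- function(presence, species = NULL) {
  pm <- presence$present
  zc <- presence$zeroed_counts
  if (!is.null(species)) {
    pm <- pm[, species, drop = FALSE]
    zc <- zc[, species, drop = FALSE]
  }
  keep <- rowSums(pm) >= 2L
  if (!any(keep)) stop("no sample has at least two present species")
  zc[keep, , drop = FALSE]
}

# Basis correlations from a matrix of log fractions (samples x species),
# solving the log-ratio variance system under the sparsity assumption with
# iterative exclusion of the strongest pairs.
sparcc_from_logfrac <- function(logx, n_exclusion_iters = 10L,
                                exclusion_threshold = 0.1) {
  d <- ncol(logx)
  V <- stats::cov(logx)
  vd <- diag(V)
  # t_ij = var(log(x_i/x_j)) = V_ii + V_jj - 2 V_ij
  tmat <- outer(vd, vd, "+") - 2 * V
  diag(tmat) <- 0
  M <- matrix(1, d, d)
  diag(M) <- d - 1
  excluded <- matrix(FALSE, d, d)
  solve_rho <- function() {
    t_eff <- tmat
    t_eff[excluded] <- 0
    w <- solve(M, rowSums(t_eff))
    w <- pmax(w, 1e-12)
    rho <- (outer(w, w, "+") - tmat) / (2 * sqrt(outer(w, w)))
    rho <- pmin(pmax(rho, -1), 1)
    diag(rho) <- 1
    rho
  }
  rho <- solve_rho()
  for (it in seq_len(n_exclusion_iters)) {
    cand <- abs(rho)
    cand[excluded] <- 0
    diag(cand) <- 0
    # do not let a component's effective degree drop below 3
    deg <- diag(M)
    low <- deg <= 3
    cand[low, ] <- 0
    cand[, low] <- 0
    mx <- max(cand)
    if (mx <= exclusion_threshold) break
    ij <- which(cand == mx, arr.ind = TRUE)[1L, ]
    i <- ij[1L]; j <- ij[2L]
    excluded[i, j] <- excluded[j, i] <- TRUE
    M[i, j] <- M[j, i] <- 0
    M[i, i] <- M[i, i] - 1
    M[j, j] <- M[j, j] - 1
    rho <- solve_rho()
  }
  rho
}

#' SparCC correlations from a count matrix
#'
#' Estimates correlations between underlying (basis) abundances from
#' compositional count data: per-sample fractions are drawn from a
#' Dirichlet posterior (counts + `pseudocount`), log-ratio variances
#' `t_ij = var(log(x_i/x_j))` are computed, basis variances are solved from
#' the linear system implied by the sparsity assumption, and the strongest
#' correlated pairs above `exclusion_threshold` are iteratively excluded
#' and the system re-solved. The final correlation matrix is the average
#' over `n_draws` Dirichlet resamples; `n_draws = 0` uses the point
#' estimate fractions `(counts + pseudocount) / total` instead (useful for
#' exact checks).
#'
#' @param counts samples x species count matrix.
#' @param n_exclusion_iters Maximum strong-pair exclusion rounds (default
#'   10).
#' @param exclusion_threshold Correlation magnitude above which a pair is
#'   excluded from the basis-variance system (default 0.1).
#' @param pseudocount Added to every count before forming fractions
#'   (default 1).
#' @param n_draws Number of Dirichlet resamples to average over (default
#'   20).
#' @param seed Integer seed for the Dirichlet draws.
#' @return Symmetric correlation matrix with unit diagonal, entries in
#'   `[-1, 1]`.
#' @export
sparcc <- function(counts, n_exclusion_iters = 10L, exclusion_threshold = 0.1,
                   pseudocount = 1, n_draws = 20L, seed = 1L) {
  d <- ncol(counts)
  if (d < 4L) stop("SparCC needs at least 4 species (basis system underdetermined)")
  if (nrow(counts) < 10L) stop("SparCC needs at least 10 samples")
  alpha <- counts + pseudocount
  if (n_draws == 0L) {
    frac <- alpha / rowSums(alpha)
    check_variance(log(frac))
    return(finalize_rho(sparcc_from_logfrac(log(frac), n_exclusion_iters,
                                            exclusion_threshold), colnames(counts)))
  }
  rng <- local_rng(seed)
  on.exit(rng$restore())
  acc <- matrix(0, d, d)
  for (k in seq_len(n_draws)) {
    # Dirichlet via normalized gamma draws, rowwise
    g <- matrix(stats::rgamma(length(alpha), shape = alpha, rate = 1),
                nrow = nrow(alpha))
    frac <- g / rowSums(g)
    logx <- log(frac)
    check_variance(logx)
    acc <- acc + sparcc_from_logfrac(logx, n_exclusion_iters, exclusion_threshold)
  }
  finalize_rho(acc / n_draws, colnames(counts))
}

check_variance <- function(logx) {
  v <- apply(logx, 2L, stats::var)
  if (any(!is.finite(v)) || any(v == 0)) {
    stop("zero or undefined log-abundance variance for species: ",
         paste(colnames(logx)[!is.finite(v) | v == 0], collapse = ", "))
  }
}

finalize_rho <- function(rho, species) {
  rho <- (rho + t(rho)) / 2
  rho <- pmin(pmax(rho, -1), 1)
  diag(rho) <- 1
  dimnames(rho) <- list(species, species)
  rho
}

#' Build a thresholded co-occurrence network
#'
#' Keeps the undirected edge (a, b) when `|rho| > threshold` (strict). All
#' species remain as nodes; isolated nodes are allowed.
#'
#' @param corr Correlation matrix from [sparcc()].
#' @param threshold Correlation magnitude threshold in `[0, 1)`.
#' @return A `cooccurrence_network`: list with `nodes`, `edges`
#'   (data.frame species_a, species_b, rho with `species_a < species_b`)
#'   and `threshold`.
#' @export
build_network <- function(corr, threshold) {
  if (threshold < 0 || threshold >= 1) stop("threshold must be in [0, 1)")
  sp <- colnames(corr)
  ut <- upper.tri(corr)
  keep <- ut & abs(corr) > threshold
  idx <- which(keep, arr.ind = TRUE)
  edges <- data.frame(species_a = sp[idx[, 1L]],
                      species_b = sp[idx[, 2L]],
                      rho = corr[keep],
                      stringsAsFactors = FALSE)
  swap <- edges$species_a > edges$species_b
  tmp <- edges$species_a[swap]
  edges$species_a[swap] <- edges$species_b[swap]
  edges$species_b[swap] <- tmp
  edges <- edges[order(edges$species_a, edges$species_b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = sp, edges = edges, threshold = threshold),
            class = "cooccurrence_network")
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat(sprintf("cooccurrence_network: %d nodes, %d edges (|rho| > %g)\n",
              length(x$nodes), nrow(x$edges), x$threshold))
  invisible(x)
}

#' Intersect the edge sets of several networks
#'
#' An edge is retained when the same unordered species pair appears in
#' every input network, regardless of its correlation there; per-network
#' correlations are reported side by side.
#'
#' @param networks List of at least two `cooccurrence_network` objects.
#' @return A `cooccurrence_network` whose edge table has one `rho_<i>`
#'   column per input network; nodes are the union of input node sets.
#' @export
intersect_networks <- function(networks) {
  if (length(networks) < 2L) stop("need at least 2 networks to intersect")
  keys <- lapply(networks, function(nw) {
    paste(nw$edges$species_a, nw$edges$species_b, sep = "\r")
  })
  common <- Reduce(intersect, keys)
  parts <- strsplit(common, "\r", fixed = TRUE)
  edges <- data.frame(
    species_a = vapply(parts, `[[`, character(1), 1L),
    species_b = vapply(parts, `[[`, character(1), 2L),
    stringsAsFactors = FALSE
  )
  for (i in seq_along(networks)) {
    edges[[paste0("rho_", i)]] <- networks[[i]]$edges$rho[
      match(common, keys[[i]])]
  }
  edges <- edges[order(edges$species_a, edges$species_b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = sort(unique(unlist(lapply(networks, `[[`, "nodes")))),
                 edges = edges,
                 threshold = vapply(networks, `[[`, numeric(1), "threshold")),
            class = "cooccurrence_network")
}

#' Write a network as edge-list TSV and optionally GraphML
#'
#' @param network A `cooccurrence_network`.
#' @param tsv_path Path for the edge-list TSV (`NULL` to skip).
#' @param graphml_path Path for a GraphML export via igraph (`NULL` to
#'   skip).
#' @export
write_network <- function(network, tsv_path = NULL, graphml_path = NULL) {
  if (!is.null(tsv_path)) {
    utils::write.table(network$edges, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(graphml_path)) {
    g <- igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                       vertices = network$nodes)
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  invisible(network)
}
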