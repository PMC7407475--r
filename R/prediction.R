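#' Build the initial training panel
#'
#' The training panel (TP) is the fixed-size, age-ordered set of genotyped
#' and phenotyped records the prediction model is fit on. Initially it holds
#' the whole founder collection; [tails_update()] then slides it forward
#' cycle by cycle. Genotype codes are stored over the prediction markers
#' only (QTL are never observable as markers).
#'
#' @param pop a `gs_pop` of the initial (founder) individuals.
#' @param phenotypes tibble with columns `id`, `value` covering `pop`.
#' @param q a `gs_qtl`; its `marker_idx` defines the marker set.
#' @param capacity panel capacity; defaults to the initial panel size.
#' @return An object of class `gs_tp`.
#' @export
training_panel <- function(pop, phenotypes, q, capacity = NULL) {
  i <- match(pop$id, phenotypes$id)
  if (anyNA(i)) stop("phenotypes missing for some individuals", call. = FALSE)
  Z <- geno_codes(pop, q$marker_idx)
  tp <- structure(
    list(Z = Z, y = phenotypes$value[i],
         id = pop$id, cycle_added = rep(0L, n_ind(pop)),
         marker_idx = q$marker_idx, marker_id = colnames(Z),
         capacity = if (is.null(capacity)) n_ind(pop) else as.integer(capacity)),
    class = "gs_tp")
  if (nrow(tp$Z) > tp$capacity)
    stop("initial panel exceeds capacity", call. = FALSE)
  tp
}

#' @export
print.gs_tp <- function(x, ...) {
  cat(sprintf("<gs_tp> %d/%d records x %d markers (cycles %d..%d)\n",
              nrow(x$Z), x$capacity, ncol(x$Z),
              min(x$cycle_added), max(x$cycle_added)))
  invisible(x)
}

#' Minor-allele-frequency filter
#'
#' The allele frequency of the +1-coded allele at a marker is
#' `p = sum(z + 1) / (2n)` over genotype codes `z` (a heterozygote
#' contributes one copy of each allele). Markers whose minor allele
#' frequency is strictly smaller than the threshold are removed; a MAF of
#' exactly the threshold is retained.
#'
#' @param Z genotype code matrix (-1/0/+1), individuals in rows.
#' @param threshold MAF removal threshold.
#' @return Integer vector of retained column indices.
#' @export
maf_filter <- function(Z, threshold = 0.03) {
  if (nrow(Z) == 0) stop("empty training panel", call. = FALSE)
  p <- colMeans(Z + 1) / 2
  maf <- pmin(p, 1 - p)
  unname(which(maf >= threshold))
}

#' Fit the ridge-regression BLUP model by REML
#'
#' Fits `y = 1 beta + Z u + eps` with `u ~ N(0, sigma_u2 I)` and
#' `eps ~ N(0, sigma_e2 I)` on the training panel after MAF filtering.
#' The restricted likelihood is profiled over the variance ratio
#' `delta = sigma_e2 / sigma_u2` using a single eigendecomposition of the
#' doubly centered marker kernel `Z Z'` (EMMA-style), then optimized in one
#' dimension; the fit is deterministic for fixed input. Filtered markers are
#' carried with effect zero.
#'
#' @param tp a `gs_tp`.
#' @param maf_threshold MAF threshold applied to the panel before fitting.
#' @param delta_range log10 search range for the variance ratio.
#' @param tol convergence tolerance of the one-dimensional optimization.
#' @return An object of class `gs_rrblup`: `beta`, `u` (effects of retained
#'   markers), `retained` (columns of the marker set kept), `retained_loci`
#'   (global locus indices), `sigma_u2`, `sigma_e2`, `delta`, `loglik`
#'   (restricted), `n`, `k`.
#' @export
fit_rrblup <- function(tp, maf_threshold = 0.03, delta_range = c(-8, 8),
                       tol = 1e-6) {
  retained <- maf_filter(tp$Z, maf_threshold)
  if (length(retained) < 1) stop("no markers retained", call. = FALSE)
  n <- nrow(tp$Z)
  if (n < 2) stop("need at least two training records", call. = FALSE)
  y <- tp$y
  if (var(y) == 0) stop("zero-variance phenotypes", call. = FALSE)
  Z <- tp$Z[, retained, drop = FALSE]
  storage.mode(Z) <- "double"

  K <- tcrossprod(Z)
  # project out the intercept: S (K + I) S with S = I - 11'/n (double
  # centering). Offsetting by I makes the intercept the unique null
  # direction, so the retained n-1 eigenvectors are all orthogonal to 1.
  Kp <- K + diag(n)
  SKS <- sweep(sweep(Kp, 1, colMeans(Kp)), 2, rowMeans(Kp)) + mean(Kp)
  eig <- eigen(SKS, symmetric = TRUE)
  xi <- pmax(eig$values[seq_len(n - 1)] - 1, 0)
  eta <- drop(crossprod(eig$vectors[, seq_len(n - 1), drop = FALSE], y))
  m <- n - 1

  restll <- function(log10d) {
    d <- 10^log10d
    denom <- xi + d
    0.5 * (m * log(m / (2 * pi)) - m - m * log(sum(eta^2 / denom)) -
             sum(log(denom)))
  }
  grid <- seq(delta_range[1], delta_range[2], length.out = 81)
  ll <- vapply(grid, restll, numeric(1))
  j <- which.max(ll)
  lo <- grid[max(1, j - 1)]; hi <- grid[min(length(grid), j + 1)]
  opt <- optimize(restll, c(lo, hi), maximum = TRUE, tol = tol)
  delta <- 10^opt$maximum

  sigma_u2 <- sum(eta^2 / (xi + delta)) / m
  sigma_e2 <- delta * sigma_u2
  # GLS intercept and marker BLUPs through the kernel
  Vinv <- solve(K + delta * diag(n), cbind(y, 1))
  beta <- sum(Vinv[, 2] * y) / sum(Vinv[, 2])
  u <- drop(crossprod(Z, Vinv[, 1] - beta * Vinv[, 2]))

  structure(
    list(beta = beta, u = u, retained = retained,
         retained_loci = tp$marker_idx[retained],
         marker_id = tp$marker_id[retained],
         sigma_u2 = sigma_u2, sigma_e2 = sigma_e2, delta = delta,
         loglik = opt$objective, n = n, k = length(retained)),
    class = "gs_rrblup")
}

#' @export
print.gs_rrblup <- function(x, ...) {
  cat(sprintf(
    "<gs_rrblup> n = %d, markers = %d, sigma_u2 = %.4g, sigma_e2 = %.4g (delta = %.4g)\n",
    x$n, x$k, x$sigma_u2, x$sigma_e2, x$delta))
  invisible(x)
}

#' @export
tidy.gs_rrblup <- function(x, ...) {
  tibble::tibble(marker_id = x$marker_id, locus = x$retained_loci,
                 effect = x$u)
}

#' @export
glance.gs_rrblup <- function(x, ...) {
  tibble::tibble(n_obs = x$n, n_markers = x$k, beta = x$beta,
                 sigma_u2 = x$sigma_u2, sigma_e2 = x$sigma_e2,
                 delta = x$delta, loglik = x$loglik)
}

#' Genomic estimated breeding values
#'
#' `gebv_i = beta + sum_j Z_ij u_j` over the retained markers. The intercept
#' is a constant shift, so rankings are unaffected by it.
#'
#' @param pop a `gs_pop` whose loci include all retained markers.
#' @param model a `gs_rrblup`.
#' @return A tibble with columns `id`, `gebv`.
#' @export
predict_gebv <- function(pop, model) {
  if (max(model$retained_loci) > n_loci(pop))
    stop("marker index mismatch between model and population", call. = FALSE)
  Z <- geno_codes(pop, model$retained_loci)
  storage.mode(Z) <- "double"
  tibble::tibble(id = pop$id, gebv = model$beta + unname(drop(Z %*% model$u)))
}

#' Update the training panel by the tails rule
#'
#' Selects the `n_new/2` highest-GEBV and `n_new/2` lowest-GEBV individuals
#' of the breeding population (disjoint sets), phenotypes them in one event,
#' appends their records, and evicts the `n_new` oldest records so the panel
#' stays at capacity. Ties in GEBV rank are broken by insertion order.
#'
#' @param tp a `gs_tp`.
#' @param pop the breeding population (`gs_pop`).
#' @param gebvs tibble `id`, `gebv` for `pop`.
#' @param q a `gs_qtl` (marker set must match the panel's).
#' @param vs a `gs_varsettings` used to phenotype the selected individuals.
#' @param n_new number of records exchanged (even).
#' @param cycle cycle stamp for the new records.
#' @return The updated `gs_tp`.
#' @export
tails_update <- function(tp, pop, gebvs, q, vs, n_new = 150, cycle) {
  stopifnot(n_new %% 2 == 0)
  if (n_ind(pop) < n_new)
    stop("breeding population smaller than the tails update size", call. = FALSE)
  if (!identical(q$marker_idx, tp$marker_idx))
    stop("marker set mismatch between panel and QTL model", call. = FALSE)
  o <- order(gebvs$gebv, decreasing = TRUE)         # stable: ties by position
  sel <- c(head(o, n_new / 2), rev(tail(o, n_new / 2)))
  chosen <- subset_pop(pop, gebvs$id[sel])
  ph <- simulate_phenotypes(chosen, q, vs, cycle = cycle)
  Znew <- geno_codes(chosen, tp$marker_idx)
  keep <- seq_len(nrow(tp$Z)) > (nrow(tp$Z) + n_new - tp$capacity)
  tp$Z <- rbind(tp$Z[keep, , drop = FALSE], Znew)
  tp$y <- c(tp$y[keep], ph$value)
  tp$id <- c(tp$id[keep], chosen$id)
  tp$cycle_added <- c(tp$cycle_added[keep], rep(as.integer(cycle), n_new))
  tp
}
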