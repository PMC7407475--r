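#' Truncation selection
#'
#' The `n` individuals with the highest GEBVs; ties are broken by insertion
#' order (stable sort) for reproducibility.
#'
#' @param gebvs tibble with columns `id`, `gebv`.
#' @param n number of individuals to select.
#' @return Character vector of `n` selected ids, highest GEBV first.
#' @export
truncation_select <- function(gebvs, n) {
  if (n > nrow(gebvs)) stop("cannot select more individuals than available",
                            call. = FALSE)
  gebvs$id[order(gebvs$gebv, decreasing = TRUE)][seq_len(n)]
}

#' Random mating
#'
#' Pairs an even number of parents into couples by a uniform random perfect
#' matching; every parent appears in exactly one couple.
#'
#' @param parent_ids character vector of parent ids (even length).
#' @return A tibble with columns `couple`, `p1`, `p2`.
#' @export
random_mating <- function(parent_ids) {
  n <- length(parent_ids)
  if (n %% 2 != 0) stop("random mating requires an even number of parents",
                        call. = FALSE)
  s <- sample(parent_ids)
  tibble::tibble(couple = seq_len(n / 2),
                 p1 = s[seq(1, n, by = 2)], p2 = s[seq(2, n, by = 2)])
}

#' Marker-variance score of a parental set
#'
#' `sum_j var(Z[, j]) * p_j`, where the variance is the sample variance
#' (denominator n - 1) of the selected parents' genotype codes at marker j
#' and `p` is a 0/1 mask of markers whose allelic variation is not yet
#' secured in the selected set. With fewer than two parents the variance is
#' defined as 0.
#'
#' @param Z_selected genotype code matrix of the selected parents.
#' @param p 0/1 (or logical) vector over the markers.
#' @return The score, a single number.
#' @export
fscore <- function(Z_selected, p) {
  if (ncol(Z_selected) != length(p))
    stop("mask length must equal the marker count", call. = FALSE)
  if (nrow(Z_selected) < 2) return(0)
  v <- matrixStats_colVars(Z_selected)
  sum(v * as.numeric(p))
}

# column sample variances without extra dependencies
matrixStats_colVars <- function(Z) {
  n <- nrow(Z)
  m <- colMeans(Z)
  (colSums(Z^2) - n * m^2) / (n - 1)
}

#' Scoping parental selection and mate allocation
#'
#' Pre-selects the top `SR` fraction of the breeding population by GEBV, then
#' builds couples sequentially: P1 of each couple is the highest-GEBV
#' candidate not yet selected; P2 is the candidate that maximizes the
#' marker-variance score [fscore()] of the selected parents plus the
#' candidate, restricted by a per-marker mask `p`. After each completed
#' couple, `p_j` is set to 0 for every marker whose two alleles are both
#' present among the selected parents (a heterozygote carries both); when
#' the mask becomes all zero it is reset to all ones. Ties are broken by
#' higher GEBV, then lower insertion index. At `SR` covering exactly
#' `2 * n_couples` candidates the selected set coincides with truncation
#' selection and only the pairing differs.
#'
#' @param gebvs tibble `id`, `gebv` for the breeding population.
#' @param pop the breeding population (`gs_pop`).
#' @param q a `gs_qtl`; its prediction markers define the score's marker set.
#'   Pass `NULL` to score over all loci.
#' @param SR scoping rate in `[0.1, 1]`: fraction pre-selected.
#' @param n_couples number of couples to form.
#' @return A tibble `couple`, `p1`, `p2`, with attribute `"selected"` holding
#'   the ids in selection order.
#' @export
scoping_select <- function(gebvs, pop, q = NULL, SR = 0.3, n_couples = 50) {
  stopifnot(SR >= 0.1, SR <= 1)
  n_pre <- ceiling(SR * nrow(gebvs))
  if (n_pre < 2 * n_couples)
    stop("pre-selection smaller than the number of parents needed",
         call. = FALSE)
  cand_ids <- truncation_select(gebvs, n_pre)   # GEBV order, best first
  marker_idx <- if (is.null(q)) seq_len(n_loci(pop)) else q$marker_idx
  Zc <- geno_codes(subset_pop(pop, cand_ids), marker_idx)
  storage.mode(Zc) <- "double"
  k <- ncol(Zc)
  Zc2 <- Zc^2                                   # |z|, since codes are -1/0/+1

  p <- rep(1, k)
  seen_lo <- rep(FALSE, k)   # first allele observed among selected
  seen_hi <- rep(FALSE, k)   # second allele observed
  avail <- rep(TRUE, n_pre)
  S1 <- numeric(k); S2 <- numeric(k)            # marker sums over selected
  n_sel <- 0L
  sel_order <- integer(0)

  add_parent <- function(i) {
    z <- Zc[i, ]
    S1 <<- S1 + z; S2 <<- S2 + z^2
    seen_lo <<- seen_lo | z <= 0
    seen_hi <<- seen_hi | z >= 0
    n_sel <<- n_sel + 1L
    avail[i] <<- FALSE
    sel_order <<- c(sel_order, i)
  }

  p1 <- integer(n_couples); p2 <- integer(n_couples)
  for (cp in seq_len(n_couples)) {
    i1 <- which(avail)[1]                       # highest remaining GEBV
    add_parent(i1)
    p1[cp] <- i1

    idx <- which(avail)
    # score of adding candidate c to the current selected set, masked by p:
    # sum_j p_j * ((S2_j + z^2) - (S1_j + z)^2 / (n+1)) / n
    np1 <- n_sel + 1
    base <- sum(p * (S2 - S1^2 / np1))
    sc <- (base +
             drop(Zc2[idx, , drop = FALSE] %*% p) * (n_sel / np1) -
             drop(Zc[idx, , drop = FALSE] %*% (p * S1)) * (2 / np1)) / n_sel
    best <- idx[which.max(sc)]                  # ties: first = higher GEBV
    add_parent(best)
    p2[cp] <- best

    p <- as.numeric(!(seen_lo & seen_hi))
    if (all(p == 0)) p <- rep(1, k)
  }
  out <- tibble::tibble(couple = seq_len(n_couples),
                        p1 = cand_ids[p1], p2 = cand_ids[p2])
  attr(out, "selected") <- cand_ids[sel_order]
  out
}

#' VanRaden genomic relationship matrix
#'
#' `G = M M' / (2 sum_i P_i (1 - P_i))`, where column i of `M` is
#' `Z_i - 2 (P_i - 0.5)` and `P_i` is the frequency of the +1-coded allele
#' computed from `freq_source` (by default the matrix itself; in the breeding
#' loop, the current breeding population). Monomorphic markers contribute
#' zero to both numerator and denominator.
#'
#' @param Z genotype code matrix (-1/0/+1) of the individuals of interest.
#' @param freq_source matrix supplying the allele frequencies (same marker
#'   columns); defaults to `Z`.
#' @return An object of class `gs_grm`: list with `G` (n x n matrix) and
#'   `allele_freqs`.
#' @export
vanraden_G <- function(Z, freq_source = Z) {
  if (ncol(Z) != ncol(freq_source))
    stop("marker columns of Z and freq_source differ", call. = FALSE)
  P <- colMeans(freq_source + 1) / 2
  den <- 2 * sum(P * (1 - P))
  if (den == 0) stop("all markers monomorphic: zero denominator", call. = FALSE)
  M <- sweep(Z, 2, 2 * (P - 0.5))
  structure(list(G = tcrossprod(M) / den, allele_freqs = P), class = "gs_grm")
}

#' @export
print.gs_grm <- function(x, ...) {
  cat(sprintf("<gs_grm> %d x %d genomic relationship matrix\n",
              nrow(x$G), ncol(x$G)))
  invisible(x)
}

#' Population merit
#'
#' `B = g_m - c * phi`, the mean (estimated) genetic value of a parental set
#' penalized by its average genomic relationship.
#'
#' @param mean_value mean GEBV of the parental set.
#' @param c penalty weight.
#' @param avg_relationship mean off-diagonal genomic relationship of the set.
#' @return The merit, a single number.
#' @export
population_merit <- function(mean_value, c, avg_relationship) {
  mean_value - c * avg_relationship
}

#' Population-merit parental selection
#'
#' Starts from the truncation-selected top `n` and repeatedly passes over the
#' parents; each parent in turn is swapped with the non-selected individual
#' of the breeding population giving the largest strict increase in the
#' population merit `B = g_m - c * phi`, where `g_m` is the mean GEBV of the
#' selected set and `phi` its mean off-diagonal genomic relationship (G built
#' on the whole breeding population). The search stops at a fixed point (a
#' full pass with no accepted swap) or after `max_passes`. The final set is
#' mated randomly.
#'
#' @param gebvs tibble `id`, `gebv` for the breeding population.
#' @param pop the breeding population (`gs_pop`).
#' @param q a `gs_qtl` defining the marker set for G; `NULL` for all loci.
#' @param c penalty weight.
#' @param n number of parents (even).
#' @param max_passes pass cap for the iterative improvement.
#' @return A tibble `couple`, `p1`, `p2`; attributes `"selected"` (ids),
#'   `"merit"`, `"passes"` and `"converged"`.
#' @export
pm_select <- function(gebvs, pop, q = NULL, c = 20, n = 100,
                      max_passes = 100) {
  N <- nrow(gebvs)
  if (N <= n) stop("breeding population must exceed the number of parents",
                   call. = FALSE)
  marker_idx <- if (is.null(q)) seq_len(n_loci(pop)) else q$marker_idx
  Z <- geno_codes(pop, marker_idx)[gebvs$id, , drop = FALSE]
  storage.mode(Z) <- "double"
  G <- vanraden_G(Z)$G
  g <- gebvs$gebv

  sel <- match(truncation_select(gebvs, n), gebvs$id)
  in_sel <- rep(FALSE, N); in_sel[sel] <- TRUE
  s <- rowSums(G[, sel, drop = FALSE])      # s_i = sum_{j in sel} G_ij
  Tsum <- sum(s[sel]) - sum(diag(G)[sel])   # off-diagonal pair sum (x2)
  sumg <- sum(g[sel])
  denom <- n * (n - 1)
  merit <- function(sg, Ts) sg / n - c * Ts / denom

  passes <- 0L; converged <- FALSE
  while (passes < max_passes) {
    passes <- passes + 1L
    changed <- FALSE
    for (pos in seq_len(n)) {
      r <- sel[pos]
      out <- which(!in_sel)
      # remove r, then add candidate cnd
      T_wo <- Tsum - 2 * (s[r] - G[r, r])
      sg_wo <- sumg - g[r]
      T_new <- T_wo + 2 * (s[out] - G[out, r])
      B_new <- merit(sg_wo + g[out], T_new)
      B_cur <- merit(sumg, Tsum)
      j <- which.max(B_new)
      if (B_new[j] > B_cur + 1e-12) {
        cnd <- out[j]
        s <- s - G[, r] + G[, cnd]
        Tsum <- T_wo + 2 * (s[cnd] - G[cnd, cnd])
        sumg <- sg_wo + g[cnd]
        in_sel[r] <- FALSE; in_sel[cnd] <- TRUE
        sel[pos] <- cnd
        changed <- TRUE
      }
    }
    if (!changed) { converged <- TRUE; break }
  }
  if (!converged)
    warning("population-merit optimization hit the pass cap", call. = FALSE)
  ids <- gebvs$id[sel]
  out <- random_mating(ids)
  attr(out, "selected") <- ids
  attr(out, "merit") <- merit(sumg, Tsum)
  attr(out, "passes") <- passes
  attr(out, "converged") <- converged
  out
}

#' Maximum-variance-total criterion
#'
#' `(1/n) sum_i ((1 + F_i) - 2 * Gbar_p)`, with `F_i = G_ii - 1` the genomic
#' inbreeding coefficient of parent i and `Gbar_p` the mean off-diagonal
#' genomic relationship of the parental set; equivalently
#' `mean(diag(G)) - 2 * mean(offdiag(G))`.
#'
#' @param G_sel genomic relationship matrix restricted to the parents
#'   (matrix or `gs_grm`).
#' @return The criterion, a single number.
#' @export
mvt_criterion <- function(G_sel) {
  if (inherits(G_sel, "gs_grm")) G_sel <- G_sel$G
  n <- nrow(G_sel)
  if (n < 2) stop("need at least two parents", call. = FALSE)
  offdiag_mean <- (sum(G_sel) - sum(diag(G_sel))) / (n * (n - 1))
  mean(diag(G_sel)) - 2 * offdiag_mean
}

#' Maximum-variance-total parental selection
#'
#' Pre-selects `pre_n` individuals by truncation; P1 = the top `n/2` by GEBV
#' (fixed), P2 = the next `n/2`. P2 members are then iteratively replaced by
#' unused pre-selected individuals, accepting on each step the replacement
#' with the largest strict increase of [mvt_criterion()] over the full
#' parental set, until a full pass yields no improvement or `max_passes` is
#' hit. Each P1 is finally paired with a random distinct P2.
#'
#' @param gebvs tibble `id`, `gebv` for the breeding population.
#' @param pop the breeding population (`gs_pop`).
#' @param q a `gs_qtl` defining the marker set for G; `NULL` for all loci.
#' @param pre_n pre-selection size.
#' @param n number of parents (even).
#' @param max_passes pass cap.
#' @return A tibble `couple`, `p1`, `p2`; attributes `"selected"`,
#'   `"criterion"`, `"passes"`, `"converged"`.
#' @export
mvt_select <- function(gebvs, pop, q = NULL, pre_n = 300, n = 100,
                       max_passes = 100) {
  stopifnot(n %% 2 == 0)
  if (nrow(gebvs) < pre_n || pre_n < n)
    stop("need population >= pre_n >= n", call. = FALSE)
  marker_idx <- if (is.null(q)) seq_len(n_loci(pop)) else q$marker_idx
  pre_ids <- truncation_select(gebvs, pre_n)
  # G among pre-selected individuals, allele frequencies from the whole
  # breeding population
  Zall <- geno_codes(pop, marker_idx)[gebvs$id, , drop = FALSE]
  storage.mode(Zall) <- "double"
  G <- vanraden_G(Zall[pre_ids, , drop = FALSE], freq_source = Zall)$G

  half <- n / 2
  p1_pos <- seq_len(half)                 # indices into pre_ids
  p2 <- seq(half + 1, n)
  in_set <- rep(FALSE, pre_n); in_set[c(p1_pos, p2)] <- TRUE
  cur <- c(p1_pos, p2)
  s <- rowSums(G[, cur, drop = FALSE])
  D <- sum(diag(G)[cur])
  Tsum <- sum(s[cur]) - D
  denom <- n * (n - 1)
  crit <- function(Dv, Ts) Dv / n - 2 * Ts / denom

  passes <- 0L; converged <- FALSE
  while (passes < max_passes) {
    passes <- passes + 1L
    changed <- FALSE
    for (pos in seq_len(half)) {
      r <- p2[pos]
      pool <- which(!in_set)
      if (length(pool) == 0) break
      D_wo <- D - G[r, r]
      T_wo <- Tsum - 2 * (s[r] - G[r, r])
      D_new <- D_wo + diag(G)[pool]
      T_new <- T_wo + 2 * (s[pool] - G[pool, r])
      v_new <- crit(D_new, T_new)
      v_cur <- crit(D, Tsum)
      j <- which.max(v_new)
      if (v_new[j] > v_cur + 1e-12) {
        cnd <- pool[j]
        s <- s - G[, r] + G[, cnd]
        D <- D_wo + G[cnd, cnd]
        Tsum <- T_wo + 2 * (s[cnd] - G[cnd, cnd])
        in_set[r] <- FALSE; in_set[cnd] <- TRUE
        p2[pos] <- cnd
        changed <- TRUE
      }
    }
    if (!changed) { converged <- TRUE; break }
  }
  if (!converged)
    warning("maximum-variance-total optimization hit the pass cap",
            call. = FALSE)
  p2_ids <- pre_ids[sample(p2)]
  out <- tibble::tibble(couple = seq_len(half),
                        p1 = pre_ids[p1_pos], p2 = p2_ids)
  attr(out, "selected") <- c(pre_ids[p1_pos], pre_ids[p2])
  attr(out, "criterion") <- crit(D, Tsum)
  attr(out, "passes") <- passes
  attr(out, "converged") <- converged
  out
}
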