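# small in-code fixtures shared across the suite

make_map <- function(n_loci, n_chrom = 1, len = 100) {
  per <- rep(n_loci %/% n_chrom, n_chrom)
  extra <- n_loci %% n_chrom
  if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
  tibble::tibble(
    locus_id = sprintf("M%04d", seq_len(n_loci)),
    chromosome = rep(seq_len(n_chrom), per),
    position_cM = unlist(lapply(per, function(k)
      if (k == 1) 0 else seq(0, len, length.out = k))))
}

# population from a -1/0/+1 code matrix (het stored as 0|1)
make_pop <- function(codes, map = NULL, id = NULL) {
  codes <- as.matrix(codes)
  if (is.null(map)) map <- make_map(ncol(codes))
  if (is.null(id)) id <- sprintf("I%03d", seq_len(nrow(codes)))
  h1 <- matrix(as.integer(codes == 1), nrow(codes))
  h2 <- matrix(as.integer(codes >= 0), nrow(codes))
  new_population(id, h1, h2, map)
}

# QTL model with hand-chosen effects/orientation (bypasses sampling)
make_qtl <- function(qtl_idx, n_loci, effects, favorable = NULL, a = NA_real_) {
  L <- length(qtl_idx)
  if (is.null(favorable)) favorable <- rep(1L, L)
  structure(
    list(qtl_idx = as.integer(qtl_idx), L = L, a = a, effects = effects,
         favorable = as.integer(favorable),
         marker_idx = setdiff(seq_len(n_loci), qtl_idx),
         locus_id = sprintf("M%04d", qtl_idx)),
    class = "gs_qtl")
}

make_vs <- function(sigma_E2 = 0, sigma_R2 = 0, h2 = 0.5, n_env = 3,
                    sigma_g2_ref = 1) {
  structure(list(sigma_g2_ref = sigma_g2_ref, sigma_E2 = sigma_E2,
                 sigma_R2 = sigma_R2, h2 = h2, n_env = as.integer(n_env)),
            class = "gs_varsettings")
}

# random -1/0/+1 genotype matrix
rand_codes <- function(n, k, p_het = 0.2) {
  matrix(sample(c(-1L, 0L, 1L), n * k, replace = TRUE,
                prob = c((1 - p_het) / 2, p_het, (1 - p_het) / 2)),
         nrow = n)
}

# naive reference implementations used as independent oracles -----------------

fscore_brute <- function(Z, p) {
  if (nrow(Z) < 2) return(0)
  sum(apply(Z, 2, stats::var) * as.numeric(p))
}

vanraden_brute <- function(Z, Zf = Z) {
  P <- apply(Zf, 2, function(z) sum(z + 1) / (2 * length(z)))
  M <- Z
  for (i in seq_len(ncol(Z))) M[, i] <- Z[, i] - 2 * (P[i] - 0.5)
  G <- matrix(0, nrow(Z), nrow(Z))
  for (i in seq_len(nrow(Z))) for (j in seq_len(nrow(Z)))
    G[i, j] <- sum(M[i, ] * M[j, ])
  G / (2 * sum(P * (1 - P)))
}

merit_brute <- function(g_sel, G_sel, c) {
  n <- nrow(G_sel)
  off <- G_sel[upper.tri(G_sel) | lower.tri(G_sel)]
  mean(g_sel) - c * mean(off)
}

mvt_brute <- function(G_sel) {
  n <- nrow(G_sel)
  Fi <- diag(G_sel) - 1
  off <- G_sel[upper.tri(G_sel) | lower.tri(G_sel)]
  mean((1 + Fi) - 2 * mean(off))
}
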