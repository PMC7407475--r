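#' QTL fixation report
#'
#' A QTL is fixed when one of its alleles has frequency 1 in the population.
#' `fixed_gv` is the sum of `+a^k` over QTL fixed for the favorable allele
#' and `-a^k` over QTL fixed for the unfavorable allele; `max_reachable_gv`
#' adds `+a^k` for every QTL still segregating — the best genetic value the
#' population can still attain given what is already lost. Both are
#' normalized by the maximum genetic value `sum(a^k)`.
#'
#' @param pop a `gs_pop` (the breeding population).
#' @param q a `gs_qtl`.
#' @return A list with `fixed_gv`, `max_reachable_gv`, `pct_qtl_fixed`.
#' @export
fixation_report <- function(pop, q) {
  if (n_ind(pop) == 0) stop("empty population", call. = FALSE)
  s <- geno_codes(pop, q$qtl_idx)
  s <- sweep(s, 2, q$favorable, `*`)   # +1 = favorable allele homozygote
  fixed_fav <- colSums(s == 1L) == nrow(s)
  fixed_unf <- colSums(s == -1L) == nrow(s)
  tot <- sum(q$effects)
  fixed_gv <- (sum(q$effects[fixed_fav]) - sum(q$effects[fixed_unf])) / tot
  max_reach <- fixed_gv + sum(q$effects[!(fixed_fav | fixed_unf)]) / tot
  list(fixed_gv = fixed_gv, max_reachable_gv = max_reach,
       pct_qtl_fixed = mean(fixed_fav | fixed_unf))
}

#' Per-cycle summary metrics
#'
#' @param pop a `gs_pop` (the breeding population).
#' @param q a `gs_qtl`.
#' @param gebvs optional tibble `id`, `gebv`; when supplied, prediction
#'   accuracy is the Pearson correlation between GEBVs and raw genetic
#'   values (recorded as `NA` if either vector has zero variance).
#' @param cycle cycle index recorded on the row.
#' @return A one-row tibble: `cycle`, `mean_gv`, `top10_gv`, `fixed_gv`,
#'   `max_reachable_gv`, `pct_qtl_fixed`, `genetic_variance`, `accuracy`.
#'   Genetic values are normalized; the variance is on the raw-value scale.
#' @export
summarize_cycle <- function(pop, q, gebvs = NULL, cycle = 0L) {
  gv <- genetic_values(pop, q)
  fx <- fixation_report(pop, q)
  acc <- NA_real_
  if (!is.null(gebvs)) {
    g <- gebvs$gebv[match(pop$id, gebvs$id)]
    if (var(g) > 0 && var(gv$gv_raw) > 0) acc <- cor(g, gv$gv_raw)
  }
  tibble::tibble(
    cycle = as.integer(cycle),
    mean_gv = mean(gv$gv_norm),
    top10_gv = mean(sort(gv$gv_norm, decreasing = TRUE)[seq_len(min(10, nrow(gv)))]),
    fixed_gv = fx$fixed_gv,
    max_reachable_gv = fx$max_reachable_gv,
    pct_qtl_fixed = fx$pct_qtl_fixed,
    genetic_variance = var(gv$gv_raw),
    accuracy = acc)
}
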