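#' Sample a QTL model with geometric effects
#'
#' `L` causal loci are drawn uniformly at random from the map; every other
#' locus becomes a prediction marker (markers are never causal). The k-th
#' QTL (k = 1..L) has additive effect `a^k` with `a = (L - 1)/(L + 1)`:
#' the favorable homozygote scores `+a^k`, the heterozygote 0 and the
#' unfavorable homozygote `-a^k`. Which homozygote is favorable is drawn
#' uniformly per QTL. Dominance and epistasis are absent.
#'
#' @param map a marker-map tibble (or a `gs_pop`, whose map is used).
#' @param L number of QTL; must be smaller than the number of loci.
#' @param seed optional integer seed.
#' @return An object of class `gs_qtl` with fields `qtl_idx` (locus column
#'   indices of the QTL, in effect order), `L`, `a`, `effects` (`a^k`),
#'   `favorable` (+1 or -1: the genotype code of the favorable homozygote)
#'   and `marker_idx` (the non-causal prediction-marker columns).
#' @export
sample_qtl <- function(map, L = 100, seed = NULL) {
  if (inherits(map, "gs_pop")) map <- map$map
  m <- nrow(map)
  if (L >= m) stop("L must be smaller than the number of loci", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  idx <- sort(sample.int(m, L))
  # effect order is random among the chosen loci (position is irrelevant)
  idx <- sample(idx)
  a <- (L - 1) / (L + 1)
  structure(
    list(qtl_idx = idx, L = as.integer(L), a = a, effects = a^seq_len(L),
         favorable = sample(c(-1L, 1L), L, replace = TRUE),
         marker_idx = setdiff(seq_len(m), idx),
         locus_id = map$locus_id[idx]),
    class = "gs_qtl")
}

#' @export
print.gs_qtl <- function(x, ...) {
  cat(sprintf("<gs_qtl> L = %d QTL, a = %.4f, max genetic value = %.4f\n",
              x$L, x$a, sum(x$effects)))
  invisible(x)
}

#' Serialize a QTL model to TSV
#' @param q a `gs_qtl`.
#' @param file output path.
#' @return `q`, invisibly.
#' @export
write_qtl <- function(q, file) {
  readr::write_tsv(tibble::tibble(
    locus_id = q$locus_id, k = seq_len(q$L), effect = q$effects,
    favorable_allele = q$favorable), file)
  invisible(q)
}

#' True genetic values of a population
#'
#' The raw genetic value is the sum over QTL of `s_k * a^k`, where `s_k` is
#' +1 for the favorable homozygote, 0 for a heterozygote and -1 for the
#' unfavorable homozygote. The normalized value divides by the maximum
#' genetic value `sum(a^k)`, so an individual carrying every favorable
#' homozygote scores exactly 1.
#'
#' @param pop a `gs_pop`.
#' @param q a `gs_qtl` sharing the population's locus indexing.
#' @return A tibble with columns `id`, `gv_raw`, `gv_norm`.
#' @export
genetic_values <- function(pop, q) {
  s <- geno_codes(pop, q$qtl_idx)
  s <- sweep(s, 2, q$favorable, `*`)      # orient so +1 = favorable homozygote
  raw <- unname(drop(s %*% q$effects))
  tibble::tibble(id = pop$id, gv_raw = raw, gv_norm = raw / sum(q$effects))
}

#' Simulate gametes by meiosis
#'
#' Per chromosome, the crossover count is Poisson with mean equal to the map
#' length in Morgans, crossover positions are uniform, and the starting
#' haplotype is chosen with probability 1/2 (Haldane model: no interference,
#' no mutation). Randomness comes from R's RNG stream.
#'
#' @param pop a `gs_pop`.
#' @param parents integer or character indices, one per requested gamete
#'   (repeat an index for several independent gametes).
#' @return Integer 0/1 matrix, one gamete per row.
#' @export
make_gametes <- function(pop, parents) {
  if (is.character(parents)) parents <- match(parents, pop$id)
  if (anyNA(parents)) stop("unknown parent id", call. = FALSE)
  blk <- chrom_blocks(pop$map)
  gs_gametes_cpp(pop$h1, pop$h2, as.integer(parents), blk$first, blk$last,
                 pop$map$position_cM)
}

#' @describeIn make_gametes single gamete from one parent, as a 0/1 vector.
#' @param parent one parent index or id.
#' @export
meiosis <- function(pop, parent) drop(make_gametes(pop, parent))

#' Cross couples to produce offspring
#'
#' Each offspring receives one independent gamete from each parent of its
#' couple.
#'
#' @param pop a `gs_pop` containing all parents.
#' @param couples tibble with columns `p1`, `p2` (individual ids), one row per
#'   couple; `p1 != p2` within a couple.
#' @param n_offspring offspring per couple.
#' @param cycle origin cycle recorded on the offspring.
#' @return A `gs_pop` of `nrow(couples) * n_offspring` F1 individuals.
#' @export
cross <- function(pop, couples, n_offspring = 20, cycle = 1L) {
  stopifnot(all(c("p1", "p2") %in% names(couples)), n_offspring >= 1)
  if (any(couples$p1 == couples$p2))
    stop("a couple must consist of two distinct parents", call. = FALSE)
  i1 <- rep(match(couples$p1, pop$id), each = n_offspring)
  i2 <- rep(match(couples$p2, pop$id), each = n_offspring)
  if (anyNA(i1) || anyNA(i2)) stop("unknown parent id", call. = FALSE)
  h1 <- make_gametes(pop, i1)
  h2 <- make_gametes(pop, i2)
  new_population(sprintf("C%d_%05d", cycle, seq_along(i1)), h1, h2, pop$map,
                 origin_cycle = cycle)
}

#' Advance a population by single-seed descent
#'
#' Each plant is selfed and exactly one random offspring per lineage is kept
#' per generation, so the population size is unchanged. Two generations turn
#' an F1 set into F3 lines.
#'
#' @param pop a `gs_pop`.
#' @param generations number of selfing generations (>= 1).
#' @return A `gs_pop` of the same size with the same ids (lineage labels).
#' @export
single_seed_descent <- function(pop, generations = 2) {
  stopifnot(generations >= 1)
  idx <- seq_len(n_ind(pop))
  for (g in seq_len(generations)) {
    h1 <- make_gametes(pop, idx)
    h2 <- make_gametes(pop, idx)
    pop <- new_population(pop$id, h1, h2, pop$map, pop$panel, pop$origin_cycle)
  }
  pop
}
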