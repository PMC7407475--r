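#' Population of phased inbred-line genotypes
#'
#' A `gs_pop` holds a set of individuals as two phased 0/1 haplotype matrices
#' over the loci of a shared genetic map. Inbred founders are fully homozygous
#' (`h1 == h2`); simulated offspring may be heterozygous. Genotype codes used
#' throughout the package are `h1 + h2 - 1`, i.e. -1/0/+1 for the first-allele
#' homozygote, the heterozygote and the second-allele homozygote.
#'
#' @param id character vector of unique individual ids.
#' @param h1,h2 integer 0/1 matrices, individuals in rows, loci in columns.
#' @param map marker map tibble with columns `locus_id`, `chromosome`,
#'   `position_cM`; loci in column order of `h1`/`h2`.
#' @param panel optional panel label (e.g. to distinguish founder panels).
#' @param origin_cycle integer breeding cycle the individuals were created in.
#' @return An object of class `gs_pop`.
#' @export
new_population <- function(id, h1, h2, map, panel = NA_character_,
                           origin_cycle = 0L) {
  id <- as.character(id)
  h1 <- as.matrix(h1); h2 <- as.matrix(h2)
  storage.mode(h1) <- "integer"; storage.mode(h2) <- "integer"
  if (nrow(h1) != length(id) || nrow(h2) != length(id))
    stop("haplotype row count does not match number of ids", call. = FALSE)
  if (ncol(h1) != nrow(map) || ncol(h2) != nrow(map))
    stop("haplotype locus count does not match the marker map", call. = FALSE)
  if (anyDuplicated(id))
    stop("duplicate individual ids", call. = FALSE)
  if (!all(h1 %in% c(0L, 1L)) || !all(h2 %in% c(0L, 1L)))
    stop("haplotype entries must be 0/1", call. = FALSE)
  validate_map(map)
  structure(
    list(id = id, h1 = h1, h2 = h2, map = map, panel = panel,
         origin_cycle = rep_len(as.integer(origin_cycle), length(id))),
    class = "gs_pop")
}

validate_map <- function(map) {
  stopifnot(all(c("locus_id", "chromosome", "position_cM") %in% names(map)))
  if (anyDuplicated(map$locus_id))
    stop("duplicate locus ids in marker map", call. = FALSE)
  if (any(map$position_cM < 0))
    stop("negative cM positions in marker map", call. = FALSE)
  # chromosome blocks must be contiguous and positions sorted within a block
  r <- rle(as.integer(map$chromosome))
  if (anyDuplicated(r$values))
    stop("marker map chromosomes must form contiguous blocks", call. = FALSE)
  for (ch in split(map$position_cM, map$chromosome))
    if (is.unsorted(ch))
      stop("cM positions must be non-decreasing within each chromosome",
           call. = FALSE)
  invisible(map)
}

#' Number of individuals / loci in a population
#' @param pop a `gs_pop`.
#' @return An integer count.
#' @export
n_ind <- function(pop) length(pop$id)

#' @rdname n_ind
#' @export
n_loci <- function(pop) ncol(pop$h1)

#' Genotype codes of a population
#'
#' @param pop a `gs_pop`.
#' @param loci optional integer column indices to extract.
#' @return Integer matrix of -1/0/+1 codes, individuals in rows (rownames =
#'   ids), loci in columns (colnames = locus ids).
#' @export
geno_codes <- function(pop, loci = NULL) {
  z <- pop$h1 + pop$h2 - 1L
  dimnames(z) <- list(pop$id, pop$map$locus_id)
  if (!is.null(loci)) z <- z[, loci, drop = FALSE]
  z
}

#' Subset a population by individual
#' @param pop a `gs_pop`.
#' @param i integer or character index of individuals to keep.
#' @return A `gs_pop` with the selected individuals.
#' @export
subset_pop <- function(pop, i) {
  if (is.character(i)) i <- match(i, pop$id)
  if (anyNA(i)) stop("unknown individual id", call. = FALSE)
  new_population(pop$id[i], pop$h1[i, , drop = FALSE], pop$h2[i, , drop = FALSE],
                 pop$map, pop$panel, pop$origin_cycle[i])
}

#' Combine two populations sharing a marker map
#' @param a,b `gs_pop` objects on identical maps.
#' @return A `gs_pop` containing the individuals of both.
#' @export
bind_pops <- function(a, b) {
  if (!identical(a$map$locus_id, b$map$locus_id))
    stop("populations are on different marker maps", call. = FALSE)
  new_population(c(a$id, b$id), rbind(a$h1, b$h1), rbind(a$h2, b$h2), a$map,
                 NA_character_, c(a$origin_cycle, b$origin_cycle))
}

#' @export
print.gs_pop <- function(x, ...) {
  cat(sprintf("<gs_pop> %d individuals x %d loci on %d chromosome(s)%s\n",
              n_ind(x), n_loci(x), length(unique(x$map$chromosome)),
              if (!is.na(x$panel)) paste0(" [panel ", x$panel, "]") else ""))
  invisible(x)
}

# chromosome block boundaries (1-based first/last column) in map order
chrom_blocks <- function(map) {
  r <- rle(as.integer(map$chromosome))
  last <- cumsum(r$lengths)
  list(first = c(1L, head(last, -1L) + 1L), last = last,
       chromosome = r$values)
}
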