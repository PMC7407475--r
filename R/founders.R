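#' Read a founder panel from a genotype matrix and marker map
#'
#' Founders are fully inbred lines, so the genotype file may only contain the
#' homozygote codes -1 and +1; a 0 (heterozygote) entry is rejected. The
#' canonical dialect is a tab-separated matrix with a header row of locus ids,
#' rows = individuals, first column = individual id. The map file is a TSV
#' with columns `locus_id`, `chromosome`, `position_cM` and must cover exactly
#' the genotype columns; genotype columns are reordered to map order.
#'
#' @param genotype_file path to the TSV genotype matrix.
#' @param map_file path to the TSV marker map.
#' @param panel optional panel label.
#' @return A `gs_pop` of fully homozygous individuals.
#' @export
read_founders <- function(genotype_file, map_file, panel = NA_character_) {
  map <- read_marker_map(map_file)
  gt <- readr::read_tsv(genotype_file, col_types = readr::cols(
    .default = readr::col_integer(), id = readr::col_character()))
  if (names(gt)[1] != "id") names(gt)[1] <- "id"
  ids <- gt$id
  z <- as.matrix(gt[, -1, drop = FALSE])
  if (anyDuplicated(ids)) stop("duplicate individual ids", call. = FALSE)
  if (!setequal(colnames(z), map$locus_id) || ncol(z) != nrow(map))
    stop("genotype columns and marker map do not match", call. = FALSE)
  z <- z[, map$locus_id, drop = FALSE]
  if (any(z == 0L)) stop("heterozygous founder: founders must be inbred lines",
                         call. = FALSE)
  if (!all(z %in% c(-1L, 1L))) stop("unknown genotype code", call. = FALSE)
  h <- (z + 1L) %/% 2L
  new_population(ids, h, h, map, panel = panel, origin_cycle = 0L)
}

#' Read a marker map TSV
#' @param map_file path to a TSV with columns `locus_id`, `chromosome`,
#'   `position_cM`.
#' @return A validated marker-map tibble.
#' @export
read_marker_map <- function(map_file) {
  map <- readr::read_tsv(map_file, col_types = readr::cols(
    locus_id = readr::col_character(), chromosome = readr::col_integer(),
    position_cM = readr::col_double()))
  validate_map(map)
  map
}

#' Write a founder panel in the canonical TSV dialect
#'
#' Inverse of [read_founders()]: writes the -1/+1 genotype matrix and the
#' marker map so that a read/write round trip reproduces the files exactly.
#'
#' @param pop a fully homozygous `gs_pop`.
#' @param genotype_file,map_file output paths.
#' @return `pop`, invisibly.
#' @export
write_founders <- function(pop, genotype_file, map_file = NULL) {
  z <- geno_codes(pop)
  if (any(z == 0L)) stop("population contains heterozygotes; not a founder panel",
                         call. = FALSE)
  df <- tibble::as_tibble(z)
  df <- dplyr::bind_cols(tibble::tibble(id = pop$id), df)
  readr::write_tsv(df, genotype_file)
  if (!is.null(map_file)) readr::write_tsv(pop$map, map_file)
  invisible(pop)
}

#' Read founders from a VCF file
#'
#' Maps REF/REF homozygotes to -1 and ALT/ALT homozygotes to +1; heterozygous
#' or missing calls are rejected because founders must be inbred lines. Marker
#' ids in the VCF must match the supplied genetic map, which provides the cM
#' coordinates the VCF lacks.
#'
#' @param vcf_file path to a VCF (v4.x) file.
#' @param map_file path to the TSV marker map.
#' @param panel optional panel label.
#' @return A `gs_pop` of fully homozygous individuals.
#' @export
read_founders_vcf <- function(vcf_file, map_file, panel = NA_character_) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("the vcfR package is required for VCF import", call. = FALSE)
  map <- read_marker_map(map_file)
  v <- vcfR::read.vcfR(vcf_file, verbose = FALSE)
  gt <- vcfR::extract.gt(v)
  locus <- rownames(gt)
  if (!setequal(locus, map$locus_id) || length(locus) != nrow(map))
    stop("VCF loci and marker map do not match", call. = FALSE)
  code <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt))
  norm <- gsub("\\|", "/", gt)
  code[norm == "0/0"] <- -1L
  code[norm == "1/1"] <- 1L
  if (anyNA(code))
    stop("heterozygous or missing founder genotypes in VCF; founders must be inbred lines",
         call. = FALSE)
  z <- t(code)
  colnames(z) <- locus
  z <- z[, map$locus_id, drop = FALSE]
  h <- (z + 1L) %/% 2L
  new_population(colnames(gt), h, h, map, panel = panel, origin_cycle = 0L)
}

#' Generate two synthetic inbred founder panels
#'
#' Stand-in for a pair of real breeding panels: per-locus second-allele
#' frequencies are drawn once from the given spectrum and shared by both
#' panels, then each fully homozygous line draws its allele at each locus
#' independently with that frequency. Loci are assigned to chromosomes in
#' contiguous blocks with uniformly spaced cM positions spanning
#' `[0, chrom_length_cM]`. The default shape (7 chromosomes x 150 cM,
#' allele frequencies uniform on [0.05, 0.95]) emulates a barley SNP panel.
#'
#' @param n_lines_per_panel lines per panel (>= 2).
#' @param n_loci total loci across all chromosomes (>= `n_chrom`).
#' @param n_chrom number of chromosomes.
#' @param chrom_length_cM genetic length of each chromosome.
#' @param allele_freq_spectrum either a numeric length-2 range for a uniform
#'   spectrum or a function `f(n)` returning `n` frequencies in (0, 1).
#' @param seed optional integer seed; when supplied the result is a pure
#'   function of the arguments.
#' @return A list of two `gs_pop` panels (`panel_a`, `panel_b`) on a shared map.
#' @export
synth_founders <- function(n_lines_per_panel = 380, n_loci = 1590,
                           n_chrom = 7, chrom_length_cM = 150,
                           allele_freq_spectrum = c(0.05, 0.95),
                           seed = NULL) {
  stopifnot(n_lines_per_panel >= 2, n_loci >= n_chrom, n_chrom >= 1)
  if (!is.null(seed)) set.seed(seed)
  per <- rep(n_loci %/% n_chrom, n_chrom)
  extra <- n_loci %% n_chrom
  if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
  map <- tibble::tibble(
    locus_id = sprintf("M%04d", seq_len(n_loci)),
    chromosome = rep(seq_len(n_chrom), per),
    position_cM = unlist(lapply(per, function(k)
      if (k == 1) 0 else seq(0, chrom_length_cM, length.out = k))))

  p <- if (is.function(allele_freq_spectrum)) allele_freq_spectrum(n_loci)
       else runif(n_loci, allele_freq_spectrum[1], allele_freq_spectrum[2])
  stopifnot(length(p) == n_loci, all(p >= 0), all(p <= 1))

  draw_panel <- function(label) {
    h <- matrix(rbinom(n_lines_per_panel * n_loci, 1L,
                       rep(p, each = n_lines_per_panel)),
                nrow = n_lines_per_panel)
    if (all(apply(h, 2, function(col) length(unique(col)) == 1)))
      warning("degenerate allele-frequency spectrum: all loci monomorphic",
              call. = FALSE)
    new_population(sprintf("%s%04d", label, seq_len(n_lines_per_panel)),
                   h, h, map, panel = label, origin_cycle = 0L)
  }
  list(panel_a = draw_panel("A"), panel_b = draw_panel("B"))
}
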