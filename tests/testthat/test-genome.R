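test_that("geometric effect series follows a = (L-1)/(L+1)", {
  map <- make_map(1590)
  q3 <- sample_qtl(map, L = 3, seed = 1)
  expect_equal(q3$a, 0.5)
  expect_equal(q3$effects, c(0.5, 0.25, 0.125))

  q1 <- sample_qtl(map, L = 1, seed = 1)
  expect_equal(q1$a, 0)
  expect_equal(q1$effects, 0)

  q100 <- sample_qtl(map, L = 100, seed = 1)
  a <- 99 / 101
  expect_equal(sum(q100$effects), a * (1 - a^100) / (1 - a)) # geometric sum
  expect_true(all(diff(q100$effects) < 0))
})

test_that("QTL and prediction markers partition the loci", {
  map <- make_map(1590, n_chrom = 7, len = 150)
  q <- sample_qtl(map, L = 100, seed = 5)
  expect_length(q$qtl_idx, 100)
  expect_length(q$marker_idx, 1490)
  expect_length(intersect(q$qtl_idx, q$marker_idx), 0)
  expect_setequal(c(q$qtl_idx, q$marker_idx), seq_len(1590))
  expect_error(sample_qtl(make_map(50), L = 50), "smaller")
  # deterministic given seed
  expect_identical(sample_qtl(map, L = 100, seed = 5)$qtl_idx, q$qtl_idx)
})

test_that("genetic values score favorable/het/unfavorable as +a^k/0/-a^k", {
  # L = 2: a = 1/3, effects (1/3, 1/9)
  q <- make_qtl(c(1, 2), n_loci = 3, effects = c(1 / 3, 1 / 9),
                favorable = c(1, 1), a = 1 / 3)
  pop <- make_pop(rbind(c(1, -1, 1),   # favorable at QTL1, unfavorable at QTL2
                        c(1, 1, -1),   # all favorable
                        c(0, 0, 0)))   # all heterozygous
  gv <- genetic_values(pop, q)
  expect_equal(gv$gv_raw, c(2 / 9, 4 / 9, 0))
  expect_equal(gv$gv_norm, c(0.5, 1, 0))

  # orientation flips with the favorable-allele designation
  qf <- make_qtl(c(1, 2), n_loci = 3, effects = c(1 / 3, 1 / 9),
                 favorable = c(-1, 1))
  expect_equal(genetic_values(pop, qf)$gv_raw[1], -1 / 3 - 1 / 9)

  # bounded in [-1, 1] over random individuals
  rnd <- make_pop(rand_codes(50, 3))
  expect_true(all(abs(genetic_values(rnd, q)$gv_norm) <= 1))
})

test_that("meiosis of a homozygote returns the parental haplotype", {
  pop <- make_pop(matrix(c(-1, 1, 1, -1, 1, -1), nrow = 1),
                  map = make_map(6, n_chrom = 2, len = 120))
  for (i in 1:5) expect_identical(meiosis(pop, 1), pop$h1[1, ])
})

test_that("zero-length chromosomes transmit an unrecombined haplotype", {
  map <- tibble::tibble(locus_id = c("A", "B"), chromosome = c(1L, 1L),
                        position_cM = c(0, 0))
  pop <- new_population("x", matrix(c(1L, 1L), 1), matrix(c(0L, 0L), 1), map)
  g <- replicate(200, meiosis(pop, 1))
  expect_true(all(g[1, ] == g[2, ])) # never split the two co-located loci
  expect_true(any(g[1, ] == 1) && any(g[1, ] == 0)) # both haplotypes occur
})

test_that("offspring alleles always come from the parents (no mutation)", {
  set.seed(2)
  pans <- synth_founders(10, 60, n_chrom = 3, seed = 12)
  pop <- pans$panel_a
  cpl <- tibble::tibble(p1 = pop$id[1:3], p2 = pop$id[4:6])
  off <- cross(pop, cpl, n_offspring = 4)
  for (r in seq_len(n_ind(off))) {
    i1 <- match(cpl$p1[ceiling(r / 4)], pop$id)
    i2 <- match(cpl$p2[ceiling(r / 4)], pop$id)
    expect_true(all(off$h1[r, ] %in% c(pop$h1[i1, ], pop$h2[i1, ])))
    ok1 <- off$h1[r, ] == pop$h1[i1, ] | off$h1[r, ] == pop$h2[i1, ]
    ok2 <- off$h2[r, ] == pop$h1[i2, ] | off$h2[r, ] == pop$h2[i2, ]
    expect_true(all(ok1) && all(ok2))
  }
})

test_that("crossing structure: couples x offspring, Mendelian certainties", {
  set.seed(3)
  pans <- synth_founders(60, 40, n_chrom = 2, seed = 8)
  pop <- pans$panel_a
  cpl <- tibble::tibble(p1 = pop$id[1:30], p2 = pop$id[31:60])
  off <- cross(pop, cpl, n_offspring = 20)
  expect_equal(n_ind(off), 30 * 20)

  # two identical homozygous parents -> offspring identical to them
  clone <- make_pop(rbind(c(1, -1, 1, -1), c(1, -1, 1, -1)))
  kid <- cross(clone, tibble::tibble(p1 = "I001", p2 = "I002"), 5)
  expect_true(all(geno_codes(kid) == rep(c(1, -1, 1, -1), each = 5)))

  # opposite homozygotes -> every F1 heterozygous everywhere
  opp <- make_pop(rbind(c(1, 1, 1), c(-1, -1, -1)))
  f1 <- cross(opp, tibble::tibble(p1 = "I001", p2 = "I002"), 8)
  expect_true(all(geno_codes(f1) == 0))

  expect_error(cross(clone, tibble::tibble(p1 = "I001", p2 = "I001"), 2),
               "distinct")
})

test_that("single-seed descent keeps size and fixes homozygotes", {
  set.seed(4)
  pans <- synth_founders(15, 30, n_chrom = 2, seed = 21)
  out <- single_seed_descent(pans$panel_a, generations = 2)
  expect_equal(n_ind(out), 15)
  expect_identical(out$h1, pans$panel_a$h1) # homozygous input is a fixed point
  expect_identical(out$h2, pans$panel_a$h2)
})

test_that("selfing halves heterozygosity per generation", {
  set.seed(5)
  # 1500 independent single-het lineages on 4 one-locus chromosomes
  map <- make_map(4, n_chrom = 4, len = 80)
  pop <- new_population(sprintf("H%04d", 1:1500),
                        matrix(0L, 1500, 4), matrix(1L, 1500, 4), map)
  g1 <- single_seed_descent(pop, generations = 1)
  g2 <- single_seed_descent(g1, generations = 1)
  het1 <- mean(geno_codes(g1) == 0)
  het2 <- mean(geno_codes(g2) == 0)
  se1 <- sqrt(0.5 * 0.5 / 6000); se2 <- sqrt(0.25 * 0.75 / 6000)
  expect_lt(abs(het1 - 0.5), 4 * se1)
  expect_lt(abs(het2 - 0.25), 4 * se2)
})
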