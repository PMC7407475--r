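# reference greedy scoping selection with naive score recomputation
scoping_brute <- function(Z, gebv, n_couples) {
  n <- nrow(Z); k <- ncol(Z)
  ord <- order(gebv, decreasing = TRUE)
  Z <- Z[ord, , drop = FALSE]
  avail <- rep(TRUE, n); p <- rep(1, k)
  sel <- integer(0)
  p1 <- integer(n_couples); p2 <- integer(n_couples)
  for (cp in seq_len(n_couples)) {
    i1 <- which(avail)[1]; avail[i1] <- FALSE; sel <- c(sel, i1)
    cands <- which(avail)
    sc <- sapply(cands, function(cc)
      fscore_brute(Z[c(sel, cc), , drop = FALSE], p))
    i2 <- cands[which.max(sc)]
    avail[i2] <- FALSE; sel <- c(sel, i2)
    p1[cp] <- i1; p2[cp] <- i2
    zs <- Z[sel, , drop = FALSE]
    both <- apply(zs, 2, function(col) any(col <= 0) && any(col >= 0))
    p <- as.numeric(!both)
    if (all(p == 0)) p <- rep(1, k)
  }
  list(p1 = ord[p1], p2 = ord[p2]) # indices into original order
}

test_that("truncation selection matches a full-sort oracle", {
  set.seed(30)
  gebvs <- tibble::tibble(id = sprintf("x%04d", 1:1000), gebv = rnorm(1000))
  sel <- truncation_select(gebvs, 100)
  oracle <- gebvs$id[order(gebvs$gebv, decreasing = TRUE)][1:100]
  expect_identical(sel, oracle)
  expect_identical(truncation_select(gebvs, 1000),
                   gebvs$id[order(gebvs$gebv, decreasing = TRUE)])
  expect_error(truncation_select(gebvs, 1001), "more individuals")
  # stable tie-breaking by insertion order
  tied <- tibble::tibble(id = c("a", "b", "c"), gebv = c(1, 2, 1))
  expect_identical(truncation_select(tied, 2), c("b", "a"))
})

test_that("random mating is a uniform perfect matching", {
  set.seed(31)
  ids <- sprintf("p%02d", 1:100)
  m <- random_mating(ids)
  expect_equal(nrow(m), 50)
  expect_setequal(c(m$p1, m$p2), ids)
  expect_error(random_mating(ids[1:3]), "even")

  # with 4 parents there are 3 matchings; each should occur ~1/3 of the time
  key <- replicate(6000, {
    mm <- random_mating(c("a", "b", "c", "d"))
    pair <- vapply(seq_len(2), function(i)
      paste(sort(c(mm$p1[i], mm$p2[i])), collapse = ""), "")
    paste(sort(pair), collapse = "|")
  })
  freq <- table(key) / 6000
  expect_length(freq, 3)
  expect_true(all(abs(freq - 1 / 3) < 4 * sqrt((1 / 3) * (2 / 3) / 6000)))
})

test_that("fscore equals the masked sum of sample variances", {
  expect_equal(fscore(rbind(1, -1), 1), 2)
  expect_equal(fscore(rbind(c(1, 0, 1), c(-1, 0, 1)), c(1, 1, 0)), 2)
  expect_equal(fscore(matrix(c(1, 1, 1), 3, 1), 1), 0) # identical parents
  expect_equal(fscore(matrix(1, 1, 2), c(1, 1)), 0)    # single row -> 0
  set.seed(32)
  for (i in 1:25) {
    Z <- rand_codes(sample(2:10, 1), sample(1:20, 1))
    p <- sample(0:1, ncol(Z), replace = TRUE)
    expect_equal(fscore(Z, p), fscore_brute(Z, p), tolerance = 1e-12)
  }
})

test_that("scoping selection matches the exhaustive greedy oracle", {
  set.seed(33)
  for (i in 1:20) {
    n_cand <- 8; k <- 5; n_couples <- 3
    codes <- rand_codes(n_cand, k, p_het = 0.3)
    pop <- make_pop(codes, map = make_map(k))
    gebv <- rnorm(n_cand)
    gebvs <- tibble::tibble(id = pop$id, gebv = gebv)
    got <- scoping_select(gebvs, pop, q = NULL, SR = 1, n_couples = n_couples)
    want <- scoping_brute(codes, gebv, n_couples)
    expect_identical(got$p1, pop$id[want$p1])
    expect_identical(got$p2, pop$id[want$p2])
  }
})

test_that("scoping at the boundary SR reduces to truncation selection", {
  set.seed(34)
  pop <- make_pop(rand_codes(100, 12), map = make_map(12))
  gebvs <- tibble::tibble(id = pop$id, gebv = rnorm(100))
  # SR covering exactly 2 * n_couples candidates
  got <- scoping_select(gebvs, pop, q = NULL, SR = 0.2, n_couples = 10)
  expect_setequal(c(got$p1, got$p2), truncation_select(gebvs, 20))
  expect_length(unique(c(got$p1, got$p2)), 20)
  expect_error(scoping_select(gebvs, pop, q = NULL, SR = 0.1, n_couples = 10),
               "pre-selection")
})

test_that("scoping degenerates gracefully on clone populations", {
  set.seed(35)
  pop <- make_pop(matrix(rep(c(1, -1, 1, 1), each = 10), nrow = 10),
                  map = make_map(4))
  gebvs <- tibble::tibble(id = pop$id, gebv = 10:1)
  got <- scoping_select(gebvs, pop, q = NULL, SR = 1, n_couples = 3)
  # all candidates identical: P2 falls back to the tie-break (next-highest GEBV)
  expect_identical(got$p1, pop$id[c(1, 3, 5)])
  expect_identical(got$p2, pop$id[c(2, 4, 6)])
})

test_that("VanRaden G matches hand computations and the brute-force oracle", {
  # two opposite inbreds over 2 markers with P = (0.5, 0.5)
  Z <- rbind(c(1, 1), c(-1, -1))
  G <- vanraden_G(Z)$G
  expect_equal(unname(G), rbind(c(2, -2), c(-2, 2)))
  # fully inbred line at P = 0.5 markers: diagonal 2, inbreeding F = 1
  expect_equal(diag(G), c(2, 2), ignore_attr = TRUE)

  expect_error(vanraden_G(matrix(1, 4, 3)), "monomorphic")

  set.seed(36)
  for (i in 1:25) {
    Zi <- rand_codes(sample(2:10, 1), sample(2:20, 1))
    if (all(apply(Zi, 2, function(x) length(unique(x))) == 1)) next
    expect_equal(vanraden_G(Zi)$G, vanraden_brute(Zi), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("population merit is mean value minus weighted relationship", {
  expect_equal(population_merit(1.0, 20, 0.02), 0.6)
  expect_equal(population_merit(0.3, 0, 5), 0.3)
  expect_equal(population_merit(0.3, 100, 0), 0.3)
})

test_that("population-merit selection reaches a swap-optimal parental set", {
  set.seed(37)
  # c = 0 reduces to truncation selection
  pop <- make_pop(rand_codes(30, 8), map = make_map(8))
  gebvs <- tibble::tibble(id = pop$id, gebv = rnorm(30))
  got0 <- pm_select(gebvs, pop, q = NULL, c = 0, n = 10)
  expect_setequal(attr(got0, "selected"), truncation_select(gebvs, 10))

  # local optimality against exhaustive single-swap neighbors
  for (i in 1:5) {
    pop <- make_pop(rand_codes(8, 6, p_het = 0.3), map = make_map(6))
    gebvs <- tibble::tibble(id = pop$id, gebv = rnorm(8))
    got <- pm_select(gebvs, pop, q = NULL, c = 2, n = 4)
    sel <- attr(got, "selected")
    G <- vanraden_G(geno_codes(pop))$G
    merit_of <- function(ids) {
      ix <- match(ids, pop$id)
      merit_brute(gebvs$gebv[ix], G[ix, ix], c = 2)
    }
    base <- merit_of(sel)
    for (r in sel) for (cnd in setdiff(pop$id, sel))
      expect_lte(merit_of(c(setdiff(sel, r), cnd)), base + 1e-10)
  }
})

test_that("a harsh relationship penalty keeps clones apart", {
  set.seed(38)
  z <- rand_codes(10, 12)
  z[2, ] <- z[1, ]                      # two clones with the top GEBVs
  pop <- make_pop(z, map = make_map(12))
  gebvs <- tibble::tibble(id = pop$id, gebv = c(10, 9.9, rnorm(8)))
  got <- pm_select(gebvs, pop, q = NULL, c = 1e4, n = 4)
  sel <- attr(got, "selected")
  expect_lt(sum(sel %in% pop$id[1:2]), 2)
})

test_that("MVT criterion matches hand computations and brute force", {
  expect_equal(mvt_criterion(rbind(c(2, -2), c(-2, 2))), 6)
  expect_equal(mvt_criterion(rbind(c(2, 2), c(2, 2))), -2)
  expect_error(mvt_criterion(matrix(2, 1, 1)), "two parents")
  set.seed(39)
  for (i in 1:25) {
    Zi <- rand_codes(sample(2:10, 1), 15)
    G <- vanraden_G(Zi)$G
    expect_equal(mvt_criterion(G), mvt_brute(G), tolerance = 1e-12)
  }
})

test_that("MVT selection fixes P1 and improves P2 to swap optimality", {
  set.seed(40)
  pop <- make_pop(rand_codes(20, 10, p_het = 0.3), map = make_map(10))
  gebvs <- tibble::tibble(id = pop$id, gebv = rnorm(20))

  # pre_n = n: no pool, output is plain truncation with pairing
  got <- mvt_select(gebvs, pop, q = NULL, pre_n = 4, n = 4)
  expect_setequal(attr(got, "selected"), truncation_select(gebvs, 4))

  for (i in 1:5) {
    pop <- make_pop(rand_codes(12, 8, p_het = 0.3), map = make_map(8))
    Zall <- geno_codes(pop)
    gebvs <- tibble::tibble(id = pop$id, gebv = rnorm(12))
    got <- mvt_select(gebvs, pop, q = NULL, pre_n = 8, n = 4)
    sel <- attr(got, "selected")
    pre <- truncation_select(gebvs, 8)
    expect_identical(sel[1:2], truncation_select(gebvs, 2)) # P1 fixed
    Gp <- vanraden_G(Zall[match(pre, pop$id), , drop = FALSE],
                     freq_source = Zall)$G
    crit_of <- function(ids) mvt_brute(Gp[match(ids, pre), match(ids, pre)])
    base <- crit_of(sel)
    p2 <- sel[3:4]
    for (r in p2) for (cnd in setdiff(pre, sel))
      expect_lte(crit_of(c(sel[1:2], setdiff(p2, r), cnd)), base + 1e-10)
  }
})

test_that("every strategy returns disjoint couples covering 2n parents", {
  set.seed(41)
  pop <- make_pop(rand_codes(60, 15, p_het = 0.2), map = make_map(15))
  gebvs <- tibble::tibble(id = pop$id, gebv = rnorm(60))
  runs <- list(
    random_mating(truncation_select(gebvs, 12)),
    scoping_select(gebvs, pop, q = NULL, SR = 0.5, n_couples = 6),
    pm_select(gebvs, pop, q = NULL, c = 5, n = 12),
    mvt_select(gebvs, pop, q = NULL, pre_n = 20, n = 12))
  for (cpl in runs) {
    expect_equal(nrow(cpl), 6)
    expect_length(unique(c(cpl$p1, cpl$p2)), 12)
    expect_true(all(cpl$p1 != cpl$p2))
  }
})
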