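test_that("Haldane map function", {
  expect_equal(haldane_theta(0), 0)
  expect_equal(haldane_theta(50), 0.5 * (1 - exp(-1)), tolerance = 1e-12)
  expect_equal(round(haldane_theta(50), 5), 0.31606)
  expect_lt(haldane_theta(500), 0.5)
  expect_lte(haldane_theta(1e6), 0.5)  # reaches 0.5 only at fp precision
  d <- seq(0, 300, by = 7)
  expect_true(all(diff(haldane_theta(d)) > 0))
  expect_error(haldane_theta(-1), "negative")
})

test_that("expected kinship matrices", {
  fam <- list(family_id = "F1", parents = c("P1", "P2"),
              sibs = c("S1", "S2"))
  K <- expected_kinship(fam)
  expect_equal(K["S1", "S2"], 0.5)
  expect_equal(K["P1", "S1"], 0.5)
  expect_equal(K["P1", "P2"], 0)
  expect_equal(diag(K), setNames(rep(1, 4), c("P1", "P2", "S1", "S2")))
})

test_that("fully informative and exclusion cases", {
  # parents 1/2 x 3/4; sibs 1/3, 1/3 -> IBD 2 with certainty
  a1 <- matrix(c(1L, 3L, 1L, 1L), 4, 1)
  a2 <- matrix(c(2L, 4L, 3L, 3L), 4, 1)
  co <- make_family_cohort(2, 10, 4, a1, a2)
  r <- multipoint_ibd(nuclear_families(co)[[1]], co, grid_cM = 10)
  expect_equal(r$p2[1, 1], 1, tolerance = 1e-12)
  expect_equal(r$pihat[1, 1], 1, tolerance = 1e-12)

  # sibs 1/3, 2/4 -> IBD 0
  a1 <- matrix(c(1L, 3L, 1L, 2L), 4, 1)
  a2 <- matrix(c(2L, 4L, 3L, 4L), 4, 1)
  co <- make_family_cohort(2, 10, 4, a1, a2)
  r <- multipoint_ibd(nuclear_families(co)[[1]], co, grid_cM = 10)
  expect_equal(r$p0[1, 1], 1, tolerance = 1e-12)
  expect_equal(r$pihat[1, 1], 0, tolerance = 1e-12)

  # nothing genotyped -> prior (1/4, 1/2, 1/4)
  a0 <- matrix(0L, 4, 1)
  co <- make_family_cohort(2, 10, 4, a0, a0)
  r <- multipoint_ibd(nuclear_families(co)[[1]], co, grid_cM = 10,
                      freqs = list(rep(0.25, 4)))
  expect_equal(c(r$p0[1, 1], r$p1[1, 1], r$p2[1, 1]), c(0.25, 0.5, 0.25),
               tolerance = 1e-12)

  # Mendelian-inconsistent marker is dropped with a warning
  a1 <- matrix(c(1L, 1L, 2L, 1L), 4, 1)  # parents 1/1 x 1/1, sib1 2/2
  a2 <- matrix(c(1L, 1L, 2L, 1L), 4, 1)
  co <- make_family_cohort(2, 10, 2, a1, a2)
  expect_warning(r <- multipoint_ibd(nuclear_families(co)[[1]], co,
                                     grid_cM = 10,
                                     freqs = list(c(0.5, 0.5))),
                 "Mendelian")
  expect_true(r$excluded[1])
  expect_equal(r$p1[1, 1], 0.5, tolerance = 1e-12)
})

test_that("HMM equals the exhaustive enumeration oracle", {
  set.seed(99)
  for (rep in 1:8) {
    s <- sample(2:3, 1)
    m <- sample(1:3, 1)
    nal <- sample(2:4, 1)
    freqs <- lapply(seq_len(m), function(k) {
      f <- runif(nal) + 0.2; f / sum(f)
    })
    pos <- sort(runif(m, 0, 40))
    fa <- matrix(sample(seq_len(nal), 2 * m, TRUE), m, 2)
    mo <- matrix(sample(seq_len(nal), 2 * m, TRUE), m, 2)
    sibs_a <- sibs_b <- matrix(NA_integer_, s, m)
    for (k in seq_len(m)) for (i in seq_len(s)) {
      sibs_a[i, k] <- fa[k, sample(1:2, 1)]
      sibs_b[i, k] <- mo[k, sample(1:2, 1)]
    }
    hide_fa <- rep %% 2 == 0
    hide_sib <- rep %% 3 == 0
    fa_in <- if (hide_fa) matrix(NA_integer_, m, 2) else fa
    if (hide_sib) sibs_a[1, 1] <- sibs_b[1, 1] <- NA
    # enumeration is 4^s per position: extra off-marker query points are
    # affordable only for 2-sib families
    grid <- if (s == 2)
      sort(unique(c(pos[1], mean(range(pos)), max(pos) + 5)))
    else pos
    orc <- oracle_ibd(s, sibs_a, sibs_b, fa_in, mo, freqs, pos, grid)
    a1 <- rbind(if (hide_fa) rep(0L, m) else fa[, 1], mo[, 1],
                matrix(ifelse(is.na(sibs_a), 0L, sibs_a), s, m))
    a2 <- rbind(if (hide_fa) rep(0L, m) else fa[, 2], mo[, 2],
                matrix(ifelse(is.na(sibs_b), 0L, sibs_b), s, m))
    co <- make_family_cohort(s, pos, rep(nal, m), a1, a2)
    r <- multipoint_ibd(nuclear_families(co)[[1]], co, grid_cM = grid,
                        freqs = freqs)
    hmm <- rbind(r$p0[1, ], r$p1[1, ], r$p2[1, ])
    expect_lt(max(abs(hmm - orc)), 1e-9)
  }
})

test_that("single-point consistency: other markers removed", {
  set.seed(7)
  m <- 3; nal <- 3
  freqs <- lapply(1:m, function(k) rep(1 / nal, nal))
  pos <- c(5, 15, 30)
  fa <- matrix(sample(1:nal, 2 * m, TRUE), m, 2)
  mo <- matrix(sample(1:nal, 2 * m, TRUE), m, 2)
  a1 <- rbind(fa[, 1], mo[, 1],
              sapply(1:m, function(k) fa[k, sample(1:2, 1)]),
              sapply(1:m, function(k) fa[k, sample(1:2, 1)]))
  a2 <- rbind(fa[, 2], mo[, 2],
              sapply(1:m, function(k) mo[k, sample(1:2, 1)]),
              sapply(1:m, function(k) mo[k, sample(1:2, 1)]))
  co <- make_family_cohort(2, pos, rep(nal, m), a1, a2)
  # single-marker cohort for marker 2 only
  co1 <- make_family_cohort(2, pos[2], nal,
                            a1[, 2, drop = FALSE], a2[, 2, drop = FALSE])
  r1 <- multipoint_ibd(nuclear_families(co1)[[1]], co1, grid_cM = pos[2],
                       freqs = freqs[2])
  # multipoint run with the other markers' genotypes blanked out
  a1b <- a1; a2b <- a2; a1b[, c(1, 3)] <- 0L; a2b[, c(1, 3)] <- 0L
  cob <- make_family_cohort(2, pos, rep(nal, m), a1b, a2b)
  rb <- multipoint_ibd(nuclear_families(cob)[[1]], cob, grid_cM = pos[2],
                       freqs = freqs)
  expect_equal(rb$p0[1, 1], r1$p0[1, 1], tolerance = 1e-12)
  expect_equal(rb$p2[1, 1], r1$p2[1, 1], tolerance = 1e-12)
})

test_that("fully informative sib pairs: pihat mass at {0, 1/2, 1}", {
  set.seed(11)
  n <- 600
  # parents 1/2 x 3/4 everywhere; sibs drawn by true segregation
  vals <- replicate(n, {
    p <- sample(1:2, 2, TRUE); m <- sample(3:4, 2, TRUE)
    a1 <- matrix(c(1L, 3L, p[1], p[2]), 4, 1)
    a2 <- matrix(c(2L, 4L, m[1], m[2]), 4, 1)
    co <- make_family_cohort(2, 10, 4, a1, a2)
    multipoint_ibd(nuclear_families(co)[[1]], co, grid_cM = 10)$pihat[1, 1]
  })
  expect_true(all(vals %in% c(0, 0.5, 1)))
  expect_equal(mean(vals), 0.5, tolerance = 0.06)
  expect_equal(mean(vals == 0.5), 0.5, tolerance = 0.08)
})

test_that("surface assembly, pihat matrices and serialization", {
  co <- simulate_cohort(partition_world_config(n_families = 25, seed = 5))
  surf <- ibd_surface(co, grid_cM = c(10, 20.5, 140))
  expect_s3_class(surf, "ibd_surface")
  tab <- ibd_surface_table(surf)
  expect_true(all(abs(tab$p0 + tab$p1 + tab$p2 - 1) < 1e-9))
  expect_true(all(tab$pihat >= 0 & tab$pihat <= 1))
  pih <- pihat_matrices(surf, co, 20.5)
  f1 <- names(surf$families)[1]
  expect_true(isSymmetric(pih[[f1]]))
  fam <- nuclear_families(co)[[f1]]
  expect_equal(pih[[f1]][fam$parents[1], fam$sibs[1]], 0.5)
  expect_error(pihat_matrices(surf, co, 33.33), "not on the IBD grid")
})
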