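test_that("EM haplotype frequencies: counting, degeneracy, recovery", {
  # 9 individuals hom 22/22... phase-unambiguous counting world:
  # 9 of AB/AB and 1 of ab/ab (coded as dosage rows)
  g <- rbind(matrix(rep(c(2, 2), 9), ncol = 2, byrow = TRUE),
             c(0, 0))
  em <- em_haplotype_freqs(g)
  f <- setNames(em$freq, em$hap)
  expect_equal(unname(f["22"]), 0.9, tolerance = 1e-9)
  expect_equal(unname(f["11"]), 0.1, tolerance = 1e-9)
  expect_equal(sum(em$freq), 1, tolerance = 1e-9)

  # all double heterozygotes: bimodal likelihood, ambiguity flagged
  g2 <- matrix(1, 20, 2)
  em2 <- em_haplotype_freqs(g2)
  expect_true(attr(em2, "ambiguous"))

  # loglik trajectory is non-decreasing
  set.seed(401)
  g3 <- cbind(rbinom(100, 2, 0.4), rbinom(100, 2, 0.4),
              rbinom(100, 2, 0.2))
  em3 <- em_haplotype_freqs(g3)
  expect_true(all(diff(attr(em3, "trajectory")) > -1e-9))
  expect_error(em_haplotype_freqs(matrix(NA_real_, 5, 2)), "no complete")
})

test_that("simulated 4-SNP frequencies recovered within 0.03 at n=1000", {
  set.seed(402)
  haps <- rbind(c(1L, 1L, 1L, 1L), c(2L, 2L, 1L, 1L),
                c(1L, 1L, 2L, 2L), c(2L, 1L, 2L, 1L))
  hf <- c(0.35, 0.30, 0.25, 0.10)
  idx1 <- sample(4, 1000, TRUE, hf); idx2 <- sample(4, 1000, TRUE, hf)
  g <- haps[idx1, ] + haps[idx2, ] - 2L
  em <- em_haplotype_freqs(g)
  f <- setNames(em$freq, em$hap)
  truth <- setNames(hf, apply(haps, 1, paste, collapse = ""))
  expect_true(all(abs(f[names(truth)] - truth) < 0.03))
  # singleton posterior dosages: rows sum to 2
  D <- em_haplotype_dosages(g, em)
  expect_true(all(abs(rowSums(D) - 2) < 1e-6))
})

test_that("pairwise LD: exact fixture, duplicated and independent SNPs", {
  # homozygous-by-construction sample with haplotype counts
  # AB=40, ab=40, Ab=10, aB=10 (phase-free, so EM is exact counting)
  da <- c(rep(2, 20), rep(0, 20), rep(2, 5), rep(0, 5))
  db <- c(rep(2, 20), rep(0, 20), rep(0, 5), rep(2, 5))
  ld <- pairwise_ld(da, db)
  expect_equal(ld$D, 0.15, tolerance = 1e-9)
  expect_equal(ld$Dprime, 0.6, tolerance = 1e-9)
  expect_equal(ld$r2, 0.36, tolerance = 1e-9)
  expect_true(ld$ci_lo <= 0.6 && 0.6 <= ld$ci_hi)
  # closed form straight from frequencies
  c2 <- ld_from_hap_freqs(c(0.4, 0.1, 0.1, 0.4))
  expect_equal(c(c2$D, c2$Dprime, c2$r2), c(0.15, 0.6, 0.36))

  set.seed(403)
  x <- rbinom(300, 2, 0.4)
  dup <- pairwise_ld(x, x)
  expect_equal(dup$Dprime, 1)
  expect_equal(dup$r2, 1)

  # independence: product haplotype frequencies
  ind <- ld_from_hap_freqs(c(0.42, 0.28, 0.18, 0.12))
  expect_equal(ind$D, 0, tolerance = 1e-12)
  expect_equal(ind$r2, 0, tolerance = 1e-12)
  expect_error(pairwise_ld(rep(0, 50), rbinom(50, 2, 0.5)), "monomorphic")
})

test_that("r2 <= Dprime^2 over random pairs", {
  set.seed(404)
  for (i in 1:20) {
    p <- rgamma(4, 1); p <- p / sum(p)
    ldc <- ld_from_hap_freqs(p)
    expect_lte(ldc$r2, ldc$Dprime^2 + 1e-9)
    expect_true(ldc$Dprime >= 0 && ldc$Dprime <= 1)
  }
})

test_that("Gabriel blocks from constructed LD patterns", {
  set.seed(405)
  # two tight 3-SNP clusters separated by free recombination
  spec <- ld_spec(
    freqs = rep(list(c(0.6, 0.4)), 6),
    cluster_cols = 1:3,
    cluster_haps = rbind(c(1L, 1L, 1L), c(2L, 2L, 2L)),
    cluster_freqs = c(0.6, 0.4),
    proxy = data.frame(col = 5:6, source = 4, flip = 0.01))
  # cols 4-6: second cluster built from col 4 with near-perfect proxies
  pool <- simulate_founder_haplotypes(spec, 1200, seed = 405)
  g <- pool[1:600, ] + pool[601:1200, ] - 2L
  snps <- paste0("s", 1:6)
  colnames(g) <- snps
  ld <- do.call(rbind, lapply(utils::combn(6, 2, simplify = FALSE),
    function(ij) pairwise_ld(g[, ij[1]], g[, ij[2]],
                             names_ab = snps[ij])))
  maf <- setNames(vapply(1:6, function(j) min(mean(g[, j]) / 2,
                                              1 - mean(g[, j]) / 2),
                         numeric(1)), snps)
  blocks <- gabriel_blocks(ld, snps, maf)
  expect_equal(length(blocks), 2)
  expect_setequal(blocks[[1]], c("s1", "s2", "s3"))
  expect_setequal(blocks[[2]], c("s4", "s5", "s6"))
  # uninformative tiny sample: no blocks
  ld_tiny <- do.call(rbind, lapply(utils::combn(3, 2, simplify = FALSE),
    function(ij) pairwise_ld(g[1:8, ij[1]], g[1:8, ij[2]],
                             names_ab = snps[ij])))
  expect_lte(length(gabriel_blocks(ld_tiny, snps[1:3], maf[1:3])), 1)
})

test_that("greedy tag selection with tie-breaks and full capture", {
  r2 <- diag(3)
  r2[1, 2] <- r2[2, 1] <- 0.95
  r2[1, 3] <- r2[3, 1] <- 0.1
  r2[2, 3] <- r2[3, 2] <- 0.1
  dimnames(r2) <- list(c("a", "b", "c"), c("a", "b", "c"))
  tg <- select_tags(r2, 0.8)
  expect_setequal(tg$tags, c("a", "c"))
  expect_setequal(unique(unlist(tg$capture)), c("a", "b", "c"))
  # nothing redundant: every SNP its own tag
  r5 <- diag(5); dimnames(r5) <- list(letters[1:5], letters[1:5])
  expect_equal(sort(select_tags(r5, 0.8)$tags), letters[1:5])
})

test_that("a 21-SNP one-gene region needs few tags and full capture", {
  co <- simulate_cohort(default_paper_config(seed = 406))
  snps <- co$markers$name[co$markers$pos_cM >= 130.04 &
                            co$markers$pos_cM <= 132.06]
  expect_equal(length(snps), 21)
  G <- cohort_dosage_matrix(co, snps)
  r2m <- suppressWarnings(cor(G, use = "pairwise.complete.obs")^2)
  tg <- select_tags(r2m, 0.8,
                    positions = setNames(
                      co$markers$pos_cM[match(snps, co$markers$name)], snps))
  expect_lte(length(tg$tags), 6)
  expect_setequal(unique(unlist(tg$capture)), snps)
})

test_that("family-aware haplotype dosages", {
  # 2-SNP toy family: parents homozygous, child double het -> integer
  # dosages with phase resolved by the parents
  ind <- data.frame(id = c("P1", "P2", "S1"), family_id = "F1",
                    father_id = c(NA, NA, "P1"),
                    mother_id = c(NA, NA, "P2"),
                    sex = c("male", "female", "male"),
                    stringsAsFactors = FALSE)
  mk <- data.frame(name = c("x", "y"), chrom = 1L, pos_cM = c(1, 1.1),
                   pos_bp = 1:2)
  mk$alleles <- rep(list(c("A", "B")), 2)
  a1 <- rbind(c(2L, 2L), c(1L, 1L), c(2L, 2L))
  a2 <- rbind(c(2L, 2L), c(1L, 1L), c(1L, 1L))
  co <- new_cohort(ind, mk, a1, a2)
  fr <- data.frame(hap = c("11", "22", "12", "21"),
                   freq = c(0.4, 0.4, 0.1, 0.1), stringsAsFactors = FALSE)
  fh <- family_haplotype_dosage(co, c("x", "y"), freqs = fr)
  expect_equal(fh$dosage["S1", "22"], 1)
  expect_equal(fh$dosage["S1", "11"], 1)
  expect_equal(fh$dosage["P1", "22"], 2)
  expect_true(all(abs(rowSums(fh$dosage) - 2) < 1e-6))

  # singleton double het with only 11/22 haplotypes: forced phase
  ind1 <- ind[1, , drop = FALSE]; ind1$id <- "X"
  co1 <- new_cohort(ind1, mk, matrix(c(2L, 2L), 1), matrix(c(1L, 1L), 1))
  fr2 <- data.frame(hap = c("11", "22"), freq = c(0.5, 0.5),
                    stringsAsFactors = FALSE)
  fh1 <- family_haplotype_dosage(co1, c("x", "y"), freqs = fr2)
  expect_equal(unname(fh1$dosage["X", c("11", "22")]), c(1, 1))

  # family information never increases dosage uncertainty
  co2 <- simulate_cohort(default_paper_config(seed = 407))
  tags <- paste0("T", 1:4)
  fh2 <- family_haplotype_dosage(co2, tags)
  G <- cohort_dosage_matrix(co2, tags)
  Dsing <- em_haplotype_dosages(G, fh2$freqs)
  keep <- intersect(colnames(fh2$dosage), colnames(Dsing))
  cc <- stats::complete.cases(G)
  for (h in keep[1:3]) {
    vf <- var(fh2$dosage[cc, h]); vs <- var(Dsing[cc, h])
    expect_lte(vf, vs * 1.05 + 1e-6)
  }
  expect_true(all(abs(rowSums(fh2$dosage) - 2) < 1e-6))
})

test_that("haplotype association finds the functional haplotype", {
  co <- simulate_cohort(default_paper_config(seed = 408))
  tags <- paste0("T", 1:4)
  fh <- family_haplotype_dosage(co, tags)
  ha <- haplotype_assoc(co, "trait", fh$dosage, fh$freqs,
                        covariates = character())
  # the high-activity allele rides haplotype 2211 (D)
  expect_equal(ha$per_hap$snp[which.min(ha$per_hap$p)], "hap_2211")
  expect_true(any(grepl("determined by the others",
                        ha$per_hap$collinear_note)))
  expect_true(is.finite(ha$p_trend) || is.na(ha$p_trend))
  expect_true(all(diff(ha$combos$score) > 0))
})
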