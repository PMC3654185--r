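# Shared fixtures and independent oracles.  Everything here is built in
# code at test time; the oracles deliberately re-derive results from
# first principles (path enumeration, counting, closed forms) without
# touching the package's HMM or likelihood code paths.

# -- tiny nuclear-family cohort builder ------------------------------------
# geno: list with a1, a2 integer matrices (rows: P1, P2, S1..Sk)
make_family_cohort <- function(n_sibs, pos, alleles_per_marker, a1, a2,
                               traits = NULL) {
  m <- length(pos)
  ids <- c("P1", "P2", paste0("S", seq_len(n_sibs)))
  ind <- data.frame(
    id = ids, family_id = "F1",
    father_id = c(NA, NA, rep("P1", n_sibs)),
    mother_id = c(NA, NA, rep("P2", n_sibs)),
    sex = c("male", "female", rep(c("male", "female"),
                                  length.out = n_sibs)),
    stringsAsFactors = FALSE)
  mk <- data.frame(name = paste0("m", seq_len(m)), chrom = 1L,
                   pos_cM = pos, pos_bp = seq_len(m) * 1000L,
                   stringsAsFactors = FALSE)
  mk$alleles <- lapply(alleles_per_marker, function(k) as.character(seq_len(k)))
  new_cohort(ind, mk, a1, a2, traits)
}

# -- exhaustive inheritance-vector oracle ----------------------------------
# Emission by direct summation over ordered parental genotypes.
oracle_emission <- function(v, s, sibA, sibB, fa, mo, freq) {
  nal <- length(freq)
  expand_parent <- function(g) {
    if (!any(is.na(g))) return(list(set = list(g, rev(g)), w = c(0.5, 0.5)))
    eg <- as.matrix(expand.grid(seq_len(nal), seq_len(nal)))
    list(set = split(eg, row(eg)), w = freq[eg[, 1]] * freq[eg[, 2]])
  }
  fp <- expand_parent(fa); mp <- expand_parent(mo)
  tot <- 0
  for (i in seq_along(fp$set)) for (j in seq_along(mp$set)) {
    pr <- 1
    for (k in seq_len(s)) {
      if (is.na(sibA[k])) next
      pbit <- bitwAnd(bitwShiftR(v, 2L * (k - 1L)), 1L) + 1L
      mbit <- bitwAnd(bitwShiftR(v, 2L * (k - 1L) + 1L), 1L) + 1L
      trans <- sort(as.integer(c(fp$set[[i]][pbit], mp$set[[j]][mbit])))
      if (!identical(trans, sort(as.integer(c(sibA[k], sibB[k]))))) {
        pr <- 0; break
      }
    }
    tot <- tot + fp$w[i] * mp$w[j] * pr
  }
  tot
}

# Posterior IBD for sib pair (1,2) by brute-force path enumeration over
# all inheritance-vector sequences (markers plus query positions).
oracle_ibd <- function(s, sibs_a, sibs_b, fa, mo, freqs, pos, grid) {
  ns <- 4^s
  allpos <- sort(unique(c(pos, grid)))
  ismark <- allpos %in% pos
  Em <- matrix(1, ns, length(allpos))
  for (ii in seq_along(allpos)) {
    if (!ismark[ii]) next
    k <- match(allpos[ii], pos)
    for (v in 0:(ns - 1))
      Em[v + 1, ii] <- oracle_emission(v, s, sibs_a[, k], sibs_b[, k],
                                       fa[k, ], mo[k, ], freqs[[k]])
  }
  th <- 0.5 * (1 - exp(-2 * diff(allpos) / 100))
  trans_p <- function(u, v, theta) {
    h <- sum(bitwAnd(bitwXor(u, v), 2^(0:(2 * s - 1))) > 0)
    theta^h * (1 - theta)^(2 * s - h)
  }
  npos <- length(allpos)
  paths <- as.matrix(expand.grid(rep(list(0:(ns - 1)), npos)))
  w <- rep(1 / ns, nrow(paths))
  for (ii in seq_len(npos)) {
    w <- w * Em[paths[, ii] + 1, ii]
    if (ii < npos) {
      tm <- outer(0:(ns - 1), 0:(ns - 1),
                  Vectorize(function(u, v) trans_p(u, v, th[ii])))
      w <- w * tm[cbind(paths[, ii] + 1, paths[, ii + 1] + 1)]
    }
  }
  res <- matrix(0, 3, length(grid))
  for (gi in seq_along(grid)) {
    ii <- match(grid[gi], allpos)
    for (v in 0:(ns - 1)) {
      pb <- bitwAnd(v, 1L) == bitwAnd(bitwShiftR(v, 2L), 1L)
      mb <- bitwAnd(bitwShiftR(v, 1L), 1L) ==
        bitwAnd(bitwShiftR(v, 3L), 1L)
      res[pb + mb + 1, gi] <- res[pb + mb + 1, gi] + sum(w[paths[, ii] == v])
    }
  }
  sweep(res, 2, colSums(res), "/")
}

# -- independent Mendelian-consistency validator ---------------------------
check_mendelian <- function(cohort) {
  ind <- cohort$individuals
  bad <- 0L
  for (i in which(!ind$founder)) {
    fi <- match(ind$father_id[i], ind$id)
    mi <- match(ind$mother_id[i], ind$id)
    for (k in seq_len(nrow(cohort$markers))) {
      c1 <- cohort$geno_a1[i, k]; c2 <- cohort$geno_a2[i, k]
      if (c1 == 0 || c2 == 0) next
      fa <- c(cohort$geno_a1[fi, k], cohort$geno_a2[fi, k])
      mo <- c(cohort$geno_a1[mi, k], cohort$geno_a2[mi, k])
      if (any(fa == 0) || any(mo == 0)) next
      ok <- (c1 %in% fa && c2 %in% mo) || (c2 %in% fa && c1 %in% mo)
      if (!ok) bad <- bad + 1L
    }
  }
  bad
}

# -- lean linked-trait world for partition tests ---------------------------
# 5 microsatellite flanks, an additive QTL SNP at 20.5 cM and an
# unlinked SNP at 140 cM; sib-trio families, parents genotyped but not
# phenotyped.
partition_world_config <- function(n_families = 400, beta = 1.29,
                                   seed = 1L) {
  map <- data.frame(
    name = c(paste0("M", 1:5), "Q", "U"), chrom = 1L,
    pos_cM = c(0, 10, 20, 30, 40, 20.5, 140),
    type = c(rep("micro", 5), "snp", "snp"),
    n_alleles = c(rep(8L, 5), 2L, 2L), stringsAsFactors = FALSE)
  map <- map[order(map$pos_cM), ]
  map$pos_bp <- as.integer(map$pos_cM * 1e6)
  freqs <- lapply(seq_len(nrow(map)), function(k)
    if (map$n_alleles[k] == 8) rep(1 / 8, 8) else c(0.7, 0.3))
  spec <- ld_spec(freqs = freqs)
  sim_config(n_families = n_families, sibs_weights = c(0, 0, 1),
             parent_genotyping_rate = 1, map = map, founder_spec = spec,
             qtl = list(snp = "Q", means = c(0, beta, 2 * beta)),
             sigma_g = 0.3, sigma_e = 0.4,
             trait_nondiabetic_only = FALSE, measure_rate = 1,
             replication = list(n_full = 0, n_mixed = 0), seed = seed)
}

partition_world <- function(seed, n_families = 400) {
  co <- simulate_cohort(partition_world_config(n_families = n_families,
                                               seed = seed))
  # sibs only carry the phenotype (linkage is a sibship analysis)
  par <- grepl("_P", co$traits$id)
  co$traits$trait[par] <- NA
  co
}
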