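# Synthetic nuclear-family cohorts with the statistical structure the
# downstream analyses assume: founder haplotypes with a designated LD
# cluster, Mendelian gene-dropping with Haldane recombination, a
# quantitative trait driven by a cluster SNP plus a polygenic background,
# and an age-dependent disease generated from a liability with a
# Gompertz-like onset hazard, so the age-adjusted score and the bivariate
# linkage stages see real signal.

#' Founder-haplotype LD specification
#'
#' @param freqs list of per-marker allele-frequency vectors (each sums
#'   to 1); markers outside the cluster are drawn independently.
#' @param cluster_cols integer marker indices of the LD cluster.
#' @param cluster_haps integer matrix (haplotype classes x cluster SNPs)
#'   of allele indices.
#' @param cluster_freqs frequencies of the haplotype classes.
#' @param proxy optional data.frame (`col`, `source`, `flip`): marker
#'   `col` copies the allele of cluster member `source` on the same
#'   haplotype, flipped with probability `flip` (creates r2 ~ (1-2 flip)^2
#'   tagging structure).
#' @return An `ld_spec` object for [simulate_founder_haplotypes()].
#' @export
ld_spec <- function(freqs, cluster_cols = integer(), cluster_haps = NULL,
                    cluster_freqs = NULL, proxy = NULL) {
  if (length(cluster_cols) > 0) {
    stopifnot(is.matrix(cluster_haps),
              ncol(cluster_haps) == length(cluster_cols),
              length(cluster_freqs) == nrow(cluster_haps))
    if (abs(sum(cluster_freqs) - 1) > 1e-9)
      stop("cluster haplotype frequencies must sum to 1")
  }
  structure(list(freqs = freqs, cluster_cols = cluster_cols,
                 cluster_haps = cluster_haps, cluster_freqs = cluster_freqs,
                 proxy = proxy),
            class = "ld_spec")
}

#' Two-SNP LD specification from marginals and a target r2
#'
#' Solves for the haplotype frequencies implied by minor-allele
#' frequencies `pA`, `pB` (allele 2 at each SNP) and squared correlation
#' `r2` with the given sign of D; errors when no valid frequency vector
#' exists.
#' @param pA,pB allele-2 frequencies.
#' @param r2 target squared allelic correlation.
#' @param sign sign of D (+1 or -1).
#' @export
ld_spec_two_snp <- function(pA, pB, r2, sign = 1) {
  D <- sign * sqrt(r2 * pA * (1 - pA) * pB * (1 - pB))
  f <- c(`11` = (1 - pA) * (1 - pB) + D, `12` = (1 - pA) * pB - D,
         `21` = pA * (1 - pB) - D, `22` = pA * pB + D)
  if (any(f < -1e-12))
    stop("infeasible LD spec: requested r2 incompatible with allele frequencies")
  f <- pmax(f, 0); f <- f / sum(f)
  haps <- cbind(c(1L, 1L, 2L, 2L), c(1L, 2L, 1L, 2L))
  keep <- f > 0
  ld_spec(freqs = list(c(1 - pA, pA), c(1 - pB, pB)),
          cluster_cols = 1:2, cluster_haps = haps[keep, , drop = FALSE],
          cluster_freqs = f[keep])
}

#' Draw a pool of founder haplotypes
#'
#' @param spec an [ld_spec()].
#' @param n number of haplotypes.
#' @param seed integer seed.
#' @return Integer matrix `n x n_markers` of allele indices.
#' @export
simulate_founder_haplotypes <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "ld_spec"))
  if (!is.null(seed)) set.seed(seed)
  m <- length(spec$freqs)
  H <- matrix(0L, n, m)
  indep <- setdiff(seq_len(m), c(spec$cluster_cols,
                                 if (!is.null(spec$proxy)) spec$proxy$col))
  for (k in indep)
    H[, k] <- sample.int(length(spec$freqs[[k]]), n, replace = TRUE,
                         prob = spec$freqs[[k]])
  if (length(spec$cluster_cols) > 0) {
    cls <- sample.int(nrow(spec$cluster_haps), n, replace = TRUE,
                      prob = spec$cluster_freqs)
    H[, spec$cluster_cols] <- spec$cluster_haps[cls, , drop = FALSE]
  }
  if (!is.null(spec$proxy)) {
    for (r in seq_len(nrow(spec$proxy))) {
      src <- H[, spec$proxy$source[r]]
      flip <- runif(n) < spec$proxy$flip[r]
      H[, spec$proxy$col[r]] <- ifelse(flip, 3L - src, src)
    }
  }
  H
}

#' Empirical r2 between two biallelic columns of a haplotype pool
#' @param pool matrix from [simulate_founder_haplotypes()].
#' @param i,j column indices.
#' @export
pool_r2 <- function(pool, i, j) cor(pool[, i], pool[, j])^2

#' Simulation configuration
#'
#' The defaults of [default_paper_config()] describe the emulated study;
#' `sim_config` itself is the general constructor.  Variance units are
#' those of the quantitative trait (enzyme units).
#'
#' @param n_families number of nuclear families.
#' @param sibs_weights distribution of sibship sizes 1..length(weights).
#' @param parent_genotyping_rate probability each parent is genotyped.
#' @param map marker map data.frame (`name`, `chrom`, `pos_cM`, `pos_bp`,
#'   `type` in `"micro"`/`"snp"`, `n_alleles`).
#' @param founder_spec an [ld_spec()] over the map's markers.
#' @param qtl list: `snp` (name), `means` (trait mean by minor-allele
#'   dosage 0/1/2).
#' @param sigma_g,sigma_e polygenic and environmental trait variances.
#' @param disease list: `rho_locus` (genetic correlation target between
#'   the trait QTL effect and the disease-liability locus effect),
#'   `w_locus`, `w_poly`, `sigma_liab` (liability weights/SD), `lambda0`,
#'   `gompertz_k` (baseline hazard scale and age slope per year).
#' @param trait2 optional second quantitative trait: list `mu`, `c_locus`
#'   (loading on the shared-locus effect), `rho_locus`, `sigma_g`,
#'   `sigma_e`.
#' @param trait_nondiabetic_only measure the trait only in individuals
#'   non-diabetic at a draw exam preceding the last exam.
#' @param measure_rate probability an eligible individual has the trait
#'   measured.
#' @param admixture_shape Beta parameters for the admixture fraction.
#' @param replication list `n_full`, `n_mixed`: extra singleton/sib-pair
#'   families labelled as replication strata.
#' @param seed integer; fully determines the simulated cohort.
#' @return A `sim_config` object.
#' @export
sim_config <- function(n_families = 264,
                       sibs_weights = c(0.58, 0.24, 0.09, 0.05, 0.025, 0.015),
                       parent_genotyping_rate = 0.7,
                       map = NULL, founder_spec = NULL,
                       qtl = list(snp = NULL, means = c(0, 0, 0)),
                       sigma_g = 29, sigma_e = 42.7,
                       disease = list(rho_locus = -0.5, w_locus = 0.7,
                                      w_poly = 0.7, sigma_liab = 0.7,
                                      lambda0 = 4e-4, gompertz_k = 0.07),
                       trait2 = NULL,
                       trait_nondiabetic_only = TRUE, measure_rate = 0.74,
                       admixture_shape = c(1.5, 6),
                       replication = list(n_full = 0, n_mixed = 0),
                       seed = 1L) {
  cfg <- structure(as.list(environment()), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_families >= 1,
            all(cfg$sibs_weights >= 0), sum(cfg$sibs_weights) > 0,
            cfg$parent_genotyping_rate >= 0, cfg$parent_genotyping_rate <= 1,
            cfg$sigma_g >= 0, cfg$sigma_e > 0,
            abs(cfg$disease$rho_locus) <= 1,
            cfg$measure_rate >= 0, cfg$measure_rate <= 1)
  if (!is.null(cfg$map))
    stopifnot(!is.null(cfg$founder_spec),
              length(cfg$founder_spec$freqs) == nrow(cfg$map))
  invisible(cfg)
}

# Default map: 13 microsatellites every 12.5 cM across a ~160 cM
# chromosome, 40 background scan SNPs, and a 21-SNP region at 131 cM
# containing 4 tag SNPs plus 17 proxies (groups of 2/2/4/9, emulating the
# capture pattern of a one-gene LD region).
default_map <- function() {
  micro <- data.frame(name = sprintf("M%02d", 1:13), chrom = 1L,
                      pos_cM = seq(5, 155, by = 12.5), type = "micro",
                      n_alleles = 8L, stringsAsFactors = FALSE)
  scan_pos <- setdiff(seq(2, 158, by = 4), seq(5, 155, by = 12.5))
  snp <- data.frame(name = sprintf("S%02d", seq_along(scan_pos)), chrom = 1L,
                    pos_cM = scan_pos, type = "snp", n_alleles = 2L,
                    stringsAsFactors = FALSE)
  ldr_pos <- seq(130.05, 132.05, by = 0.1)
  ldr <- data.frame(name = c(sprintf("L%02d", 1:17), paste0("T", 1:4)),
                    chrom = 1L, pos_cM = NA_real_, type = "snp",
                    n_alleles = 2L, stringsAsFactors = FALSE)
  # interleave tags among the proxies along the region
  ord <- c("L01", "L02", "T1", "L03", "L04", "T2", "L05", "L06", "L07",
           "L08", "T3", "L09", "L10", "L11", "L12", "T4", "L13", "L14",
           "L15", "L16", "L17")
  ldr <- ldr[match(ord, ldr$name), ]
  ldr$pos_cM <- ldr_pos
  map <- rbind(micro, snp, ldr)
  map <- map[order(map$pos_cM), ]
  map$pos_bp <- as.integer(round(map$pos_cM * 1e6))
  rownames(map) <- NULL
  map
}

default_founder_spec <- function(map) {
  micro_freq <- c(0.2, 0.2, 0.15, 0.15, 0.1, 0.1, 0.05, 0.05)
  scan_maf <- c(0.10, 0.35, 0.22, 0.45, 0.28, 0.15, 0.40, 0.08)
  freqs <- vector("list", nrow(map))
  j <- 0
  for (k in seq_len(nrow(map))) {
    if (map$type[k] == "micro") {
      freqs[[k]] <- micro_freq
    } else if (grepl("^S", map$name[k])) {
      j <- j + 1
      p <- scan_maf[(j - 1) %% length(scan_maf) + 1]
      freqs[[k]] <- c(1 - p, p)
    } else {
      freqs[[k]] <- c(0.5, 0.5) # cluster/proxy columns: overwritten below
    }
  }
  tags <- match(paste0("T", 1:4), map$name)
  # haplotype classes over the tags (allele 2 = minor); minor-allele
  # frequencies implied: (0.36, 0.08, 0.29, 0.13)
  haps <- rbind(c(2L, 1L, 2L, 2L),  # A: low-activity haplotype
                c(1L, 1L, 1L, 1L),  # B
                c(2L, 1L, 2L, 1L),  # C
                c(2L, 2L, 1L, 1L),  # D: carries the high-activity allele
                c(1L, 1L, 2L, 1L))  # rare remainder class
  hfreq <- c(0.13, 0.63, 0.15, 0.08, 0.01)
  src_tag <- c(rep(1, 2), rep(2, 2), rep(3, 4), rep(4, 9))
  # flip 0.01 keeps proxies of even the rarest tag above r2 = 0.8
  proxy <- data.frame(col = match(sprintf("L%02d", 1:17), map$name),
                      source = tags[src_tag], flip = 0.01)
  ld_spec(freqs = freqs, cluster_cols = tags, cluster_haps = haps,
          cluster_freqs = hfreq, proxy = proxy)
}

#' Configuration emulating the study design
#'
#' 264 nuclear families (~970 members), ~60% of them with the
#' quantitative trait measured at a non-diabetic draw exam, a 4-SNP tag
#' cluster at 131 cM with minor-allele frequencies (0.36, 0.08, 0.29,
#' 0.13), per-genotype trait means (15, 35, 80) at the cluster QTL so
#' that the cluster accounts for roughly half of the trait variance, and
#' an age-dependent disease whose liability shares the QTL with genetic
#' correlation -0.5.
#' @param seed integer seed.
#' @export
default_paper_config <- function(seed = 1L) {
  map <- default_map()
  sim_config(map = map, founder_spec = default_founder_spec(map),
             qtl = list(snp = "T2", means = c(15, 35, 80)),
             replication = list(n_full = 600, n_mixed = 600),
             seed = seed)
}

# recombinant gamete: returns list(alleles, origin) along the map
make_gamete <- function(hap1, hap2, org1, org2, theta_adj) {
  m <- length(hap1)
  slot <- integer(m)
  slot[1] <- sample.int(2L, 1L)
  if (m > 1) {
    sw <- runif(m - 1) < theta_adj
    slot <- 1L + (cumsum(c(slot[1] - 1L, sw)) %% 2L)
  }
  list(alleles = ifelse(slot == 1L, hap1, hap2),
       origin = ifelse(slot == 1L, org1, org2),
       slot = slot)
}

#' Simulate a cohort
#'
#' Founders draw haplotype pairs from the founder pool; offspring are
#' produced by Mendelian gene-dropping with Haldane recombination between
#' adjacent markers.  The quantitative trait is `mean_by_QTL_genotype +
#' polygenic + environmental`; disease is assigned by comparing the
#' cumulative Gompertz hazard of the liability model to the age at last
#' exam.  The true founder origin of every transmitted allele is recorded
#' in `attr(cohort, "truth")` so tests can compare against exact IBD.
#'
#' @param cfg a [sim_config()].
#' @return A [new_cohort()] with traits attached.
#' @export
simulate_cohort <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  map <- if (is.null(cfg$map)) default_map() else cfg$map
  spec <- if (is.null(cfg$founder_spec)) default_founder_spec(map) else cfg$founder_spec
  m <- nrow(map)
  theta_adj <- haldane_theta(diff(map$pos_cM))

  sib_sizes <- sample.int(length(cfg$sibs_weights), cfg$n_families,
                          replace = TRUE, prob = cfg$sibs_weights)
  n_core <- sum(sib_sizes) + 2 * cfg$n_families
  # replication strata: families of 1-2 sibs with ungenotyped parents
  rep_sizes <- list(full = integer(), mixed = integer())
  for (st in c("full", "mixed")) {
    n_target <- cfg$replication[[paste0("n_", st)]]
    if (n_target > 0) {
      sz <- integer()
      while (sum(sz) < n_target) sz <- c(sz, sample(1:2, 1))
      rep_sizes[[st]] <- sz
    }
  }
  fam_sibs <- c(sib_sizes, rep_sizes$full, rep_sizes$mixed)
  fam_stratum <- c(rep("linkage", cfg$n_families),
                   rep("full_heritage", length(rep_sizes$full)),
                   rep("mixed_heritage", length(rep_sizes$mixed)))
  fam_in_ped <- c(rep(TRUE, cfg$n_families),
                  rep(FALSE, length(fam_sibs) - cfg$n_families))
  n_fam <- length(fam_sibs)

  pool <- simulate_founder_haplotypes(spec, 4 * n_fam)
  qtl_col <- if (!is.null(cfg$qtl$snp)) match(cfg$qtl$snp, map$name) else NA
  # hidden biallelic locus at the QTL position, independent of the pool
  hid_pool <- rbinom(4 * n_fam, 1, 0.3)

  rows <- list(); ga1 <- list(); ga2 <- list(); oa1 <- list(); oa2 <- list()
  hid <- list(); poly <- list(); dpoly <- list()
  next_hap <- 0
  for (f in seq_len(n_fam)) {
    fid <- sprintf("F%04d", f)
    s <- fam_sibs[f]
    hp <- next_hap + 1:4; next_hap <- next_hap + 4
    fa <- list(h1 = pool[hp[1], ], h2 = pool[hp[2], ], o = hp[1:2],
               z = hid_pool[hp[1:2]])
    mo <- list(h1 = pool[hp[3], ], h2 = pool[hp[4], ], o = hp[3:4],
               z = hid_pool[hp[3:4]])
    pa <- rnorm(2, 0, sqrt(cfg$sigma_g))   # trait polygenic, founders
    pd <- rnorm(2, 0, 1)                   # disease polygenic, founders
    ids <- c(paste0(fid, "_P1"), paste0(fid, "_P2"),
             paste0(fid, "_S", seq_len(s)))
    rows[[f]] <- data.frame(
      id = ids, family_id = fid,
      father_id = c(NA, NA, rep(ids[1], s)),
      mother_id = c(NA, NA, rep(ids[2], s)),
      sex = c("male", "female",
              sample(c("male", "female"), s, replace = TRUE)),
      stratum = fam_stratum[f], in_core = fam_in_ped[f],
      stringsAsFactors = FALSE)
    A1 <- matrix(0L, s + 2, m); A2 <- A1; O1 <- A1; O2 <- A1
    A1[1, ] <- fa$h1; A2[1, ] <- fa$h2; O1[1, ] <- fa$o[1]; O2[1, ] <- fa$o[2]
    A1[2, ] <- mo$h1; A2[2, ] <- mo$h2; O1[2, ] <- mo$o[1]; O2[2, ] <- mo$o[2]
    zc <- matrix(0L, s + 2, 2)
    zc[1, ] <- fa$z; zc[2, ] <- mo$z
    av <- c(pa, numeric(s)); dv <- c(pd, numeric(s))
    for (i in seq_len(s)) {
      g1 <- make_gamete(fa$h1, fa$h2, rep(fa$o[1], m), rep(fa$o[2], m), theta_adj)
      g2 <- make_gamete(mo$h1, mo$h2, rep(mo$o[1], m), rep(mo$o[2], m), theta_adj)
      A1[i + 2, ] <- g1$alleles; A2[i + 2, ] <- g2$alleles
      O1[i + 2, ] <- g1$origin;  O2[i + 2, ] <- g2$origin
      sl1 <- if (is.na(qtl_col)) g1$slot[1] else g1$slot[qtl_col]
      sl2 <- if (is.na(qtl_col)) g2$slot[1] else g2$slot[qtl_col]
      zc[i + 2, ] <- c(fa$z[sl1], mo$z[sl2])
      av[i + 2] <- mean(pa) + rnorm(1, 0, sqrt(cfg$sigma_g / 2))
      dv[i + 2] <- mean(pd) + rnorm(1, 0, sqrt(1 / 2))
    }
    ga1[[f]] <- A1; ga2[[f]] <- A2; oa1[[f]] <- O1; oa2[[f]] <- O2
    hid[[f]] <- zc; poly[[f]] <- av; dpoly[[f]] <- dv
  }
  individuals <- do.call(rbind, rows)
  G1 <- do.call(rbind, ga1); G2 <- do.call(rbind, ga2)
  O1 <- do.call(rbind, oa1); O2 <- do.call(rbind, oa2)
  Z <- do.call(rbind, hid)
  polyg <- unlist(poly); dpolyg <- unlist(dpoly)
  n <- nrow(individuals)
  is_parent <- grepl("_P", individuals$id)

  # trait construction
  qtl_dos <- if (!is.na(qtl_col))
    (G1[, qtl_col] == 2L) + (G2[, qtl_col] == 2L) else rep(0L, n)
  gmean <- cfg$qtl$means[qtl_dos + 1]
  z1 <- if (sd(gmean) > 0) (gmean - mean(gmean)) / sd(gmean) else rep(0, n)
  z2raw <- Z[, 1] + Z[, 2]
  z2 <- if (sd(z2raw) > 0) (z2raw - mean(z2raw)) / sd(z2raw) else rep(0, n)
  trait <- gmean + polyg + rnorm(n, 0, sqrt(cfg$sigma_e))

  # disease liability and Gompertz-like onset
  dz <- cfg$disease
  locus_liab <- dz$rho_locus * z1 + sqrt(1 - dz$rho_locus^2) * z2
  liab <- dz$w_locus * locus_liab + dz$w_poly * dpolyg +
    rnorm(n, 0, dz$sigma_liab)
  age <- ifelse(is_parent, rnorm(n, 60, 8), rnorm(n, 38, 12))
  age <- pmin(pmax(age, 16), 90)
  k <- dz$gompertz_k
  E <- -log(runif(n))
  onset <- log(1 + k * E / (dz$lambda0 * exp(liab))) / k
  affected <- as.integer(onset <= age)
  age_onset <- ifelse(affected == 1, round(onset, 1), NA_real_)

  # trait measured at a "draw" exam where the subject was non-diabetic
  draw_age <- pmax(age - 8, 16)
  eligible <- if (cfg$trait_nondiabetic_only)
    (affected == 0 | onset > draw_age) else rep(TRUE, n)
  measured <- eligible & (runif(n) < cfg$measure_rate) &
    individuals$stratum == "linkage"
  trait_obs <- ifelse(measured, trait, NA_real_)

  admix <- stats::rbeta(n, cfg$admixture_shape[1], cfg$admixture_shape[2])
  admix[individuals$stratum == "mixed_heritage"] <-
    stats::rbeta(sum(individuals$stratum == "mixed_heritage"), 4, 4)

  trait2 <- NULL
  if (!is.null(cfg$trait2)) {
    t2 <- cfg$trait2
    l2 <- t2$rho_locus * z1 + sqrt(1 - t2$rho_locus^2) * z2
    a2 <- simulate_family_polygenic(individuals, t2$sigma_g)
    trait2 <- t2$mu + t2$c_locus * l2 + a2 + rnorm(n, 0, sqrt(t2$sigma_e))
  }

  # genotyping missingness: replication-strata parents and a fraction of
  # core parents are ungenotyped; 1% sporadic missingness elsewhere
  gen_par <- rep(FALSE, n)
  pidx <- which(is_parent & individuals$in_core)
  gen_par[pidx] <- runif(length(pidx)) < cfg$parent_genotyping_rate
  genotyped <- !is_parent | gen_par
  sporadic <- matrix(runif(n * m) < 0.01, n, m)
  A1o <- G1; A2o <- G2
  A1o[!genotyped, ] <- 0L; A2o[!genotyped, ] <- 0L
  A1o[sporadic] <- 0L; A2o[sporadic] <- 0L

  alleles <- lapply(seq_len(m), function(k) {
    nk <- length(spec$freqs[[k]])
    if (nk == 2) c("A", "B") else as.character(seq_len(nk))
  })
  markers <- map[, c("name", "chrom", "pos_cM", "pos_bp")]
  markers$alleles <- alleles

  traits <- data.frame(
    id = individuals$id, family_id = individuals$family_id,
    trait = round(trait_obs, 4), affected = affected,
    age_last_exam = round(age, 1), age_onset = age_onset,
    age = round(age, 1), sex = individuals$sex,
    birth_year = as.integer(round(1990 - age)),
    admixture = round(admix, 4), stratum = individuals$stratum,
    stringsAsFactors = FALSE)
  if (!is.null(trait2)) traits$trait2 <- round(trait2, 4)

  cohort <- new_cohort(individuals[, c("id", "family_id", "father_id",
                                       "mother_id", "sex")],
                       markers, A1o, A2o, traits)
  attr(cohort, "truth") <- list(
    origin_a1 = O1, origin_a2 = O2, qtl_col = qtl_col,
    qtl_dosage = qtl_dos, genetic_mean = gmean, liability = liab,
    z_locus1 = z1, z_locus2 = z2, polygenic = polyg,
    true_a1 = G1, true_a2 = G2, seed = cfg$seed)
  cohort
}

# family-structured polygenic values (founders N(0, s2), offspring
# midparent + segregation N(0, s2/2)); order must match `individuals`
simulate_family_polygenic <- function(individuals, s2) {
  out <- numeric(nrow(individuals))
  founder <- is.na(individuals$father_id)
  out[founder] <- rnorm(sum(founder), 0, sqrt(s2))
  kid <- which(!founder)
  fi <- match(individuals$father_id[kid], individuals$id)
  mi <- match(individuals$mother_id[kid], individuals$id)
  out[kid] <- (out[fi] + out[mi]) / 2 + rnorm(length(kid), 0, sqrt(s2 / 2))
  out
}

#' Exact IBD-sharing matrices from simulation truth
#'
#' Builds, for each family, the locus-specific expected-sharing matrix
#' over the given individuals at a marker, using the recorded founder
#' origin of every allele (diagonal 1, sib pairs share/2, parent-offspring
#' 0.5, spouses 0).
#' @param cohort a simulated cohort (must carry the `truth` attribute).
#' @param marker marker name or index (defaults to the QTL column).
#' @param ids individuals to include (default: all).
#' @return Named list of matrices by family id.
#' @export
true_ibd_pihat <- function(cohort, marker = NULL, ids = NULL) {
  tru <- attr(cohort, "truth")
  if (is.null(tru)) stop("cohort carries no simulation truth")
  k <- if (is.null(marker)) tru$qtl_col
  else if (is.character(marker)) match(marker, cohort$markers$name) else marker
  ind <- cohort$individuals
  if (is.null(ids)) ids <- ind$id
  out <- list()
  for (fid in unique(ind$family_id[ind$id %in% ids])) {
    mem <- ids[ids %in% ind$id[ind$family_id == fid]]
    nm <- length(mem)
    P <- diag(1, nm); rownames(P) <- colnames(P) <- mem
    ii <- match(mem, ind$id)
    for (a in seq_len(nm)) for (b in seq_len(nm)) {
      if (a >= b) next
      ia <- ii[a]; ib <- ii[b]
      rel <- relationship(ind, ia, ib)
      P[a, b] <- P[b, a] <- switch(rel,
        sib = {
          sh <- (tru$origin_a1[ia, k] == tru$origin_a1[ib, k]) +
                (tru$origin_a2[ia, k] == tru$origin_a2[ib, k])
          sh / 2
        },
        parent_offspring = 0.5,
        unrelated = 0)
    }
    out[[fid]] <- P
  }
  out
}

relationship <- function(ind, i, j) {
  if (!is.na(ind$father_id[i]) && !is.na(ind$father_id[j]) &&
      ind$father_id[i] == ind$father_id[j] &&
      ind$mother_id[i] == ind$mother_id[j]) return("sib")
  if ((!is.na(ind$father_id[i]) &&
       ind$id[j] %in% c(ind$father_id[i], ind$mother_id[i])) ||
      (!is.na(ind$father_id[j]) &&
       ind$id[i] %in% c(ind$father_id[j], ind$mother_id[j])))
    return("parent_offspring")
  "unrelated"
}

#' Simulate traits directly from the variance-components model
#'
#' A model-based world for parameter-recovery checks: nuclear families of
#' `n_sibs` sibs, locus sharing generated by true Mendelian segregation
#' (two meiosis bits per sib), and sib trait vectors drawn from
#' `MVN(mu, s2_q * Pi + s2_g * 2Phi + s2_e * I)`.
#'
#' @param n_fam number of families.
#' @param n_sibs sibs per family.
#' @param sigma c(s2_q, s2_g, s2_e).
#' @param mu trait mean.
#' @param seed integer seed.
#' @return List with per-family elements `y`, `X` (intercept), `Pi`
#'   (true sharing at the locus), `K` (2*kinship), and the segregation
#'   bits.
#' @export
simulate_vc_families <- function(n_fam, n_sibs, sigma, mu = 0, seed = 1L) {
  set.seed(seed)
  fams <- list()
  K <- matrix(0.5, n_sibs, n_sibs); diag(K) <- 1
  for (f in seq_len(n_fam)) {
    pat <- sample.int(2L, n_sibs, replace = TRUE)
    mat <- sample.int(2L, n_sibs, replace = TRUE)
    Pi <- diag(1, n_sibs)
    for (a in seq_len(n_sibs)) for (b in seq_len(n_sibs)) {
      if (a >= b) next
      sh <- ((pat[a] == pat[b]) + (mat[a] == mat[b])) / 2
      Pi[a, b] <- Pi[b, a] <- sh
    }
    Om <- sigma[1] * Pi + sigma[2] * K + sigma[3] * diag(n_sibs)
    L <- chol(Om)
    y <- mu + as.vector(t(L) %*% rnorm(n_sibs))
    ids <- sprintf("F%04d_S%d", f, seq_len(n_sibs))
    dimnames(Pi) <- dimnames(K) <- list(ids, ids)
    fams[[sprintf("F%04d", f)]] <-
      list(ids = ids, y = y, X = matrix(1, n_sibs, 1), Pi = Pi, K = K,
           pat = pat, mat = mat)
  }
  fams
}

#' Simulate two traits from the bivariate covariance-components model
#'
#' Families of `n_sibs` sibs with locus sharing from true Mendelian
#' segregation; the stacked trait pair is drawn from
#' `Sigma_q (x) Pi + Sigma_g (x) 2Phi + Sigma_e (x) I` where each 2x2
#' `Sigma` combines the per-trait variances with correlations `rho`.
#' `rho["q"] = -1` is complete (mirror-image) pleiotropy at the locus.
#'
#' @param n_fam,n_sibs family count and sibship size.
#' @param sigma1,sigma2 per-trait c(s2_q, s2_g, s2_e).
#' @param rho named c(q=, g=, e=) correlations.
#' @param seed integer seed.
#' @return Family list consumable by [fit_vc_bivariate()] via its `fams`
#'   argument (each element carries `Pi`, `K`, `idx1`, `idx2`, `X1`,
#'   `X2`, `y1`, `y2`).
#' @export
simulate_biv_families <- function(n_fam, n_sibs, sigma1, sigma2,
                                  rho = c(q = 0, g = 0, e = 0), seed = 1L) {
  set.seed(seed)
  K <- matrix(0.5, n_sibs, n_sibs); diag(K) <- 1
  Smat <- function(v1, v2, r)
    matrix(c(v1, r * sqrt(v1 * v2), r * sqrt(v1 * v2), v2), 2, 2)
  Sq <- Smat(sigma1[1], sigma2[1], rho["q"])
  Sg <- Smat(sigma1[2], sigma2[2], rho["g"])
  Se <- Smat(sigma1[3], sigma2[3], rho["e"])
  fams <- list()
  for (f in seq_len(n_fam)) {
    pat <- sample.int(2L, n_sibs, replace = TRUE)
    mat <- sample.int(2L, n_sibs, replace = TRUE)
    Pi <- diag(1, n_sibs)
    for (a in seq_len(n_sibs)) for (b in seq_len(n_sibs)) {
      if (a >= b) next
      Pi[a, b] <- Pi[b, a] <- ((pat[a] == pat[b]) + (mat[a] == mat[b])) / 2
    }
    Om <- kronecker(Sq, Pi) + kronecker(Sg, K) +
      kronecker(Se, diag(n_sibs)) + 1e-10 * diag(2 * n_sibs)
    y <- as.vector(t(chol(Om)) %*% rnorm(2 * n_sibs))
    ids <- sprintf("F%04d_S%d", f, seq_len(n_sibs))
    dimnames(Pi) <- dimnames(K) <- list(ids, ids)
    fams[[sprintf("F%04d", f)]] <- list(
      ids = ids, Pi = Pi, K = K,
      idx1 = seq_len(n_sibs), idx2 = seq_len(n_sibs),
      X1 = matrix(1, n_sibs, 1), X2 = matrix(1, n_sibs, 1),
      y1 = y[seq_len(n_sibs)], y2 = y[n_sibs + seq_len(n_sibs)])
  }
  fams
}

#' Rescale the baseline hazard so that disease prevalence in older adults
#' hits a target
#'
#' Multiplicative bisection on `lambda0` against simulated prevalence
#' among individuals with last exam at or beyond `age_min`.
#' @param cfg a [sim_config()].
#' @param target prevalence target.
#' @param age_min age cutoff.
#' @param iter bisection iterations.
#' @return The config with `disease$lambda0` recalibrated.
#' @export
calibrate_prevalence <- function(cfg, target = 0.4, age_min = 45, iter = 8) {
  prev_at <- function(l0) {
    c2 <- cfg; c2$disease$lambda0 <- l0
    co <- simulate_cohort(c2)
    tr <- co$traits
    mean(tr$affected[tr$age_last_exam >= age_min])
  }
  lo <- cfg$disease$lambda0 / 64; hi <- cfg$disease$lambda0 * 64
  for (it in seq_len(iter)) {
    mid <- sqrt(lo * hi)
    if (prev_at(mid) < target) lo <- mid else hi <- mid
  }
  cfg$disease$lambda0 <- sqrt(lo * hi)
  cfg
}
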