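# Linkage disequilibrium and haplotype machinery: EM haplotype
# frequencies from unphased genotypes, pairwise D/D'/r2 with a
# profile-likelihood confidence interval on |D'|, confidence-interval
# haplotype blocks (95% of informative pairs in strong LD), greedy
# tag-SNP selection at an r2 threshold, zero-recombinant family-aware
# haplotype dosages, and haplotype association.

#' Allele-2 dosage matrix over a SNP set
#' @param cohort a cohort.
#' @param snps biallelic marker names.
#' @return Integer matrix (individuals x SNPs), `NA` where missing.
#' @export
cohort_dosage_matrix <- function(cohort, snps) {
  ks <- match(snps, cohort$markers$name)
  if (anyNA(ks)) stop("unknown marker(s): ", paste(snps[is.na(ks)], collapse = ", "))
  D <- sapply(ks, function(k) {
    a1 <- cohort$geno_a1[, k]; a2 <- cohort$geno_a2[, k]
    d <- (a1 == 2L) + (a2 == 2L)
    d[a1 == 0 | a2 == 0] <- NA
    d
  })
  D <- matrix(as.integer(D), nrow = nrow(cohort$geno_a1))
  dimnames(D) <- list(cohort$individuals$id, snps)
  D
}

hap_code <- function(hbits, L) {
  # integer 0..2^L-1 -> string of allele indices ("1"/"2") per SNP
  vapply(hbits, function(h)
    paste(1L + bitwAnd(bitwShiftR(h, (L - 1):0), 1L), collapse = ""),
    character(1))
}

# ordered haplotype-pair expansions compatible with a complete genotype
# row (dosage 0/1/2 per SNP); returns two integer vectors (bit codes)
compatible_pairs <- function(dos) {
  L <- length(dos)
  bits <- 2^((L - 1):0)
  base <- sum(bits[dos == 2])
  het <- which(dos == 1)
  if (length(het) == 0) return(list(h1 = base, h2 = base))
  nh <- length(het)
  combos <- as.matrix(expand.grid(rep(list(0:1), nh)))
  h1 <- h2 <- integer(nrow(combos))
  for (r in seq_len(nrow(combos))) {
    h1[r] <- base + sum(bits[het[combos[r, ] == 1]])
    h2[r] <- base + sum(bits[het[combos[r, ] == 0]])
  }
  list(h1 = h1, h2 = h2)
}

#' EM haplotype frequencies from unphased genotypes
#'
#' Standard EM over all `2^L` haplotypes; the log-likelihood is
#' non-decreasing every iteration and convergence is declared at
#' `delta loglik < 1e-10` (or 1000 iterations).  Five starts; a mode tie
#' within 1e-6 log-likelihood with different frequencies sets the
#' `ambiguous` flag, and the lexicographically largest frequency vector
#' is returned.
#'
#' @param geno dosage matrix (individuals x SNPs, values 0/1/2);
#'   individuals with any missing genotype are dropped.
#' @param n_starts random restarts.
#' @param tol,max_iter convergence control.
#' @return data.frame (`hap`, `freq`) sorted by frequency, with
#'   attributes `loglik`, `ambiguous`, `trajectory` (loglik per
#'   iteration of the winning run), `n_used`.
#' @export
em_haplotype_freqs <- function(geno, n_starts = 5, tol = 1e-10,
                               max_iter = 1000) {
  stopifnot(ncol(geno) >= 2)
  L <- ncol(geno)
  cc <- stats::complete.cases(geno)
  if (!any(cc)) stop("no complete genotypes for EM")
  G <- geno[cc, , drop = FALSE]
  # collapse identical genotype rows
  key <- apply(G, 1, paste, collapse = "/")
  tab <- table(key)
  urows <- G[match(names(tab), key), , drop = FALSE]
  wts <- as.numeric(tab)
  pairs <- lapply(seq_len(nrow(urows)), function(r)
    compatible_pairs(urows[r, ]))
  H <- 2^L
  run_em <- function(f0) {
    f <- f0
    ll_old <- -Inf; traj <- numeric()
    for (it in seq_len(max_iter)) {
      newf <- numeric(H); ll <- 0
      for (r in seq_along(pairs)) {
        p1 <- pairs[[r]]$h1 + 1L; p2 <- pairs[[r]]$h2 + 1L
        w <- f[p1] * f[p2]
        tw <- sum(w)
        if (tw <= 0) { w <- rep(1 / length(w), length(w)); tw <- 1e-300 }
        ll <- ll + wts[r] * log(tw)
        po <- w / sum(w)
        for (q in seq_along(p1)) {
          newf[p1[q]] <- newf[p1[q]] + wts[r] * po[q]
          newf[p2[q]] <- newf[p2[q]] + wts[r] * po[q]
        }
      }
      f <- newf / sum(newf)
      traj <- c(traj, ll)
      if (is.finite(ll_old) && ll - ll_old < tol) break
      ll_old <- ll
    }
    list(f = f, loglik = ll, traj = traj)
  }
  # uniform start plus two deterministic parity-biased starts: the
  # classic all-double-heterozygote bimodality splits exactly along
  # haplotype bit parity, so these land in opposite modes when they exist
  parity <- vapply(0:(H - 1), function(h)
    sum(bitwAnd(h, 2^(0:(L - 1))) > 0L) %% 2L, integer(1))
  f_even <- ifelse(parity == 0, 2, 1); f_even <- f_even / sum(f_even)
  f_odd <- ifelse(parity == 1, 2, 1); f_odd <- f_odd / sum(f_odd)
  runs <- lapply(list(rep(1 / H, H), f_even, f_odd), run_em)
  if (n_starts > 3)
    for (s in seq_len(n_starts - 3)) {
      f0 <- rgamma(H, 1); f0 <- f0 / sum(f0)
      runs[[length(runs) + 1]] <- run_em(f0)
    }
  lls <- vapply(runs, `[[`, numeric(1), "loglik")
  best_ll <- max(lls)
  near <- which(lls > best_ll - 1e-6)
  ambiguous <- FALSE
  pick <- near[1]
  if (length(near) > 1) {
    fmat <- do.call(rbind, lapply(runs[near], `[[`, "f"))
    if (max(apply(fmat, 2, function(col) diff(range(col)))) > 1e-3) {
      ambiguous <- TRUE
      ord <- do.call(order, c(as.data.frame(-fmat), list()))
      pick <- near[ord[1]]
    }
  }
  f <- runs[[pick]]$f
  out <- data.frame(hap = hap_code(0:(H - 1), L), freq = f,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$freq, out$hap), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, loglik = runs[[pick]]$loglik, ambiguous = ambiguous,
            trajectory = runs[[pick]]$traj, n_used = sum(cc))
}

#' Per-individual expected haplotype dosages by singleton EM posterior
#' @param geno dosage matrix as in [em_haplotype_freqs()].
#' @param freqs data.frame (`hap`, `freq`).
#' @return Matrix (individuals x haplotypes); rows sum to 2; `NA` rows
#'   for incomplete genotypes.
#' @export
em_haplotype_dosages <- function(geno, freqs) {
  L <- ncol(geno)
  f <- setNames(freqs$freq, freqs$hap)
  allh <- hap_code(0:(2^L - 1), L)
  fv <- rep(0, 2^L); names(fv) <- allh
  fv[names(f)] <- f
  D <- matrix(NA_real_, nrow(geno), 2^L, dimnames = list(rownames(geno), allh))
  for (i in seq_len(nrow(geno))) {
    if (anyNA(geno[i, ])) next
    pr <- compatible_pairs(geno[i, ])
    p1 <- pr$h1 + 1L; p2 <- pr$h2 + 1L
    w <- fv[p1] * fv[p2]
    if (sum(w) <= 0) w <- rep(1, length(w))
    w <- w / sum(w)
    row <- numeric(2^L)
    for (q in seq_along(p1)) {
      row[p1[q]] <- row[p1[q]] + w[q]
      row[p2[q]] <- row[p2[q]] + w[q]
    }
    D[i, ] <- row
  }
  D
}

two_locus_geno_probs <- function(p) {
  # p = c(p11, p12, p21, p22) haplotype freqs (allele index 1/2 per SNP);
  # returns 3x3 genotype-class probabilities indexed by dosages (0..2, 0..2)
  P <- matrix(0, 3, 3)
  hapd <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  for (a in 1:4) for (b in 1:4) {
    d1 <- hapd[a, 1] + hapd[b, 1]; d2 <- hapd[a, 2] + hapd[b, 2]
    P[d1 + 1, d2 + 1] <- P[d1 + 1, d2 + 1] + p[a] * p[b]
  }
  P
}

#' LD coefficients from two-locus haplotype frequencies
#'
#' Definitional closed forms: `D = p_22 - p_2. p_.2`,
#' `D' = |D| / D_max` (`D_max = min(p q, q p)` on the side matching the
#' sign of D), `r2 = D^2 / (p(1-p) q(1-q))`.
#' @param p length-4 haplotype frequencies in order `11, 12, 21, 22`
#'   (allele index per SNP).
#' @return list `D`, `Dprime`, `r2`, `pa`, `pb` (allele-2 frequencies).
#' @export
ld_from_hap_freqs <- function(p) {
  stopifnot(length(p) == 4, abs(sum(p) - 1) < 1e-6)
  pa <- p[3] + p[4]; pb <- p[2] + p[4]
  D <- p[4] - pa * pb
  dmax <- if (D >= 0) min(pa * (1 - pb), (1 - pa) * pb)
          else min(pa * pb, (1 - pa) * (1 - pb))
  dp <- if (dmax <= 0) 0 else abs(D) / dmax
  r2 <- if (pa <= 0 || pa >= 1 || pb <= 0 || pb >= 1) 0
        else D^2 / (pa * (1 - pa) * pb * (1 - pb))
  list(D = unname(D), Dprime = unname(min(dp, 1)), r2 = unname(min(r2, 1)),
       pa = unname(pa), pb = unname(pb), dmax = unname(dmax))
}

#' Pairwise linkage disequilibrium between two SNPs
#'
#' Two-locus haplotype frequencies by EM; `D = p_22 - p_2 q_2`,
#' `D' = |D| / D_max`, `r2 = D^2 / (p q p q)`.  The 90% CI on `|D'|` is
#' from the multinomial profile likelihood of the 3x3 genotype table
#' over a 1001-point grid on `[0, 1]` (allele frequencies held at their
#' MLEs, 0.05 tail masses).
#' @param da,db dosage vectors (0/1/2) for the two SNPs.
#' @param names_ab optional SNP names.
#' @return One-row data.frame: `D`, `Dprime`, `r2`, `ci_lo`, `ci_hi`.
#' @export
pairwise_ld <- function(da, db, names_ab = c("a", "b")) {
  ok <- !is.na(da) & !is.na(db)
  da <- da[ok]; db <- db[ok]
  if (length(unique(da)) < 2 || length(unique(db)) < 2)
    stop("monomorphic SNP in LD computation")
  em <- em_haplotype_freqs(cbind(da, db), n_starts = 3)
  f <- setNames(em$freq, em$hap)
  p <- c(f["11"], f["12"], f["21"], f["22"])
  p[is.na(p)] <- 0
  ldc <- ld_from_hap_freqs(p)
  pa <- ldc$pa; pb <- ldc$pb; dmax <- ldc$dmax
  D <- ldc$D; dp <- ldc$Dprime; r2 <- ldc$r2
  # genotype table for the profile likelihood
  tab <- matrix(0, 3, 3)
  for (i in seq_along(da)) tab[da[i] + 1, db[i] + 1] <- tab[da[i] + 1, db[i] + 1] + 1
  sgn <- if (D >= 0) 1 else -1
  grid <- seq(0, 1, length.out = 1001)
  ll <- vapply(grid, function(dpv) {
    Dv <- sgn * dpv * dmax
    pv <- c((1 - pa) * (1 - pb) + Dv, (1 - pa) * pb - Dv,
            pa * (1 - pb) - Dv, pa * pb + Dv)
    if (any(pv < -1e-12)) return(-Inf)
    pv <- pmax(pv, 1e-12)
    sum(tab * log(pmax(two_locus_geno_probs(pv), 1e-300)))
  }, numeric(1))
  w <- exp(ll - max(ll))
  cw <- cumsum(w) / sum(w)
  ci_lo <- grid[which(cw >= 0.05)[1]]
  ci_hi <- grid[which(cw >= 0.95)[1]]
  data.frame(snp_a = names_ab[1], snp_b = names_ab[2],
             D = unname(D), Dprime = unname(min(dp, 1)), r2 = unname(min(r2, 1)),
             ci_lo = ci_lo, ci_hi = ci_hi, n = length(da),
             stringsAsFactors = FALSE)
}

#' All pairwise LD over a SNP window
#' @param cohort a cohort.
#' @param snps marker names.
#' @return data.frame of [pairwise_ld()] rows for every pair.
#' @export
ld_matrix <- function(cohort, snps) {
  D <- cohort_dosage_matrix(cohort, snps)
  rows <- list()
  for (i in seq_along(snps)) for (j in seq_along(snps)) {
    if (i >= j) next
    rows[[length(rows) + 1]] <-
      pairwise_ld(D[, i], D[, j], c(snps[i], snps[j]))
  }
  do.call(rbind, rows)
}

#' Confidence-interval haplotype blocks
#'
#' A pair is "strong LD" when its D' CI has upper bound >= 0.98 and
#' lower bound >= 0.70, and "strong recombination" when the upper bound
#' is < 0.90; other pairs are uninformative.  A block is a contiguous
#' run whose outermost pair is strong LD and in which at least 95% of
#' informative pairs are strong LD; SNPs below the MAF threshold are
#' ignored.  Longest candidates win; blocks do not overlap.
#' @param ld output of [ld_matrix()].
#' @param snps SNP names in map order.
#' @param maf named MAF vector (from `snp_maf`); SNPs with MAF <
#'   `maf_threshold` are ignored.
#' @param maf_threshold default 0.05.
#' @return List of character vectors (SNP names per block).
#' @export
gabriel_blocks <- function(ld, snps, maf = NULL, maf_threshold = 0.05) {
  keep <- if (is.null(maf)) snps else snps[!is.na(maf[snps]) &
                                             maf[snps] >= maf_threshold]
  ns <- length(keep)
  if (ns < 2) return(list())
  cls <- function(a, b) {
    r <- ld[(ld$snp_a == a & ld$snp_b == b) | (ld$snp_a == b & ld$snp_b == a), ]
    if (nrow(r) == 0) return("none")
    if (r$ci_hi[1] >= 0.98 && r$ci_lo[1] >= 0.70) return("strong_ld")
    if (r$ci_hi[1] < 0.90) return("strong_recomb")
    "uninformative"
  }
  cand <- list()
  for (i in seq_len(ns - 1)) for (j in (i + 1):ns) {
    if (cls(keep[i], keep[j]) != "strong_ld") next
    cl <- outer(i:j, i:j, Vectorize(function(a, b)
      if (a < b) cls(keep[a], keep[b]) else "none"))
    n_ld <- sum(cl == "strong_ld"); n_rec <- sum(cl == "strong_recomb")
    inf <- n_ld + n_rec
    if (inf == 0) next
    if (n_ld / inf >= 0.95)
      cand[[length(cand) + 1]] <- list(i = i, j = j, len = j - i + 1)
  }
  if (length(cand) == 0) return(list())
  cand <- cand[order(-vapply(cand, `[[`, numeric(1), "len"))]
  used <- rep(FALSE, ns)
  blocks <- list()
  for (cd in cand) {
    if (any(used[cd$i:cd$j])) next
    used[cd$i:cd$j] <- TRUE
    blocks[[length(blocks) + 1]] <- keep[cd$i:cd$j]
  }
  blocks[order(vapply(blocks, function(b) match(b[1], keep), numeric(1)))]
}

#' Greedy tag-SNP selection
#'
#' Repeatedly picks the SNP capturing the most not-yet-captured SNPs at
#' `r2 > threshold` (capturing itself); ties broken by lower map
#' position.  Every SNP ends up captured by at least one tag.
#' @param r2_matrix symmetric r2 matrix with SNP dimnames.
#' @param threshold redundancy threshold (default 0.8).
#' @param positions named cM positions (tie-break); default: matrix
#'   order.
#' @return List: `tags` (character), `capture` (named list tag ->
#'   captured SNPs).
#' @export
select_tags <- function(r2_matrix, threshold = 0.8, positions = NULL) {
  snps <- rownames(r2_matrix)
  if (is.null(positions)) positions <- setNames(seq_along(snps), snps)
  uncaptured <- snps
  tags <- character(); capture <- list()
  while (length(uncaptured) > 0) {
    gain <- vapply(snps, function(s) {
      cap <- snps[r2_matrix[s, ] > threshold | snps == s]
      length(intersect(cap, uncaptured))
    }, numeric(1))
    best <- max(gain)
    cands <- snps[gain == best]
    pick <- cands[which.min(positions[cands])]
    cap <- snps[r2_matrix[pick, ] > threshold | snps == pick]
    capture[[pick]] <- cap
    tags <- c(tags, pick)
    uncaptured <- setdiff(uncaptured, cap)
  }
  list(tags = tags, capture = capture)
}

#' Family-aware haplotype dosages (zero-recombinant enumeration)
#'
#' For each nuclear family, enumerates every phase configuration
#' consistent with Mendelian transmission and no recombination within
#' the SNP cluster, weights configurations by founder-haplotype
#' frequencies, and returns the posterior expected copy count of each
#' haplotype for every family member.  Families with no consistent
#' configuration are flagged and fall back to singleton posteriors.
#'
#' @param cohort a cohort.
#' @param snps cluster SNP names (at most 6).
#' @param freqs data.frame (`hap`, `freq`) from [em_haplotype_freqs()]
#'   (default: EM on the cluster genotypes).
#' @param min_freq haplotypes below this frequency are pruned from the
#'   enumeration support (renormalized).
#' @return List: `dosage` (individuals x haplotypes, rows sum to 2),
#'   `freqs`, `flagged` (family ids that needed the fallback).
#' @export
family_haplotype_dosage <- function(cohort, snps, freqs = NULL,
                                    min_freq = 1e-4) {
  if (length(snps) > 6) stop("at most 6 SNPs for exact family enumeration")
  G <- cohort_dosage_matrix(cohort, snps)
  if (is.null(freqs)) freqs <- em_haplotype_freqs(G)
  fr <- freqs[freqs$freq > min_freq, , drop = FALSE]
  fr$freq <- fr$freq / sum(fr$freq)
  H <- nrow(fr)
  L <- length(snps)
  hapmat <- t(vapply(fr$hap, function(h)
    as.integer(strsplit(h, "")[[1]]) - 1L, integer(L))) # allele-2 indicator
  # consistency of ordered pair (h1, h2) with an observed dosage row
  pair_ok <- function(dos) {
    M <- matrix(TRUE, H, H)
    for (k in seq_len(L)) {
      if (is.na(dos[k])) next
      s <- outer(hapmat[, k], hapmat[, k], `+`)
      M <- M & (s == dos[k])
    }
    M
  }
  ind <- cohort$individuals
  out <- matrix(0, nrow(ind), H, dimnames = list(ind$id, fr$hap))
  flagged <- character()
  singleton_post <- function(dos) {
    M <- pair_ok(dos)
    w <- outer(fr$freq, fr$freq) * M
    if (sum(w) <= 0) w <- M * 1
    if (sum(w) <= 0) w <- matrix(1, H, H)
    w <- w / sum(w)
    rowSums(w) + colSums(w)
  }
  for (fam in nuclear_families(cohort)) {
    mem <- c(fam$parents, fam$sibs)
    mi <- match(mem, ind$id)
    if (length(fam$sibs) == 0 || length(fam$parents) == 0) {
      for (i in mi) out[i, ] <- singleton_post(G[i, ])
      next
    }
    kid1 <- match(fam$sibs[1], ind$id)
    fa_id <- ind$father_id[kid1]; mo_id <- ind$mother_id[kid1]
    fa_dos <- if (fa_id %in% ind$id) G[match(fa_id, ind$id), ] else rep(NA, L)
    mo_dos <- if (mo_id %in% ind$id) G[match(mo_id, ind$id), ] else rep(NA, L)
    okF <- which(pair_ok(fa_dos), arr.ind = TRUE)
    okM <- which(pair_ok(mo_dos), arr.ind = TRUE)
    if (nrow(okF) == 0 || nrow(okM) == 0) {
      flagged <- c(flagged, fam$family_id)
      for (i in mi) out[i, ] <- singleton_post(G[i, ])
      next
    }
    wF <- fr$freq[okF[, 1]] * fr$freq[okF[, 2]]
    wM <- fr$freq[okM[, 1]] * fr$freq[okM[, 2]]
    kids <- match(fam$sibs, ind$id)
    Cs <- lapply(kids, function(i) pair_ok(G[i, ]))
    # per (father-pair a, mother-pair b): child transmission probability
    Pc <- lapply(Cs, function(C) {
      (C[cbind(rep(okF[, 1], nrow(okM)), rep(okM[, 1], each = nrow(okF)))] +
       C[cbind(rep(okF[, 1], nrow(okM)), rep(okM[, 2], each = nrow(okF)))] +
       C[cbind(rep(okF[, 2], nrow(okM)), rep(okM[, 1], each = nrow(okF)))] +
       C[cbind(rep(okF[, 2], nrow(okM)), rep(okM[, 2], each = nrow(okF)))]) / 4
    })
    Pc <- lapply(Pc, function(p) matrix(p, nrow(okF), nrow(okM)))
    W <- outer(wF, wM)
    for (p in Pc) W <- W * p
    if (sum(W) <= 0) {
      flagged <- c(flagged, fam$family_id)
      for (i in mi) out[i, ] <- singleton_post(G[i, ])
      next
    }
    Wn <- W / sum(W)
    # parents: expected copies from their own ordered pair
    fa_row <- numeric(H); mo_row <- numeric(H)
    wa <- rowSums(Wn); wb <- colSums(Wn)
    for (a in seq_len(nrow(okF))) {
      fa_row[okF[a, 1]] <- fa_row[okF[a, 1]] + wa[a]
      fa_row[okF[a, 2]] <- fa_row[okF[a, 2]] + wa[a]
    }
    for (b in seq_len(nrow(okM))) {
      mo_row[okM[b, 1]] <- mo_row[okM[b, 1]] + wb[b]
      mo_row[okM[b, 2]] <- mo_row[okM[b, 2]] + wb[b]
    }
    if (fa_id %in% mem) out[match(fa_id, ind$id), ] <- fa_row
    if (mo_id %in% mem) out[match(mo_id, ind$id), ] <- mo_row
    # children: transmission-resolved posterior
    for (ci in seq_along(kids)) {
      C <- Cs[[ci]]
      Pci <- Pc[[ci]]
      Pci[Pci == 0] <- Inf  # those configs contribute nothing
      row <- numeric(H)
      for (t1 in 1:2) for (t2 in 1:2) {
        fh <- okF[, t1]; mh <- okM[, t2]
        okT <- C[cbind(rep(fh, nrow(okM)), rep(mh, each = nrow(okF)))]
        okT <- matrix(okT, nrow(okF), nrow(okM))
        contrib <- Wn * okT / (4 * Pci)
        for (h in seq_len(H)) {
          sel_f <- fh == h
          sel_m <- mh == h
          if (any(sel_f)) row[h] <- row[h] + sum(contrib[sel_f, , drop = FALSE])
          if (any(sel_m)) row[h] <- row[h] + sum(contrib[, sel_m, drop = FALSE])
        }
      }
      out[kids[ci], ] <- row
    }
  }
  list(dosage = out, freqs = fr, flagged = unique(flagged))
}

#' Haplotype association and ordered-combination trend test
#'
#' Each common haplotype's expected dosage is tested like a SNP dosage
#' (mixed model for a quantitative outcome, GEE logistic for 0/1).  The
#' diplotype report groups individuals by most-likely haplotype pair,
#' orders groups by mean of `order_by` (default the outcome), and tests
#' for trend of the outcome across the ordered groups (GEE logistic for
#' disease).
#' @param cohort a cohort.
#' @param outcome trait column (0/1 columns use the GEE route).
#' @param dosage haplotype dosage matrix ([family_haplotype_dosage()] or
#'   [em_haplotype_dosages()]).
#' @param freqs data.frame (`hap`, `freq`).
#' @param covariates adjustment columns.
#' @param min_freq only haplotypes above this frequency are tested.
#' @param order_by column used to order diplotype groups for the trend
#'   test.
#' @return List: `per_hap` (assoc rows; the last haplotype is flagged
#'   collinear with the others), `combos`, `p_trend`.
#' @export
haplotype_assoc <- function(cohort, outcome, dosage, freqs,
                            covariates = c("age", "sex"), min_freq = 0.05,
                            order_by = NULL) {
  common <- freqs$hap[freqs$freq > min_freq]
  yv <- cohort$traits[[outcome]]
  binary <- all(yv[!is.na(yv)] %in% c(0, 1))
  rows <- list()
  for (h in common) {
    d <- dosage[, h]
    dv <- structure(setNames(as.numeric(d), rownames(dosage)),
                    snp_name = paste0("hap_", h), effect_allele = h)
    r <- if (binary)
      gee_logistic_assoc(cohort, outcome, dv, covariates)
    else lmm_quant_assoc(cohort, outcome, dv, covariates)
    attr(r, "fit") <- NULL
    rows[[h]] <- r
  }
  cols <- Reduce(union, lapply(rows, names))
  rows <- lapply(rows, function(r) { r[setdiff(cols, names(r))] <- NA; r[cols] })
  per_hap <- do.call(rbind, rows)
  per_hap$collinear_note <- c(rep("", nrow(per_hap) - 1),
                              "dosages sum to 2: determined by the others")
  # diplotype groups: most likely unordered pair of common haplotypes
  dip <- apply(dosage, 1, function(d) {
    if (anyNA(d) || sum(d) < 1.9) return(NA_character_)
    top <- order(-d)[1:2]
    pair <- if (d[top[1]] >= 1.5) c(top[1], top[1]) else top
    paste(sort(colnames(dosage)[pair]), collapse = "/")
  })
  ob <- if (is.null(order_by)) outcome else order_by
  obv <- cohort$traits[[ob]]
  df <- data.frame(id = cohort$traits$id, dip = dip[cohort$traits$id],
                   y = yv, ov = obv,
                   family = cohort$individuals$family_id[
                     match(cohort$traits$id, cohort$individuals$id)],
                   stringsAsFactors = FALSE)
  df <- df[!is.na(df$dip) & !is.na(df$y), , drop = FALSE]
  gm <- aggregate(ov ~ dip, data = df[!is.na(df$ov), ], FUN = mean)
  gm <- gm[order(gm$ov), , drop = FALSE]
  gm$score <- seq_len(nrow(gm))
  gm$n <- as.vector(table(df$dip)[gm$dip])
  df$score <- gm$score[match(df$dip, gm$dip)]
  df <- df[!is.na(df$score), , drop = FALSE]
  p_trend <- NA_real_
  if (length(unique(df$score)) > 1 && length(unique(df$y)) > 1) {
    X <- cbind(1, df$score)
    colnames(X) <- c("(Intercept)", "score")
    if (binary) {
      fit <- gee_logistic(df$y, X, df$family)
      se <- sqrt(fit$vcov_robust[2, 2])
      p_trend <- 2 * pnorm(-abs(fit$beta[2] / se))
    } else {
      fit <- lm(y ~ score, data = df)
      p_trend <- summary(fit)$coefficients["score", 4]
    }
  }
  combo_mean <- aggregate(y ~ dip, data = df, FUN = mean)
  combos <- merge(gm, combo_mean, by = "dip")
  combos <- combos[order(combos$score), , drop = FALSE]
  names(combos)[names(combos) == "ov"] <- paste0("mean_", ob)
  names(combos)[names(combos) == "y"] <- paste0("mean_", outcome)
  list(per_hap = per_hap, combos = combos, p_trend = p_trend)
}
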