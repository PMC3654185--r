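# SNP-conditioned decomposition of a linkage signal.  The question: how
# much of the variance attributed to the linked locus does an associated
# polymorphism explain?  Answered by fitting a bivariate
# covariance-components model to the original trait and to the residual
# adjusted for genotype (fixed effects only subtracted, so the family
# random effect is not absorbed by the adjustment), and testing the
# equality of the two locus-specific variances by a chi2_1 LRT.  A
# scaled normalizing transformation of the ranks stabilizes the
# bivariate fit (default on).

#' Rank-based normalizing transform, rescaled to the original moments
#'
#' `v_i -> Phi^{-1}((rank_i - 0.5)/n)`, average ranks for ties, then
#' rescaled to the input's mean and SD.
#' @param values numeric vector (`NA`s passed through).
#' @export
rank_normalize <- function(values) {
  ok <- !is.na(values)
  v <- values[ok]
  if (length(v) < 3) stop("need at least 3 non-missing values")
  if (max(v) - min(v) == 0) stop("all values identical: rank transform undefined")
  z <- qnorm((rank(v, ties.method = "average") - 0.5) / length(v))
  z <- (z - mean(z)) / sd(z) * sd(v) + mean(v)
  out <- values
  out[ok] <- z
  out
}

#' Residuals of a trait adjusted for genotype dosages
#'
#' Mixed-model regression of the trait on the SNP dosages plus
#' covariates with a family random intercept; only the fixed part is
#' subtracted, so within-family (including linked-locus) covariance
#' survives into the residual.
#' @inheritParams lmm_quant_assoc
#' @param snps marker names to adjust for.
#' @return List: `residuals` (named by id), `var_with`, `var_without`
#'   (total random + residual variance with and without the dosage
#'   block), `percent_total`.
#' @export
genotype_residuals <- function(cohort, trait, snps,
                               covariates = c("age", "sex")) {
  stopifnot(length(snps) >= 1)
  df <- assoc_frame(cohort, trait, covariates)
  for (s in snps) {
    d <- additive_dosage(cohort, s)
    df[[paste0("g_", s)]] <- d[df$id]
  }
  df <- df[complete.cases(df), , drop = FALSE]
  gcols <- paste0("g_", snps)
  ctrl <- lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                            check.nobs.vs.nRE = "ignore",
                            calc.derivs = FALSE)
  f1 <- as.formula(paste("y ~", paste(c("1", covariates, gcols),
                                      collapse = " + "), "+ (1 | family)"))
  f0 <- as.formula(paste("y ~", paste(c("1", covariates), collapse = " + "),
                         "+ (1 | family)"))
  m1 <- quiet_lmer(f1, data = df, REML = FALSE, control = ctrl)
  m0 <- quiet_lmer(f0, data = df, REML = FALSE, control = ctrl)
  vc <- function(m) {
    v <- as.data.frame(lme4::VarCorr(m))
    sum(v$vcov)
  }
  var_with <- vc(m1); var_without <- vc(m0)
  X <- model.matrix(as.formula(paste("~", paste(c("1", covariates, gcols),
                                                collapse = " + "))), data = df)
  fe <- lme4::fixef(m1)  # collinear dosage columns are dropped by lmer
  r <- df$y - drop(X[, names(fe), drop = FALSE] %*% fe)
  list(residuals = setNames(r, df$id), var_with = var_with,
       var_without = var_without,
       percent_total = 100 * (1 - var_with / var_without),
       fit = m1)
}

#' Partition the linked-locus variance by an associated SNP set
#'
#' @inheritParams genotype_residuals
#' @param surface an [ibd_surface()].
#' @param position cM position on the surface grid (typically the
#'   unadjusted peak).
#' @param rank_transform apply [rank_normalize()] to both traits before
#'   the bivariate fits (stability; default on).
#' @param n_starts optimizer multi-starts for the VC fits.
#' @return A `partition_result`: `snps`, `percent_total`,
#'   `percent_linked`, `lod_una`, `lod_adj`, `p_linked_reduction`,
#'   `sigma_q_trait`, `sigma_q_resid`, `undefined` flag.
#' @export
linked_variance_reduction <- function(cohort, trait, snps, surface, position,
                                      covariates = c("age", "sex"),
                                      rank_transform = TRUE, n_starts = 3) {
  gr <- genotype_residuals(cohort, trait, snps, covariates)
  ids <- names(gr$residuals)
  co2 <- cohort
  tr <- co2$traits
  tr$.trait_part <- tr[[trait]]
  tr$.resid_part <- gr$residuals[tr$id]
  tr$.trait_part[!(tr$id %in% ids)] <- NA
  co2$traits <- tr

  # univariate LODs of trait and residual at the position
  pih <- pihat_matrices(surface, co2, position, ids = ids)
  lod_of <- function(col, covs) {
    fams <- vc_family_data(co2, col, covs, ids = ids)
    f0 <- fit_vc_univariate(co2, col, NULL, covs, fams = fams, n_starts = 5)
    f1 <- fit_vc_position(fams, pih, f0, n_starts = max(2, n_starts))
    list(lod = max(0, (f1$loglik - f0$loglik) / log(10)),
         sigma_q = exp(f1$logpar[1]))
  }
  una <- lod_of(".trait_part", covariates)
  adj <- lod_of(".resid_part", character())

  # bivariate fit to (trait, residual), optionally rank-normalized
  if (rank_transform) {
    tr$.trait_part <- rank_normalize(tr$.trait_part)
    tr$.resid_part <- rank_normalize(tr$.resid_part)
    co2$traits <- tr
  }
  vt <- var(tr$.trait_part, na.rm = TRUE)
  # the residual tracks the trait closely, so start near the
  # high-correlation corner as well as at the generic heuristic
  guess <- c(log(pmax(c(una$sigma_q, vt / 3, vt / 3,
                        max(adj$sigma_q, 1e-3), vt / 3, vt / 3), 1e-6)),
             0.95, 0.95, 0.95)
  free <- fit_vc_bivariate(co2, ".trait_part", ".resid_part", pih,
                           covariates, n_starts = n_starts,
                           extra_starts = list(guess))
  eq_guess <- c(log(pmax(sqrt(free$sigma1["q"] * free$sigma2["q"]), 1e-8)),
                log(pmax(c(free$sigma1[c("g", "e")],
                           free$sigma2[c("g", "e")]), 1e-8)),
                free$rho)
  eq <- fit_vc_bivariate(co2, ".trait_part", ".resid_part", pih,
                         covariates, equal_sq = TRUE, n_starts = n_starts,
                         extra_starts = list(unname(eq_guess)))
  lrt <- max(0, 2 * (free$loglik - eq$loglik))
  p_red <- pchisq(lrt, df = 1, lower.tail = FALSE)
  sq_t <- free$sigma1["q"]; sq_r <- free$sigma2["q"]
  # below ~0.5% of the trait variance the ratio percent_linked is
  # meaningless (and its LRT unreliable); report it as undefined
  undefined <- sq_t < 5e-3 * (free$sigma1["g"] + free$sigma1["e"] + sq_t)
  pct_linked <- if (undefined) NA_real_ else 100 * (1 - sq_r / sq_t)
  # secondary (variance-ratio of the univariate fits) also reported
  pct_linked_uni <- if (una$sigma_q > 1e-8)
    100 * (1 - adj$sigma_q / una$sigma_q) else NA_real_
  structure(list(snps = snps, position = position,
                 percent_total = gr$percent_total,
                 percent_linked = unname(pct_linked),
                 percent_linked_univariate = pct_linked_uni,
                 lod_una = una$lod, lod_adj = adj$lod,
                 p_linked_reduction = unname(p_red),
                 sigma_q_trait = unname(sq_t), sigma_q_resid = unname(sq_r),
                 undefined = unname(undefined),
                 constraint = "H0: s2_q(resid) = s2_q(trait), chi2_1 LRT",
                 rank_transform = rank_transform),
            class = "partition_result")
}

#' @export
print.partition_result <- function(x, ...) {
  cat(sprintf(paste0("partition [%s] @ %.1f cM: %%total=%.1f %%linked=%s ",
                     "LOD_una=%.2f LOD_adj=%.2f p_red=%.3g\n"),
              paste(x$snps, collapse = "+"), x$position, x$percent_total,
              if (is.na(x$percent_linked)) "undef"
              else sprintf("%.1f", x$percent_linked),
              x$lod_una, x$lod_adj, x$p_linked_reduction))
  invisible(x)
}

#' Greedy step-wise linked-variance reduction
#'
#' Adds at each step the SNP with the largest incremental
#' percent-of-linked-variance explained; the conditional p-value tests
#' the equality of the locus variance before and after adding the SNP.
#' Ties (e.g. perfect proxies) are broken by input order.
#' @inheritParams linked_variance_reduction
#' @param snp_set candidate markers.
#' @param alpha_stop stop when the best conditional reduction p-value
#'   reaches this threshold.
#' @return data.frame (`step`, `snp`, `percent_linked_cum`,
#'   `p_conditional`).
#' @export
stepwise_linked_reduction <- function(cohort, trait, snp_set, surface,
                                      position, covariates = c("age", "sex"),
                                      alpha_stop = 0.05, rank_transform = TRUE,
                                      n_starts = 2) {
  out <- data.frame(step = integer(), snp = character(),
                    percent_linked_cum = numeric(), p_conditional = numeric(),
                    stringsAsFactors = FALSE)
  if (length(snp_set) == 0) return(out)
  selected <- character()
  repeat {
    remaining <- setdiff(snp_set, selected)
    if (length(remaining) == 0) break
    cand <- lapply(remaining, function(s) {
      pr <- linked_variance_reduction(cohort, trait, c(selected, s), surface,
                                      position, covariates, rank_transform,
                                      n_starts)
      p_cond <- if (length(selected) == 0) pr$p_linked_reduction else {
        conditional_reduction_p(cohort, trait, selected, c(selected, s),
                                surface, position, covariates,
                                rank_transform, n_starts)
      }
      list(pct = pr$percent_linked, p = p_cond)
    })
    pcts <- vapply(cand, function(z) ifelse(is.na(z$pct), -Inf, z$pct),
                   numeric(1))
    j <- which.max(pcts) # ties resolved to the first (input order)
    if (!is.finite(pcts[j]) || cand[[j]]$p >= alpha_stop) break
    selected <- c(selected, remaining[j])
    out <- rbind(out, data.frame(step = length(selected), snp = remaining[j],
                                 percent_linked_cum = pcts[j],
                                 p_conditional = cand[[j]]$p,
                                 stringsAsFactors = FALSE))
  }
  out
}

# LRT of equal locus variance between residual|base and residual|base+new
conditional_reduction_p <- function(cohort, trait, base, full, surface,
                                    position, covariates, rank_transform,
                                    n_starts) {
  rb <- genotype_residuals(cohort, trait, base, covariates)
  rf <- genotype_residuals(cohort, trait, full, covariates)
  ids <- intersect(names(rb$residuals), names(rf$residuals))
  co2 <- cohort
  tr <- co2$traits
  tr$.rb <- rb$residuals[tr$id]
  tr$.rf <- rf$residuals[tr$id]
  tr$.rb[!(tr$id %in% ids)] <- NA
  tr$.rf[!(tr$id %in% ids)] <- NA
  if (rank_transform) {
    tr$.rb <- rank_normalize(tr$.rb)
    tr$.rf <- rank_normalize(tr$.rf)
  }
  co2$traits <- tr
  pih <- pihat_matrices(surface, co2, position, ids = ids)
  vt <- var(tr$.rb, na.rm = TRUE)
  guess <- c(log(rep(vt / 3, 6)), 0.95, 0.95, 0.95)
  free <- fit_vc_bivariate(co2, ".rb", ".rf", pih, character(),
                           n_starts = n_starts, extra_starts = list(guess))
  eq_guess <- c(log(pmax(sqrt(free$sigma1["q"] * free$sigma2["q"]), 1e-8)),
                log(pmax(c(free$sigma1[c("g", "e")],
                           free$sigma2[c("g", "e")]), 1e-8)),
                free$rho)
  eq <- fit_vc_bivariate(co2, ".rb", ".rf", pih, character(),
                         equal_sq = TRUE, n_starts = n_starts,
                         extra_starts = list(unname(eq_guess)))
  lrt <- max(0, 2 * (free$loglik - eq$loglik))
  pchisq(lrt, df = 1, lower.tail = FALSE)
}

#' Genotype-class trait summary plus linkage partition per SNP
#'
#' One row per SNP: trait mean and SE by genotype class with counts, the
#' single-SNP association p-value, percent of total and of linked
#' variance explained, and the unadjusted/adjusted LOD scores at the
#' peak.
#' @inheritParams linked_variance_reduction
#' @param snps SNPs to report.
#' @export
partition_table <- function(cohort, trait, snps, surface, position,
                            covariates = c("age", "sex"), n_starts = 2) {
  rows <- lapply(snps, function(s) {
    dos <- additive_dosage(cohort, s)
    y <- cohort$traits[[trait]]
    d <- dos[cohort$traits$id]
    cls <- lapply(0:2, function(g) y[!is.na(d) & d == g & !is.na(y)])
    a <- lmm_quant_assoc(cohort, trait, s, covariates)
    pr <- linked_variance_reduction(cohort, trait, s, surface, position,
                                    covariates, n_starts = n_starts)
    data.frame(
      snp = s, effect_allele = attr(dos, "effect_allele"),
      mean0 = mean(cls[[1]]), se0 = sd(cls[[1]]) / sqrt(max(length(cls[[1]]), 1)),
      n0 = length(cls[[1]]),
      mean1 = mean(cls[[2]]), se1 = sd(cls[[2]]) / sqrt(max(length(cls[[2]]), 1)),
      n1 = length(cls[[2]]),
      mean2 = mean(cls[[3]]), se2 = sd(cls[[3]]) / sqrt(max(length(cls[[3]]), 1)),
      n2 = length(cls[[3]]),
      p_assoc = a$p, percent_total = pr$percent_total,
      percent_linked = pr$percent_linked, lod_una = pr$lod_una,
      lod_adj = pr$lod_adj, p_linked_reduction = pr$p_linked_reduction,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
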