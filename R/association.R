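# Single-variant association in families.  Quantitative traits use a
# linear mixed model with a sibship-shared random intercept and a
# likelihood-ratio test of the dosage term; disease uses marginal
# logistic regression fit by generalized estimating equations with an
# exchangeable working correlation (sibships as clusters), reporting the
# odds ratio per copy of the effect allele with either model-based or
# robust (sandwich) standard errors.

#' Additive dosage of an effect allele
#'
#' @param cohort a cohort.
#' @param snp biallelic marker name.
#' @param effect_allele allele label whose copies are counted; default
#'   the minor allele.
#' @return Named numeric vector (0/1/2, `NA` when missing) over all
#'   individuals, with attribute `effect_allele`.
#' @export
additive_dosage <- function(cohort, snp, effect_allele = NULL) {
  k <- match(snp, cohort$markers$name)
  if (is.na(k)) stop("unknown marker: ", snp)
  lab <- cohort$markers$alleles[[k]]
  if (length(lab) != 2) stop("marker ", snp, " is not biallelic")
  if (is.null(effect_allele)) effect_allele <- minor_allele(cohort, snp)
  e <- match(effect_allele, lab)
  if (is.na(e)) stop("allele '", effect_allele, "' not among alleles of ", snp)
  a1 <- cohort$geno_a1[, k]; a2 <- cohort$geno_a2[, k]
  d <- (a1 == e) + (a2 == e)
  d[a1 == 0 | a2 == 0] <- NA
  structure(setNames(as.numeric(d), cohort$individuals$id),
            effect_allele = effect_allele)
}

#' Minor allele of a biallelic marker (frequency over all genotyped)
#' @inheritParams additive_dosage
#' @export
minor_allele <- function(cohort, snp) {
  k <- match(snp, cohort$markers$name)
  lab <- cohort$markers$alleles[[k]]
  al <- c(cohort$geno_a1[, k], cohort$geno_a2[, k])
  counts <- tabulate(al[al > 0], nbins = length(lab))
  lab[which.min(counts)]
}

snp_maf <- function(cohort, snp) {
  k <- match(snp, cohort$markers$name)
  al <- c(cohort$geno_a1[, k], cohort$geno_a2[, k])
  al <- al[al > 0]
  if (length(al) == 0) return(NA_real_)
  p <- mean(al == 1)
  min(p, 1 - p)
}

assoc_frame <- function(cohort, outcome, covariates, dosage = NULL) {
  tr <- cohort$traits
  ind <- cohort$individuals
  df <- data.frame(id = tr$id,
                   family = ind$family_id[match(tr$id, ind$id)],
                   y = tr[[outcome]], stringsAsFactors = FALSE)
  for (cv in covariates) df[[cv]] <- tr[[cv]]
  if (!is.null(dosage)) df$dosage <- dosage[df$id]
  df[complete.cases(df), , drop = FALSE]
}

#' Mixed-model association of a quantitative trait with a SNP
#'
#' `trait ~ dosage + covariates + (1 | family)` by maximum likelihood;
#' the p-value is the likelihood-ratio test of the dosage term.
#' @param cohort a cohort.
#' @param trait trait column name.
#' @param snp marker name (or a precomputed dosage vector named by id).
#' @param covariates trait-table columns.
#' @param effect_allele counted allele (default minor).
#' @return An `assoc_result` row: data.frame with `snp`, `effect_allele`,
#'   `beta`, `se`, `p`, `n`, `note`.
#' @export
lmm_quant_assoc <- function(cohort, trait, snp, covariates = c("age", "sex"),
                            effect_allele = NULL) {
  if (is.character(snp) && length(snp) == 1) {
    dos <- additive_dosage(cohort, snp, effect_allele)
    snp_name <- snp
  } else {
    dos <- snp; snp_name <- attr(snp, "snp_name") %||% "dosage"
  }
  df <- assoc_frame(cohort, trait, covariates, dos)
  ea <- attr(dos, "effect_allele") %||% NA_character_
  res <- data.frame(snp = snp_name, effect_allele = ea, coding = "additive",
                    beta = NA_real_, se = NA_real_, p = NA_real_,
                    n = nrow(df), note = "", stringsAsFactors = FALSE)
  if (nrow(df) < 3 || var(df$y) == 0) {
    res$p <- 1; res$note <- "untestable: degenerate trait"
    return(res)
  }
  if (length(unique(df$dosage)) < 2) {
    res$p <- 1; res$note <- "untestable: monomorphic"
    return(res)
  }
  rhs <- paste(c("dosage", covariates), collapse = " + ")
  ctrl <- lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                            check.nobs.vs.nRE = "ignore",
                            calc.derivs = FALSE)
  full <- quiet_lmer(as.formula(paste("y ~", rhs, "+ (1 | family)")),
                     data = df, REML = FALSE, control = ctrl)
  red <- quiet_lmer(as.formula(paste("y ~",
                                     paste(c("1", covariates), collapse = " + "),
                                     "+ (1 | family)")),
                    data = df, REML = FALSE, control = ctrl)
  co <- summary(full)$coefficients
  res$beta <- co["dosage", "Estimate"]
  res$se <- co["dosage", "Std. Error"]
  lrt <- max(0, 2 * (as.numeric(logLik(full)) - as.numeric(logLik(red))))
  res$p <- pchisq(lrt, df = 1, lower.tail = FALSE)
  attr(res, "fit") <- full
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# lme4 signals boundary-singular fits loudly; those fits are expected
# (random-effect variance legitimately hits zero in null worlds)
quiet_lmer <- function(...) suppressWarnings(suppressMessages(lme4::lmer(...)))

#' GEE logistic regression with exchangeable working correlation
#'
#' Marginal mean model `logit P(y=1) = X beta`, clusters given by `id`
#' (sibship/family), exchangeable working correlation estimated by
#' moments.  Returns both model-based and robust covariance.
#' @param y 0/1 outcome.
#' @param X design matrix (with intercept).
#' @param cluster cluster labels.
#' @param maxit,tol IRLS iteration control.
#' @return List: `beta`, `vcov_model`, `vcov_robust`, `alpha`,
#'   `converged`, `separation`.
#' @export
gee_logistic <- function(y, X, cluster, maxit = 50, tol = 1e-10) {
  if (length(unique(y)) < 2) stop("outcome does not vary")
  beta <- stats::glm.fit(X, y, family = binomial())$coefficients
  p <- ncol(X)
  cl <- split(seq_along(y), cluster)
  alpha <- 0
  step <- rep(Inf, p)
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    v <- pmax(mu * (1 - mu), 1e-10)  # guards against separation collapse
    # moment estimate of the exchangeable correlation
    e <- (y - mu) / sqrt(pmax(v, 1e-12))
    num <- 0; den <- 0
    for (ii in cl) {
      ni <- length(ii)
      if (ni > 1) {
        s <- sum(e[ii])
        num <- num + (s^2 - sum(e[ii]^2)) / 2
        den <- den + ni * (ni - 1) / 2
      }
    }
    alpha <- if (den > 0) max(min(num / max(den - p, 1), 0.95), -0.3) else 0
    U <- numeric(p); Imat <- matrix(0, p, p); M <- matrix(0, p, p)
    for (ii in cl) {
      ni <- length(ii)
      Ai <- sqrt(v[ii])
      R <- matrix(alpha, ni, ni); diag(R) <- 1
      Vi <- outer(Ai, Ai) * R
      Di <- X[ii, , drop = FALSE] * v[ii]
      ViD <- solve(Vi, Di)
      ri <- y[ii] - mu[ii]
      U <- U + drop(crossprod(ViD, ri))
      Imat <- Imat + crossprod(Di, ViD)
      sc <- drop(crossprod(ViD, ri))
      M <- M + tcrossprod(sc)
    }
    step <- try(solve(Imat, U), silent = TRUE)
    if (inherits(step, "try-error")) { step <- rep(0, p); break }
    beta <- beta + step
    if (sum(abs(step)) < tol) break
  }
  separation <- any(abs(beta) > 15)
  vcov_model <- tryCatch(solve(Imat),
                         error = function(e) matrix(NA_real_, p, p))
  vcov_robust <- vcov_model %*% M %*% vcov_model
  list(beta = beta, vcov_model = vcov_model, vcov_robust = vcov_robust,
       alpha = alpha, converged = sum(abs(step)) < 1e-6 || it < maxit,
       separation = separation)
}

#' GEE logistic association of disease with a SNP
#'
#' Additive dosage coding; odds ratio and 95% CI per copy of the effect
#' allele.  `se_mode = "model_based"` mirrors the convention of reporting
#' model-based standard errors; `"robust"` uses the sandwich.
#' @inheritParams lmm_quant_assoc
#' @param disease 0/1 trait column.
#' @param se_mode `"model_based"` or `"robust"`.
#' @return `assoc_result` data.frame row with `or`, `ci_lo`, `ci_hi`.
#' @export
gee_logistic_assoc <- function(cohort, disease, snp,
                               covariates = c("age", "sex", "birth_year",
                                              "admixture"),
                               se_mode = c("model_based", "robust"),
                               effect_allele = NULL) {
  se_mode <- match.arg(se_mode)
  if (is.character(snp) && length(snp) == 1) {
    dos <- additive_dosage(cohort, snp, effect_allele)
    snp_name <- snp
  } else {
    dos <- snp; snp_name <- attr(snp, "snp_name") %||% "dosage"
  }
  df <- assoc_frame(cohort, disease, covariates, dos)
  ea <- attr(dos, "effect_allele") %||% NA_character_
  res <- data.frame(snp = snp_name, effect_allele = ea, coding = "additive",
                    beta = NA_real_, se = NA_real_, se_robust = NA_real_,
                    or = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                    p = NA_real_, n = nrow(df), se_mode = se_mode,
                    note = "", stringsAsFactors = FALSE)
  if (length(unique(df$y)) < 2) stop("outcome does not vary")
  if (length(unique(df$dosage)) < 2) {
    res$p <- 1; res$note <- "untestable: monomorphic"
    return(res)
  }
  form <- reformulate(c("dosage", covariates))
  X <- model.matrix(form, data = df)
  fit <- gee_logistic(df$y, X, df$family)
  j <- match("dosage", colnames(X))
  res$beta <- fit$beta[j]
  res$se <- sqrt(fit$vcov_model[j, j])
  res$se_robust <- sqrt(fit$vcov_robust[j, j])
  se <- if (se_mode == "model_based") res$se else res$se_robust
  res$or <- exp(res$beta)
  res$ci_lo <- exp(res$beta - 1.96 * se)
  res$ci_hi <- exp(res$beta + 1.96 * se)
  res$p <- 2 * pnorm(-abs(res$beta / se))
  if (fit$separation) res$note <- "possible separation: estimate unstable"
  attr(res, "fit") <- fit
  res
}

#' Individual admixture estimate (two-population MLE)
#'
#' Maximizes `sum_markers log P(genotype | p(m))` with
#' `p(m) = m p_A + (1-m) p_B` under HWE, solved on `[0, 1]`.
#' @param genos integer matrix (markers x 2) of allele-2 indicators
#'   (values 1/2, `NA` missing), or a vector of dosages 0/1/2.
#' @param pA,pB per-marker frequencies of allele 2 in populations A
#'   and B.
#' @return `m` in `[0,1]`, or `NA` if all genotypes are missing.
#' @export
admixture_estimate <- function(genos, pA, pB) {
  dos <- if (is.matrix(genos)) rowSums(genos == 2) else genos
  ok <- !is.na(dos)
  if (!any(ok)) return(NA_real_)
  dos <- dos[ok]; pAo <- pA[ok]; pBo <- pB[ok]
  nll <- function(m) {
    p <- m * pAo + (1 - m) * pBo
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(dos * log(p) + (2 - dos) * log(1 - p) +
           log(ifelse(dos == 1, 2, 1)))
  }
  # boundary-aware: compare interior optimum with the endpoints
  o <- optimize(nll, c(0, 1), tol = 1e-9)
  cand <- c(o$minimum, 0, 1)
  cand[which.min(vapply(cand, nll, numeric(1)))]
}

#' Forward step-wise conditional association
#'
#' At each step adds the SNP with the smallest conditional p-value
#' (mixed-model LRT given SNPs already selected); stops when the minimum
#' p-value reaches `alpha_enter`.
#' @inheritParams lmm_quant_assoc
#' @param snp_set candidate marker names.
#' @param alpha_enter entry threshold.
#' @return data.frame (`step`, `snp`, `p_conditional`) of selected SNPs.
#' @export
stepwise_conditional <- function(cohort, trait, snp_set,
                                 covariates = c("age", "sex"),
                                 alpha_enter = 0.05) {
  stopifnot(length(snp_set) >= 1)
  selected <- character()
  out <- data.frame(step = integer(), snp = character(),
                    p_conditional = numeric(), stringsAsFactors = FALSE)
  repeat {
    remaining <- setdiff(snp_set, selected)
    if (length(remaining) == 0) break
    ps <- vapply(remaining, function(s) {
      r <- conditional_lmm_p(cohort, trait, s, selected, covariates)
      r
    }, numeric(1))
    j <- which.min(ps)
    if (ps[j] >= alpha_enter) break
    selected <- c(selected, remaining[j])
    out <- rbind(out, data.frame(step = length(selected),
                                 snp = remaining[j], p_conditional = ps[j],
                                 stringsAsFactors = FALSE))
  }
  out
}

conditional_lmm_p <- function(cohort, trait, snp, given, covariates) {
  dn <- additive_dosage(cohort, snp)
  df <- assoc_frame(cohort, trait, covariates, dn)
  for (g in given) {
    dg <- additive_dosage(cohort, g)
    df[[paste0("g_", g)]] <- dg[df$id]
  }
  df <- df[complete.cases(df), , drop = FALSE]
  if (length(unique(df$dosage)) < 2) return(1)
  ctrl <- lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                            check.nobs.vs.nRE = "ignore",
                            calc.derivs = FALSE)
  base_terms <- c(covariates,
                  if (length(given)) paste0("g_", given) else character(0))
  f1 <- as.formula(paste("y ~ dosage +",
                         paste(c("1", base_terms), collapse = " + "),
                         "+ (1 | family)"))
  f0 <- as.formula(paste("y ~", paste(c("1", base_terms), collapse = " + "),
                         "+ (1 | family)"))
  full <- quiet_lmer(f1, data = df, REML = FALSE, control = ctrl)
  red <- quiet_lmer(f0, data = df, REML = FALSE, control = ctrl)
  lrt <- max(0, 2 * (as.numeric(logLik(full)) - as.numeric(logLik(red))))
  pchisq(lrt, df = 1, lower.tail = FALSE)
}

#' Region-wide single-variant scan
#'
#' Per-SNP association (mixed model for a quantitative trait, GEE
#' logistic for a 0/1 disease).  All SNPs appear in the table; the
#' `plot_keep` flag drops minor-allele frequency < `maf_min` from plots.
#' @inheritParams lmm_quant_assoc
#' @param outcome trait column; binary 0/1 columns are detected and sent
#'   to the GEE route.
#' @param snps marker names (default: all biallelic markers).
#' @param maf_min plot-inclusion threshold.
#' @param se_mode passed to [gee_logistic_assoc()].
#' @param bonferroni annotate `p_bonferroni = min(1, p * n_snps)`
#'   (nominal p-values remain the primary output).
#' @return data.frame, one row per SNP, with `cM`, `maf`, effect, `p`,
#'   `plot_keep`.
#' @export
region_scan <- function(cohort, outcome, snps = NULL,
                        covariates = c("age", "sex"), maf_min = 0.05,
                        se_mode = "model_based", bonferroni = FALSE) {
  if (is.null(snps))
    snps <- cohort$markers$name[vapply(cohort$markers$alleles, length,
                                       integer(1)) == 2]
  if (length(snps) == 0)
    return(data.frame(snp = character(), cM = numeric(), maf = numeric(),
                      beta = numeric(), p = numeric(),
                      plot_keep = logical(), stringsAsFactors = FALSE))
  yv <- cohort$traits[[outcome]]
  binary <- all(yv[!is.na(yv)] %in% c(0, 1))
  rows <- lapply(snps, function(s) {
    r <- if (binary)
      gee_logistic_assoc(cohort, outcome, s, covariates, se_mode = se_mode)
    else lmm_quant_assoc(cohort, outcome, s, covariates)
    r$maf <- snp_maf(cohort, s)
    r$cM <- cohort$markers$pos_cM[match(s, cohort$markers$name)]
    attr(r, "fit") <- NULL
    r
  })
  cols <- Reduce(union, lapply(rows, names))
  rows <- lapply(rows, function(r) { r[setdiff(cols, names(r))] <- NA; r[cols] })
  out <- do.call(rbind, rows)
  out$plot_keep <- !is.na(out$maf) & out$maf >= maf_min
  if (bonferroni) out$p_bonferroni <- pmin(1, out$p * length(snps))
  out[order(out$cM), , drop = FALSE]
}
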