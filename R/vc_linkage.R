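# Variance-components linkage for sibship data.  Per family the trait
# vector is multivariate normal with mean X beta and covariance
#   Omega = s2_q * Pi(c) + s2_g * 2Phi + s2_e * I,
# where Pi(c) holds the expected locus-specific sharing (HMM pihat for
# sib pairs, 0.5 for parent-offspring, 0 for spouses).  Fixed effects are
# profiled out by GLS; variances are optimized on the log scale by
# bounded quasi-Newton with random multi-starts because the likelihood is
# boundary-prone.  LOD = (loglik_linked - loglik_null) / ln 10, floored
# at zero; pointwise p-values use the 1/2 chi2_0 + 1/2 chi2_1 mixture.

LOG_SIG_LOWER <- -18

# assemble per-family (y, X, K, ids) for one quantitative trait
vc_family_data <- function(cohort, trait, covariates = c("age", "sex"),
                           ids = NULL) {
  tr <- cohort$traits
  if (is.null(tr)) stop("cohort has no trait table")
  if (!trait %in% names(tr)) stop("no trait column '", trait, "'")
  keep <- !is.na(tr[[trait]])
  for (cv in covariates) keep <- keep & !is.na(tr[[cv]])
  if (!is.null(ids)) keep <- keep & tr$id %in% ids
  tr <- tr[keep, , drop = FALSE]
  if (nrow(tr) == 0) stop("no phenotyped individuals for trait ", trait)
  ind <- cohort$individuals
  fam_of <- ind$family_id[match(tr$id, ind$id)]
  form <- if (length(covariates)) reformulate(covariates) else ~1
  X <- model.matrix(form, data = tr)
  fams <- list()
  for (fid in unique(fam_of)) {
    sel <- fam_of == fid
    mem <- tr$id[sel]
    fams[[fid]] <- list(ids = mem, y = tr[[trait]][sel],
                        X = X[sel, , drop = FALSE],
                        K = expected_kinship(mem, ind))
  }
  fams
}

vc_neg_loglik <- function(logsig, groups, linked) {
  sig <- if (linked) exp(logsig) else c(0, exp(logsig))
  -vc_loglik_uni_cpp(sig, groups)$loglik
}

# batch families sharing an identical (X, Pi, K) structure: one Cholesky
# per group, trait vectors as columns of Y
vc_group_uni <- function(fams, Pis) {
  keys <- vapply(seq_along(fams), function(i) {
    f <- fams[[i]]
    paste(length(f$y),
          paste(signif(as.vector(f$X), 10), collapse = ","),
          paste(signif(as.vector(Pis[[i]]), 10), collapse = ","),
          paste(signif(as.vector(f$K), 10), collapse = ","), sep = "|")
  }, character(1))
  unname(lapply(split(seq_along(fams), keys), function(ii) {
    n <- length(fams[[ii[1]]]$y)
    list(X = fams[[ii[1]]]$X, Pi = unname(Pis[[ii[1]]]),
         K = unname(fams[[ii[1]]]$K),
         Y = matrix(vapply(ii, function(j) fams[[j]]$y, numeric(n)), nrow = n))
  }))
}

vc_group_biv <- function(cfam) {
  keys <- vapply(cfam, function(f) paste(
    paste(f$idx1, collapse = " "), paste(f$idx2, collapse = " "),
    paste(signif(as.vector(f$X1), 10), collapse = ","),
    paste(signif(as.vector(f$X2), 10), collapse = ","),
    paste(signif(as.vector(f$Pi), 10), collapse = ","),
    paste(signif(as.vector(f$K), 10), collapse = ","), sep = "|"),
    character(1))
  unname(lapply(split(seq_along(cfam), keys), function(ii) {
    f0 <- cfam[[ii[1]]]
    n1 <- length(f0$y1); n2 <- length(f0$y2)
    list(Pi = unname(f0$Pi), K = unname(f0$K), idx1 = f0$idx1, idx2 = f0$idx2,
         X1 = f0$X1, X2 = f0$X2,
         Y1 = matrix(vapply(ii, function(j) cfam[[j]]$y1, numeric(n1)),
                     nrow = n1),
         Y2 = matrix(vapply(ii, function(j) cfam[[j]]$y2, numeric(n2)),
                     nrow = n2))
  }))
}

#' Fit a univariate variance-components model
#'
#' @param cohort a cohort with traits attached.
#' @param trait name of the quantitative trait column (use
#'   [age_adjusted_score()] first for a binary disease).
#' @param pihat named list (by family id) of locus-sharing matrices from
#'   [pihat_matrices()] or [true_ibd_pihat()]; `NULL` fits the polygenic
#'   null with `s2_q = 0`.
#' @param covariates trait-table columns entering the mean model.
#' @param ids restrict to these individuals.
#' @param n_starts random multi-starts for the bounded quasi-Newton
#'   optimizer.
#' @param fams precomputed `vc_family_data` (internal fast path).
#' @return A `vc_fit`: `sigma` (named `q`,`g`,`e`), `beta`, `loglik`,
#'   `n`, `converged`, `degenerate` flag.
#' @export
fit_vc_univariate <- function(cohort, trait, pihat = NULL,
                              covariates = c("age", "sex"), ids = NULL,
                              n_starts = 5, fams = NULL) {
  if (is.null(fams)) fams <- vc_family_data(cohort, trait, covariates, ids)
  linked <- !is.null(pihat)
  Pis <- lapply(names(fams), function(fid) {
    nm <- length(fams[[fid]]$ids)
    if (!linked) return(diag(1, nm))
    P <- pihat[[fid]]
    if (is.null(P)) stop("no pihat matrix for family ", fid)
    P[fams[[fid]]$ids, fams[[fid]]$ids, drop = FALSE]
  })
  degenerate <- FALSE
  if (linked) {
    dmax <- max(vapply(seq_along(fams), function(i)
      max(abs(Pis[[i]] - fams[[i]]$K)), numeric(1)))
    if (dmax < 1e-10) {
      degenerate <- TRUE
      warning("locus sharing identical to 2*kinship in every family: ",
              "s2_q and s2_g are jointly unidentifiable")
    }
  }
  groups <- vc_group_uni(fams, Pis)
  vy <- var(unlist(lapply(fams, `[[`, "y")))
  if (!is.finite(vy) || vy <= 0) vy <- 1
  npar <- if (linked) 3 else 2
  upper <- rep(log(20 * vy), npar)
  base <- log(rep(vy / npar, npar))
  starts <- list(base)
  if (n_starts > 1)
    for (s in seq_len(n_starts - 1))
      starts[[s + 1]] <- pmin(pmax(base + rnorm(npar, 0, 1.2),
                                   LOG_SIG_LOWER), upper)
  best <- NULL
  for (st in starts) {
    o <- try(optim(st, vc_neg_loglik, groups = groups, linked = linked,
                   method = "L-BFGS-B", lower = LOG_SIG_LOWER, upper = upper,
                   control = list(factr = 1e7, maxit = 200)), silent = TRUE)
    if (inherits(o, "try-error")) next
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best)) stop("variance-components optimization failed")
  sig <- if (linked) exp(best$par) else c(0, exp(best$par))
  sig[sig < 1.01 * exp(LOG_SIG_LOWER)] <- 0
  fin <- vc_loglik_uni_cpp(pmax(sig, c(0, 0, 1e-10)), groups)
  structure(list(sigma = setNames(sig, c("q", "g", "e")),
                 beta = as.vector(fin$beta),
                 beta_names = colnames(fams[[1]]$X),
                 loglik = fin$loglik, n = sum(lengths(lapply(fams, `[[`, "y"))),
                 linked = linked, converged = best$convergence == 0,
                 degenerate = degenerate, trait = trait),
            class = "vc_fit")
}

#' @export
print.vc_fit <- function(x, ...) {
  cat(sprintf("vc_fit (%s): s2_q=%.4g s2_g=%.4g s2_e=%.4g loglik=%.4f n=%d\n",
              if (x$linked) "linked" else "null", x$sigma["q"], x$sigma["g"],
              x$sigma["e"], x$loglik, x$n))
  invisible(x)
}

#' LOD score from nested fits
#' @param fit_linked,fit_null `vc_fit`s on the same data and fixed
#'   effects (the null has `s2_q = 0`).
#' @export
lod_score <- function(fit_linked, fit_null) {
  if (fit_linked$n != fit_null$n)
    stop("fits are not nested: different numbers of observations")
  max(0, (fit_linked$loglik - fit_null$loglik) / log(10))
}

#' Pointwise LOD p-value via the boundary mixture
#'
#' `p = 0.5 P(chi2_1 >= 2 ln(10) LOD)` (the `1/2 chi2_0 + 1/2 chi2_1`
#' mixture for one variance constrained at a boundary).
#' @param lod LOD score(s).
#' @export
lod_pvalue <- function(lod) {
  ifelse(lod <= 0, 1, 0.5 * pchisq(2 * log(10) * lod, df = 1,
                                   lower.tail = FALSE))
}

#' LOD curve along the IBD grid
#'
#' Refits the linked model at each position (warm-started from the
#' previous position); the polygenic null is shared.
#' @inheritParams fit_vc_univariate
#' @param surface an [ibd_surface()].
#' @param positions subset of the surface grid (default: whole grid).
#' @param n_starts multi-starts for the per-position refits.
#' @return A `lod_curve`: data.frame (`cM`, `lod`), `peak_cM`,
#'   `peak_lod`, the shared null fit.
#' @export
lod_curve <- function(cohort, trait, surface, covariates = c("age", "sex"),
                      ids = NULL, positions = NULL, n_starts = 2) {
  fams <- vc_family_data(cohort, trait, covariates, ids)
  null_fit <- fit_vc_univariate(cohort, trait, NULL, covariates, ids,
                                n_starts = 5, fams = fams)
  if (is.null(positions)) positions <- surface$grid
  all_ids <- unlist(lapply(fams, `[[`, "ids"), use.names = FALSE)
  lods <- numeric(length(positions))
  warm <- NULL
  for (i in seq_along(positions)) {
    Pi <- pihat_matrices(surface, cohort, positions[i], ids = all_ids)
    fit <- fit_vc_position(fams, Pi, null_fit, warm, n_starts)
    warm <- fit$logpar
    lods[i] <- max(0, (fit$loglik - null_fit$loglik) / log(10))
  }
  peak <- which.max(lods)
  structure(list(curve = data.frame(cM = positions, lod = lods),
                 peak_cM = positions[peak], peak_lod = lods[peak],
                 null_fit = null_fit, trait = trait),
            class = "lod_curve")
}

# linked refit at one position with warm starts
fit_vc_position <- function(fams, pihat, null_fit, warm = NULL, n_starts = 2) {
  Pis <- lapply(names(fams), function(fid)
    pihat[[fid]][fams[[fid]]$ids, fams[[fid]]$ids, drop = FALSE])
  groups <- vc_group_uni(fams, Pis)
  vg <- max(null_fit$sigma["g"], 1e-4)
  ve <- max(null_fit$sigma["e"], 1e-4)
  upper <- rep(log(20 * (vg + ve)), 3)
  starts <- list(log(c(max(vg / 2, 1e-4), vg / 2 + 1e-4, ve)))
  if (!is.null(warm)) starts <- c(list(warm), starts)
  if (n_starts > length(starts))
    for (s in seq_len(n_starts - length(starts)))
      starts[[length(starts) + 1]] <-
        pmin(pmax(starts[[1]] + rnorm(3, 0, 1), LOG_SIG_LOWER), upper)
  best <- NULL
  for (st in starts) {
    o <- try(optim(st, vc_neg_loglik, groups = groups, linked = TRUE,
                   method = "L-BFGS-B", lower = LOG_SIG_LOWER, upper = upper,
                   control = list(factr = 1e7, maxit = 200)), silent = TRUE)
    if (inherits(o, "try-error")) next
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best)) return(list(loglik = null_fit$loglik, logpar = warm))
  # a linked fit can never be worse than the null it nests
  if (-best$value < null_fit$loglik - 1e-6) {
    forced <- c(LOG_SIG_LOWER, log(pmax(null_fit$sigma[c("g", "e")], 1e-8)))
    v <- vc_neg_loglik(forced, groups, linked = TRUE)
    if (v < best$value) best <- list(par = forced, value = v)
  }
  list(loglik = -best$value, logpar = best$par)
}

#' @export
print.lod_curve <- function(x, ...) {
  cat(sprintf("lod_curve (%s): peak LOD %.3f at %.1f cM over %d positions\n",
              x$trait, x$peak_lod, x$peak_cM, nrow(x$curve)))
  invisible(x)
}

#' Age-adjusted disease score
#'
#' Estimates the cumulative incidence `F(a)` of onset by Kaplan-Meier
#' (onset ages, censored at last exam) and scores each individual as
#' `D_i - F(a_i)` with `a_i` the onset age if affected, otherwise the age
#' at last exam.  The score is analyzed downstream as a quantitative
#' trait.
#' @param trait_table data.frame with `affected`, `age_onset`,
#'   `age_last_exam` (and `sex` if `sex_strata`).
#' @param sex_strata estimate `F` separately by sex.
#' @return Numeric score per row (`NA` where ages are missing).
#' @export
age_adjusted_score <- function(trait_table, sex_strata = FALSE) {
  tt <- trait_table
  stopifnot(all(c("affected", "age_last_exam") %in% names(tt)))
  if (!"age_onset" %in% names(tt)) tt$age_onset <- NA_real_
  time <- ifelse(tt$affected == 1 & !is.na(tt$age_onset),
                 tt$age_onset, tt$age_last_exam)
  ok <- !is.na(time) & !is.na(tt$affected)
  if (all(tt$affected[ok] == 1) || all(tt$affected[ok] == 0))
    warning("all individuals have the same affection status; ",
            "age-adjusted scores are degenerate")
  score <- rep(NA_real_, nrow(tt))
  strata <- if (sex_strata) tt$sex else rep("all", nrow(tt))
  for (st in unique(strata[ok])) {
    sel <- ok & strata == st
    sf <- survival::survfit(
      survival::Surv(time[sel], tt$affected[sel]) ~ 1)
    Fhat <- stats::stepfun(sf$time, c(0, 1 - sf$surv))
    score[sel] <- tt$affected[sel] - Fhat(time[sel])
  }
  score
}

# ---- bivariate covariance-components model ----

biv_family_data <- function(cohort, trait1, trait2, covariates, ids = NULL) {
  tr <- cohort$traits
  ind <- cohort$individuals
  ok_cov <- rep(TRUE, nrow(tr))
  if (!is.null(ids)) ok_cov <- ok_cov & tr$id %in% ids
  for (cv in covariates) ok_cov <- ok_cov & !is.na(tr[[cv]])
  tr <- tr[ok_cov, , drop = FALSE]
  k1 <- !is.na(tr[[trait1]])
  k2 <- !is.na(tr[[trait2]])
  form <- if (length(covariates)) reformulate(covariates) else ~1
  fam_of <- ind$family_id[match(tr$id, ind$id)]
  Xall <- model.matrix(form, data = tr)  # global: stable factor contrasts
  fams <- list()
  for (fid in unique(fam_of[k1 | k2])) {
    sel <- which(fam_of == fid & (k1 | k2))
    mem <- tr$id[sel]
    K <- expected_kinship(mem, ind)
    s1 <- which(k1[sel])
    s2 <- which(k2[sel])
    fams[[fid]] <- list(
      ids = mem, K = K, idx1 = as.integer(s1), idx2 = as.integer(s2),
      X1 = Xall[sel[s1], , drop = FALSE], X2 = Xall[sel[s2], , drop = FALSE],
      y1 = tr[[trait1]][sel[s1]], y2 = tr[[trait2]][sel[s2]])
  }
  fams
}

biv_par_expand <- function(th, fix_rho_q, equal_sq) {
  # th layout: log s2 (5 or 6) then free correlations
  if (equal_sq) {
    sig <- exp(th[1:5])
    sig <- c(sig[1], sig[2], sig[3], sig[1], sig[4], sig[5])
    rest <- th[-(1:5)]
  } else {
    sig <- exp(th[1:6])
    rest <- th[-(1:6)]
  }
  if (is.null(fix_rho_q)) {
    rho <- c(rest[1], rest[2], rest[3])
  } else {
    rho <- c(fix_rho_q, rest[1], rest[2])
  }
  c(sig, rho)
}

#' Fit a bivariate covariance-components linkage model
#'
#' Stacks two quantitative traits per family with cross-trait covariance
#' `rho_q s_q1 s_q2 Pi + rho_g s_g1 s_g2 2Phi + rho_e s_e1 s_e2` (same
#' individual).  With `tests = TRUE`, also fits `rho_q = 0` and
#' `rho_q = -1` and reports LRT p-values (the `-1` test is a boundary and
#' uses the half-mixture).
#'
#' @param cohort a cohort (trait2 may be an [age_adjusted_score()]
#'   column).
#' @param trait1,trait2 trait column names.
#' @param pihat locus-sharing matrices (as in [fit_vc_univariate()]).
#' @param covariates mean-model columns shared by both traits.
#' @param fix_rho_q constrain the locus correlation (used internally).
#' @param equal_sq constrain `s2_q1 = s2_q2` (linked-variance partition).
#' @param n_starts optimizer multi-starts.
#' @param tests compute the `rho_q = 0` and `rho_q = -1` LRTs.
#' @param fams precomputed family data (internal).
#' @return A `vc_biv_fit` with `sigma1`, `sigma2`, `rho` (named `q`, `g`,
#'   `e`), `loglik`, and when `tests` the p-values `p_rho0`, `p_rhom1`.
#' @export
fit_vc_bivariate <- function(cohort, trait1, trait2, pihat,
                             covariates = c("age", "sex"),
                             fix_rho_q = NULL, equal_sq = FALSE,
                             n_starts = 3, tests = FALSE, fams = NULL,
                             extra_starts = list(), ids = NULL) {
  if (is.null(fams))
    fams <- biv_family_data(cohort, trait1, trait2, covariates, ids)
  cfam <- lapply(names(fams), function(fid) {
    f <- fams[[fid]]
    P <- if (is.null(pihat)) f$Pi else pihat[[fid]]
    if (is.null(P)) stop("no pihat matrix for family ", fid)
    c(f[c("idx1", "idx2", "X1", "X2", "y1", "y2", "K")],
      list(Pi = P[f$ids, f$ids, drop = FALSE]))
  })
  groups <- vc_group_biv(cfam)
  v1 <- var(unlist(lapply(fams, `[[`, "y1"))); if (!is.finite(v1) || v1 <= 0) v1 <- 1
  v2 <- var(unlist(lapply(fams, `[[`, "y2"))); if (!is.finite(v2) || v2 <= 0) v2 <- 1
  nsig <- if (equal_sq) 5 else 6
  nrho <- if (is.null(fix_rho_q)) 3 else 2
  base_sig <- if (equal_sq)
    log(c(sqrt(v1 * v2) / 3, v1 / 3, v1 / 3, v2 / 3, v2 / 3))
  else log(c(v1 / 3, v1 / 3, v1 / 3, v2 / 3, v2 / 3, v2 / 3))
  base <- c(base_sig, rep(0, nrho))
  lower <- c(rep(LOG_SIG_LOWER, nsig),
             if (is.null(fix_rho_q)) c(-1, -1, -0.99) else c(-1, -0.99))
  upper <- c(rep(log(20 * max(v1, v2)), nsig),
             if (is.null(fix_rho_q)) c(1, 1, 0.99) else c(1, 0.99))
  nll <- function(th) {
    par <- biv_par_expand(th, fix_rho_q, equal_sq)
    r <- vc_loglik_biv_cpp(par, groups)
    if (!is.finite(r$loglik)) return(1e10)
    -r$loglik
  }
  starts <- list(base)
  if (n_starts > 1)
    for (s in seq_len(n_starts - 1)) {
      st <- base
      st[1:nsig] <- st[1:nsig] + rnorm(nsig, 0, 1)
      st[(nsig + 1):length(st)] <- runif(nrho, -0.6, 0.6)
      starts[[s + 1]] <- pmin(pmax(st, lower + 1e-9), upper - 1e-9)
    }
  if (length(extra_starts))
    starts <- c(lapply(extra_starts, function(st)
      pmin(pmax(st, lower + 1e-9), upper - 1e-9)), starts)
  best <- NULL
  for (st in starts) {
    o <- try(optim(st, nll, method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(factr = 1e7, maxit = 300)), silent = TRUE)
    if (inherits(o, "try-error")) next
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best)) stop("bivariate optimization failed")
  par <- biv_par_expand(best$par, fix_rho_q, equal_sq)
  fin <- vc_loglik_biv_cpp(par, groups)
  fit <- structure(list(
    sigma1 = setNames(par[1:3], c("q", "g", "e")),
    sigma2 = setNames(par[4:6], c("q", "g", "e")),
    rho = setNames(par[7:9], c("q", "g", "e")),
    beta = as.vector(fin$beta), loglik = fin$loglik,
    n = sum(vapply(cfam, function(f) length(f$y1) + length(f$y2), numeric(1))),
    converged = best$convergence == 0,
    equal_sq = equal_sq, fix_rho_q = fix_rho_q), class = "vc_biv_fit")
  if (tests) {
    warm <- c(best$par[1:6], best$par[8:9])  # free solution, rho_q dropped
    f0 <- fit_vc_bivariate(cohort, trait1, trait2, pihat, covariates,
                           fix_rho_q = 0, n_starts = n_starts, fams = fams,
                           extra_starts = list(warm))
    fm1 <- fit_vc_bivariate(cohort, trait1, trait2, pihat, covariates,
                            fix_rho_q = -1, n_starts = n_starts, fams = fams,
                            extra_starts = list(warm))
    d0 <- max(0, 2 * (fit$loglik - f0$loglik))
    dm1 <- max(0, 2 * (fit$loglik - fm1$loglik))
    fit$p_rho0 <- pchisq(d0, df = 1, lower.tail = FALSE)
    # rho_q = -1 sits on the parameter boundary: half-mixture
    fit$p_rhom1 <- if (dm1 <= 0) 1 else
      0.5 * pchisq(dm1, df = 1, lower.tail = FALSE)
    fit$fit_rho0 <- f0; fit$fit_rhom1 <- fm1
  }
  fit
}

#' @export
print.vc_biv_fit <- function(x, ...) {
  cat(sprintf(paste0("vc_biv_fit: rho_q=%.3f rho_g=%.3f rho_e=%.3f ",
                     "loglik=%.3f n=%d\n"),
              x$rho["q"], x$rho["g"], x$rho["e"], x$loglik, x$n))
  if (!is.null(x$p_rho0))
    cat(sprintf("  LRT p (rho_q=0): %.4g; p (rho_q=-1, boundary): %.4g\n",
                x$p_rho0, x$p_rhom1))
  invisible(x)
}
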