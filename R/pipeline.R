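# Configuration-driven end-to-end runs: simulate (or load) a cohort,
# then reproduce the full analysis surface in order: association scans,
# linkage curves for the trait and the age-adjusted disease score with
# the bivariate locus-correlation test, LD/blocks/tags, the
# genotype-partition table with adjusted linkage, GEE odds-ratio table
# by stratum, and the haplotype report.  All randomness flows through
# one seed, recorded in every output header.

#' Pipeline run configuration
#'
#' @param sim a [sim_config()] (default [default_paper_config()]), or
#'   `NULL` when `ped`/`map`/`traits` paths are given.
#' @param ped,map,traits input file paths (used when `sim` is `NULL`).
#' @param trait,disease trait-table column names.
#' @param cluster_snps the designated tag/QTL cluster.
#' @param ld_snps SNPs for the LD stage (default: all SNPs within
#'   `ld_window` cM of the cluster).
#' @param ld_window half-width in cM.
#' @param stages named logical toggles: `scan`, `linkage`, `ld`,
#'   `partition`, `haplotype`.
#' @param maf_min,tag_r2,hap_freq_min,alpha_enter thresholds.
#' @param lod_step spacing (cM) of LOD-curve evaluations (the IBD grid
#'   itself is markers + 1 cM).
#' @param seed integer seed for the whole run.
#' @export
run_config <- function(sim = NULL, ped = NULL, map = NULL, traits = NULL,
                       trait = "trait", disease = "affected",
                       cluster_snps = paste0("T", 1:4),
                       ld_snps = NULL, ld_window = 1.5,
                       stages = list(scan = TRUE, linkage = TRUE, ld = TRUE,
                                     partition = TRUE, haplotype = TRUE),
                       maf_min = 0.05, tag_r2 = 0.8, hap_freq_min = 0.05,
                       alpha_enter = 0.05, lod_step = 2, seed = 1L) {
  for (th in c(maf_min, tag_r2, hap_freq_min, alpha_enter))
    if (th <= 0 || th >= 1) stop("thresholds must lie in (0, 1)")
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#' Load a run configuration from JSON
#' @param path JSON file with [run_config()] fields (the `sim` entry,
#'   when present, holds [sim_config()] arguments).
#' @export
read_run_config <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(js$sim)) js$sim <- do.call(sim_config, as.list(js$sim))
  if (!is.null(js$stages)) js$stages <- as.list(js$stages)
  do.call(run_config, js[intersect(names(js), names(formals(run_config)))])
}

write_tsv_seeded <- function(df, path, seed) {
  con <- file(path, "w")
  writeLines(sprintf("# famlink seed=%d", seed), con)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  close(con)
  path
}

try_png <- function(path, expr, width = 900, height = 500) {
  ok <- try({
    grDevices::png(path, width = width, height = height, type = "cairo")
    on.exit(grDevices::dev.off(), add = TRUE)
    force(expr)
    TRUE
  }, silent = TRUE)
  if (inherits(ok, "try-error")) NULL else path
}

#' Run the full analysis pipeline
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created).
#' @param seed overrides `config$seed` when given.
#' @return Invisibly, the manifest list (`artifacts`, `seed`,
#'   `thresholds`, `completed`); also written as `manifest.json`.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- character()
  completed <- character()
  sd <- config$seed
  log_msg <- function(...) message("[famlink] ", sprintf(...))

  # ---- cohort ----
  if (!is.null(config$sim)) {
    cfg <- config$sim
    cfg$seed <- sd
    cohort <- simulate_cohort(cfg)
  } else {
    cohort <- read_ped_map(config$ped, config$map)
    cohort <- read_traits(config$traits, cohort)
  }
  set.seed(sd + 1L)  # analysis-stage randomness (optimizer restarts)
  tr_col <- config$trait; dz_col <- config$disease
  st_col <- cohort$traits$stratum
  linkage_ids <- if (is.null(st_col)) cohort$traits$id
                 else cohort$traits$id[is.na(st_col) | st_col == "linkage"]
  snps_all <- cohort$markers$name[vapply(cohort$markers$alleles, length,
                                         integer(1)) == 2]
  cpos <- cohort$markers$pos_cM[match(config$cluster_snps,
                                      cohort$markers$name)]
  ld_snps <- config$ld_snps
  if (is.null(ld_snps) && length(cpos) && !anyNA(cpos)) {
    lo <- min(cpos) - config$ld_window; hi <- max(cpos) + config$ld_window
    pos <- cohort$markers$pos_cM[match(snps_all, cohort$markers$name)]
    ld_snps <- snps_all[pos >= lo & pos <= hi]
  }
  emit <- function(df, name) {
    artifacts <<- c(artifacts, write_tsv_seeded(df, file.path(out_dir, name), sd))
  }

  # ---- association scans ----
  if (isTRUE(config$stages$scan)) {
    log_msg("association scan (%d SNPs)", length(snps_all))
    sc_t <- region_scan(cohort, tr_col, snps_all, c("age", "sex"),
                        maf_min = config$maf_min)
    emit(sc_t, "scan_trait.tsv")
    sc_d <- region_scan(cohort, dz_col, snps_all,
                        c("age", "sex", "birth_year", "admixture"),
                        maf_min = config$maf_min)
    emit(sc_d, "scan_disease.tsv")
    try_png(file.path(out_dir, "scan_trait.png"),
            plot_scan(sc_t, main = "association scan: quantitative trait"))
    try_png(file.path(out_dir, "scan_disease.png"),
            plot_scan(sc_d, main = "association scan: disease"))
    completed <- c(completed, "scan")
  }

  # ---- linkage ----
  surface <- NULL; peak <- NULL
  if (isTRUE(config$stages$linkage) || isTRUE(config$stages$partition)) {
    log_msg("multipoint IBD")
    fams_all <- nuclear_families(cohort)
    core <- fams_all[vapply(fams_all, function(f)
      any(c(f$parents, f$sibs) %in% linkage_ids), logical(1))]
    surface <- ibd_surface(cohort, families = core)
    lpos <- sort(unique(c(
      cohort$markers$pos_cM,
      seq(min(surface$grid), max(surface$grid), by = config$lod_step))))
    lpos <- lpos[vapply(lpos, function(p)
      any(abs(surface$grid - p) < 1e-8), logical(1))]
    log_msg("LOD curve: trait")
    lc_t <- lod_curve(cohort, tr_col, surface, ids = linkage_ids,
                      positions = lpos)
    peak <- lc_t$peak_cM
    cohort$traits$dscore <- age_adjusted_score(cohort$traits)
    if (isTRUE(config$stages$linkage)) {
      log_msg("LOD curve: age-adjusted disease score")
      lc_d <- lod_curve(cohort, "dscore", surface, ids = linkage_ids,
                        positions = lpos)
      emit(data.frame(cM = lc_t$curve$cM, lod_trait = lc_t$curve$lod,
                      lod_disease_score = lc_d$curve$lod), "lod_curves.tsv")
      try_png(file.path(out_dir, "lod_curves.png"), {
        plot_lod_curve(lc_t, col = "black",
                       main = "multipoint linkage")
        graphics::lines(lc_d$curve$cM, lc_d$curve$lod, col = "grey50", lty = 2)
        graphics::legend("topleft", c(tr_col, "age-adjusted disease score"),
                         col = c("black", "grey50"), lty = c(1, 2), bty = "n")
      })
      log_msg("bivariate fit at %.1f cM", peak)
      pih <- pihat_matrices(surface, cohort, peak, ids = linkage_ids)
      biv <- fit_vc_bivariate(cohort, tr_col, "dscore", pih, tests = TRUE,
                              ids = linkage_ids)
      emit(data.frame(position_cM = peak,
                      rho_q = biv$rho["q"], rho_g = biv$rho["g"],
                      rho_e = biv$rho["e"], loglik = biv$loglik,
                      p_rho_q_eq_0 = biv$p_rho0,
                      p_rho_q_eq_m1 = biv$p_rhom1,
                      lod_trait_peak = lc_t$peak_lod,
                      lod_dscore_peak = lc_d$peak_lod), "bivariate.tsv")
      completed <- c(completed, "linkage")
    }
  }

  # ---- LD / blocks / tags ----
  tags <- config$cluster_snps
  if (isTRUE(config$stages$ld) && length(ld_snps) >= 2) {
    log_msg("LD stage (%d SNPs)", length(ld_snps))
    ld <- ld_matrix(cohort, ld_snps)
    emit(ld, "ld_pairs.tsv")
    mafs <- setNames(vapply(ld_snps, function(s) snp_maf(cohort, s),
                            numeric(1)), ld_snps)
    blocks <- gabriel_blocks(ld, ld_snps, mafs, config$maf_min)
    emit(data.frame(block = rep(seq_along(blocks),
                                vapply(blocks, length, integer(1))),
                    snp = unlist(blocks)), "blocks.tsv")
    r2m <- matrix(0, length(ld_snps), length(ld_snps),
                  dimnames = list(ld_snps, ld_snps))
    diag(r2m) <- 1
    for (r in seq_len(nrow(ld))) {
      r2m[ld$snp_a[r], ld$snp_b[r]] <- r2m[ld$snp_b[r], ld$snp_a[r]] <- ld$r2[r]
    }
    keep <- names(mafs)[mafs >= config$maf_min]
    tg <- select_tags(r2m[keep, keep, drop = FALSE], config$tag_r2,
                      positions = setNames(
                        cohort$markers$pos_cM[match(keep, cohort$markers$name)],
                        keep))
    emit(data.frame(tag = rep(tg$tags, vapply(tg$capture, length, integer(1))),
                    captured = unlist(tg$capture)), "tags.tsv")
    try_png(file.path(out_dir, "ld_triangle.png"),
            plot_ld_triangle(ld, ld_snps), width = 700, height = 700)
    completed <- c(completed, "ld")
  }

  # ---- partition (genotype-class table + adjusted linkage) ----
  if (isTRUE(config$stages$partition) && !is.null(surface)) {
    log_msg("linked-variance partition at peak %.1f cM", peak)
    co_l <- cohort
    co_l$traits[[tr_col]][!(co_l$traits$id %in% linkage_ids)] <- NA
    t1 <- partition_table(co_l, tr_col, tags, surface, peak)
    emit(t1, "table1.tsv")
    gr <- genotype_residuals(co_l, tr_col, tags)
    co_l$traits$.adj <- gr$residuals[co_l$traits$id]
    lc_a <- lod_curve(co_l, ".adj", surface, covariates = character(),
                      positions = lpos)
    emit(data.frame(cM = lc_a$curve$cM, lod_adjusted = lc_a$curve$lod),
         "adjusted_linkage.tsv")
    try_png(file.path(out_dir, "adjusted_linkage.png"),
            plot_lod_curve(lc_a, main = "linkage adjusted for cluster SNPs"))
    completed <- c(completed, "partition")
  }

  # ---- stratified odds-ratio table ----
  if (isTRUE(config$stages$scan)) {
    strata <- unique(cohort$traits$stratum)
    strata <- strata[!is.na(strata)]
    rows <- list()
    for (s in tags) {
      for (st in c(strata, "combined")) {
        ids <- if (st == "combined") cohort$traits$id
               else cohort$traits$id[cohort$traits$stratum == st]
        co_s <- cohort
        co_s$traits <- co_s$traits[co_s$traits$id %in% ids, , drop = FALSE]
        r <- try(gee_logistic_assoc(co_s, dz_col, s,
                                    c("age", "sex", "birth_year", "admixture")),
                 silent = TRUE)
        if (inherits(r, "try-error")) next
        attr(r, "fit") <- NULL
        r$stratum <- st
        rows[[length(rows) + 1]] <- r
      }
    }
    if (length(rows)) emit(do.call(rbind, rows), "table2.tsv")
  }

  # ---- haplotypes ----
  if (isTRUE(config$stages$haplotype)) {
    log_msg("haplotype stage")
    fh <- family_haplotype_dosage(cohort, tags)
    ha_t <- haplotype_assoc(cohort, tr_col, fh$dosage, fh$freqs,
                            min_freq = config$hap_freq_min)
    ha_d <- haplotype_assoc(cohort, dz_col, fh$dosage, fh$freqs,
                            covariates = c("age", "sex", "birth_year",
                                           "admixture"),
                            min_freq = config$hap_freq_min,
                            order_by = tr_col)
    emit(rbind(cbind(outcome = tr_col, ha_t$per_hap[
                       intersect(names(ha_t$per_hap), names(ha_d$per_hap))],
                     stringsAsFactors = FALSE),
               cbind(outcome = dz_col, ha_d$per_hap[
                       intersect(names(ha_t$per_hap), names(ha_d$per_hap))],
                     stringsAsFactors = FALSE)), "haplotypes.tsv")
    combos <- ha_d$combos
    combos$p_trend <- ha_d$p_trend
    emit(combos, "haplotype_combos.tsv")
    completed <- c(completed, "haplotype")
  }

  manifest <- list(package = "famlink",
                   version = as.character(utils::packageVersion("famlink")),
                   seed = sd,
                   thresholds = list(maf_min = config$maf_min,
                                     tag_r2 = config$tag_r2,
                                     hap_freq_min = config$hap_freq_min,
                                     alpha_enter = config$alpha_enter),
                   stages_requested = names(Filter(isTRUE, config$stages)),
                   completed = completed,
                   artifacts = basename(artifacts))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

# ---- plotting helpers (base graphics) ----

#' Manhattan-style association scan plot
#' @param scan output of [region_scan()].
#' @param main title.
#' @export
plot_scan <- function(scan, main = "association scan") {
  sc <- scan[scan$plot_keep & !is.na(scan$p), , drop = FALSE]
  graphics::plot(sc$cM, -log10(pmax(sc$p, 1e-300)), pch = 19, cex = 0.6,
                 xlab = "position (cM)", ylab = expression(-log[10](p)),
                 main = main)
  graphics::abline(h = -log10(1e-3), lty = 3, col = "grey60")
  invisible(NULL)
}

#' LOD curve plot
#' @param curve a [lod_curve()].
#' @param ... passed to `plot`.
#' @export
plot_lod_curve <- function(curve, ...) {
  graphics::plot(curve$curve$cM, curve$curve$lod, type = "l",
                 xlab = "position (cM, from p-terminus)", ylab = "LOD", ...)
  graphics::abline(v = curve$peak_cM, lty = 3, col = "grey60")
  invisible(NULL)
}

#' LD triangle plot (r2 shading, D' printed)
#' @param ld output of [ld_matrix()].
#' @param snps SNP names in map order.
#' @export
plot_ld_triangle <- function(ld, snps) {
  ns <- length(snps)
  graphics::plot(NULL, xlim = c(0, ns), ylim = c(0, ns), axes = FALSE,
                 xlab = "", ylab = "", main = "pairwise LD (r2)")
  for (r in seq_len(nrow(ld))) {
    i <- match(ld$snp_a[r], snps); j <- match(ld$snp_b[r], snps)
    graphics::rect(j - 1, ns - i, j, ns - i + 1,
                   col = grDevices::grey(1 - ld$r2[r]), border = "white")
  }
  graphics::text(seq_len(ns) - 0.5, ns + 0.2, snps, srt = 90, cex = 0.5,
                 xpd = NA)
  invisible(NULL)
}
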