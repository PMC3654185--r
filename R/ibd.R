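# Multipoint IBD for nuclear families: a hidden Markov model over
# inheritance vectors (two meiosis bits per sib).  Between adjacent map
# positions each bit flips independently with the Haldane recombination
# fraction, which is the no-interference assumption that makes the chain
# Markov.  Emissions use parental genotypes when available and otherwise
# integrate over ordered founder genotypes under HWE with founder allele
# frequencies.  Markers that are Mendelian-inconsistent for a family are
# dropped for that family with a warning.

#' Haldane map function
#'
#' @param d_cM genetic distance(s) in centimorgans, nonnegative.
#' @return Recombination fraction(s) `theta = (1 - exp(-2 d / 100)) / 2`.
#' @export
haldane_theta <- function(d_cM) {
  if (any(d_cM < 0)) stop("negative map distance")
  0.5 * (1 - exp(-2 * d_cM / 100))
}

#' Default evaluation grid: marker positions plus 1-cM steps between
#' @param markers a cohort's marker table.
#' @param step step size in cM.
#' @export
default_grid <- function(markers, step = 1) {
  pos <- markers$pos_cM
  sort(unique(c(pos, seq(min(pos), max(pos), by = step))))
}

#' Expected genetic relationship matrix (2 x kinship) for one family
#'
#' Diagonal 1, sib-sib and parent-offspring 0.5, founder pairs 0.
#' @param family element of [nuclear_families()], or character ids with
#'   `individuals` supplied.
#' @param individuals pedigree table (needed when `family` is ids).
#' @export
expected_kinship <- function(family, individuals = NULL) {
  ids <- if (is.list(family)) c(family$parents, family$sibs) else family
  n <- length(ids)
  K <- diag(1, n); rownames(K) <- colnames(K) <- ids
  if (is.list(family)) {
    sibs <- family$sibs; parents <- family$parents
    for (a in seq_len(n)) for (b in seq_len(n)) {
      if (a >= b) next
      both_sib <- ids[a] %in% sibs && ids[b] %in% sibs
      po <- xor(ids[a] %in% sibs, ids[b] %in% sibs)
      K[a, b] <- K[b, a] <- if (both_sib || po) 0.5 else 0
    }
  } else {
    stopifnot(!is.null(individuals))
    ii <- match(ids, individuals$id)
    for (a in seq_len(n)) for (b in seq_len(n)) {
      if (a >= b) next
      K[a, b] <- K[b, a] <- switch(relationship(individuals, ii[a], ii[b]),
                                   sib = 0.5, parent_offspring = 0.5, 0)
    }
  }
  K
}

#' Multipoint IBD surface for one nuclear family
#'
#' @param family element of [nuclear_families()].
#' @param cohort the cohort supplying genotypes, map and founder allele
#'   frequencies.
#' @param grid_cM evaluation positions (default [default_grid()]).
#' @param freqs optional list of per-marker allele frequencies (default:
#'   [allele_freqs_from_founders()] per marker).
#' @param max_sibs refuse larger sibships (state space is `4^sibs`).
#' @return List with `pairs` (sib id pairs), `grid`, matrices `p0`, `p1`,
#'   `p2`, `pihat` (pairs x grid) and `excluded` marker flags.
#' @export
multipoint_ibd <- function(family, cohort, grid_cM = NULL, freqs = NULL,
                           max_sibs = 8) {
  sibs <- family$sibs
  if (length(sibs) < 1) stop("family has no sibs")
  if (length(sibs) > max_sibs)
    stop("family ", family$family_id, " has ", length(sibs),
         " sibs (max_sibs = ", max_sibs, ")")
  mk <- cohort$markers
  if (is.null(grid_cM)) grid_cM <- default_grid(mk)
  m <- nrow(mk)
  if (is.null(freqs))
    freqs <- lapply(seq_len(m), function(k)
      suppressWarnings(allele_freqs_from_founders(cohort, k)))
  ii <- match(sibs, cohort$individuals$id)
  sib_gt <- matrix(0L, length(sibs), 2 * m)
  sib_gt[, seq(1, 2 * m, by = 2)] <- cohort$geno_a1[ii, , drop = FALSE]
  sib_gt[, seq(2, 2 * m, by = 2)] <- cohort$geno_a2[ii, , drop = FALSE]
  pg <- function(pid) {
    out <- integer(2 * m)
    if (!is.na(pid) && pid %in% cohort$individuals$id) {
      j <- match(pid, cohort$individuals$id)
      out[seq(1, 2 * m, by = 2)] <- cohort$geno_a1[j, ]
      out[seq(2, 2 * m, by = 2)] <- cohort$geno_a2[j, ]
      # half-missing genotypes are treated as missing
      for (k in seq_len(m))
        if (out[2 * k - 1] == 0L || out[2 * k] == 0L)
          out[c(2 * k - 1, 2 * k)] <- 0L
    }
    out
  }
  ind <- cohort$individuals
  kid1 <- match(sibs[1], ind$id)
  res <- hmm_ibd_family(sib_gt, pg(ind$father_id[kid1]), pg(ind$mother_id[kid1]),
                        unname(freqs), mk$pos_cM, grid_cM)
  if (any(res$excluded))
    warning("family ", family$family_id, ": ", sum(res$excluded),
            " Mendelian-inconsistent marker(s) excluded (",
            paste(mk$name[res$excluded], collapse = ", "), ")")
  pair_ids <- cbind(sibs[res$pairs[, 1]], sibs[res$pairs[, 2]])
  structure(list(family_id = family$family_id, pairs = pair_ids,
                 grid = grid_cM, p0 = res$p0, p1 = res$p1, p2 = res$p2,
                 pihat = 0.5 * res$p1 + res$p2, excluded = res$excluded),
            class = "ibd_family")
}

#' Multipoint IBD surface for a whole cohort
#'
#' @inheritParams multipoint_ibd
#' @param cohort a cohort.
#' @param families optional subset of [nuclear_families()].
#' @return An `ibd_surface`: list of per-family results plus the shared
#'   grid.
#' @export
ibd_surface <- function(cohort, grid_cM = NULL, families = NULL, max_sibs = 8) {
  if (is.null(grid_cM)) grid_cM <- default_grid(cohort$markers)
  if (is.null(families)) families <- nuclear_families(cohort)
  freqs <- lapply(seq_len(nrow(cohort$markers)), function(k)
    suppressWarnings(allele_freqs_from_founders(cohort, k)))
  fams <- list()
  for (fam in families) {
    if (length(fam$sibs) < 2 || length(fam$sibs) > max_sibs) next
    fams[[fam$family_id]] <- multipoint_ibd(fam, cohort, grid_cM, freqs,
                                            max_sibs = max_sibs)
  }
  structure(list(families = fams, grid = grid_cM), class = "ibd_surface")
}

#' @export
print.ibd_surface <- function(x, ...) {
  cat(sprintf("ibd_surface: %d families, %d grid positions (%g-%g cM)\n",
              length(x$families), length(x$grid), min(x$grid), max(x$grid)))
  invisible(x)
}

#' Locus-sharing matrices at one position from an IBD surface
#'
#' Returns, per family, the expected-sharing matrix over `ids`: diagonal
#' 1, sib pairs the HMM posterior pihat, parent-offspring 0.5 (exact),
#' spouse pairs 0.  Used as the `Pi` weight of the linked-locus variance
#' component.
#' @param surface an [ibd_surface()].
#' @param cohort the cohort.
#' @param position cM position (must lie on the surface grid).
#' @param ids individuals to cover (default: all).
#' @export
pihat_matrices <- function(surface, cohort, position, ids = NULL) {
  g <- which(abs(surface$grid - position) < 1e-8)
  if (length(g) != 1) stop("position ", position, " is not on the IBD grid")
  ind <- cohort$individuals
  if (is.null(ids)) ids <- ind$id
  out <- list()
  for (fid in unique(ind$family_id[ind$id %in% ids])) {
    mem <- ids[ids %in% ind$id[ind$family_id == fid]]
    nm <- length(mem)
    P <- diag(1, nm); rownames(P) <- colnames(P) <- mem
    fam <- surface$families[[fid]]
    ii <- match(mem, ind$id)
    for (a in seq_len(nm)) for (b in seq_len(nm)) {
      if (a >= b) next
      rel <- relationship(ind, ii[a], ii[b])
      val <- switch(rel, parent_offspring = 0.5, unrelated = 0, sib = {
        if (is.null(fam)) 0.5 else {
          q <- which((fam$pairs[, 1] == mem[a] & fam$pairs[, 2] == mem[b]) |
                     (fam$pairs[, 1] == mem[b] & fam$pairs[, 2] == mem[a]))
          if (length(q) == 1) fam$pihat[q, g] else 0.5
        }
      })
      P[a, b] <- P[b, a] <- val
    }
    out[[fid]] <- P
  }
  out
}

#' Serialize an IBD surface as long-format table
#' @param surface an [ibd_surface()].
#' @return data.frame (family, id1, id2, cM, p0, p1, p2, pihat).
#' @export
ibd_surface_table <- function(surface) {
  rows <- lapply(surface$families, function(f) {
    np <- nrow(f$pairs); ng <- length(f$grid)
    if (np == 0) return(NULL)
    data.frame(family = f$family_id,
               id1 = rep(f$pairs[, 1], ng), id2 = rep(f$pairs[, 2], ng),
               cM = rep(f$grid, each = np),
               p0 = as.vector(f$p0), p1 = as.vector(f$p1),
               p2 = as.vector(f$p2), pihat = as.vector(f$pihat),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
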