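# Domain containers and PLINK-dialect readers/writers.
#
# A cohort bundles four pieces: the pedigree table, the marker map, the
# genotype matrices (allele indices into each marker's allele label set;
# 0 = missing, PLINK convention) and the trait/covariate table.  Marker
# order is by map position (cM) and is preserved through the pipeline.

#' Construct a cohort
#'
#' @param individuals data.frame with columns `id`, `family_id`,
#'   `father_id`, `mother_id` (`NA` for founders), `sex`
#'   (`"male"`/`"female"`/`NA`).
#' @param markers data.frame with columns `name`, `chrom`, `pos_cM`,
#'   `pos_bp` and a list-column `alleles` of character allele labels.
#' @param geno_a1,geno_a2 integer matrices (individuals x markers) of
#'   allele indices into `markers$alleles`; 0 means missing.
#' @param traits optional data.frame keyed by `id` (see [read_traits()]).
#' @return An object of class `cohort`.
#' @export
new_cohort <- function(individuals, markers, geno_a1, geno_a2, traits = NULL) {
  stopifnot(is.data.frame(individuals), is.data.frame(markers))
  individuals$founder <- is.na(individuals$father_id) & is.na(individuals$mother_id)
  rownames(geno_a1) <- rownames(geno_a2) <- individuals$id
  colnames(geno_a1) <- colnames(geno_a2) <- markers$name
  obj <- structure(list(individuals = individuals, markers = markers,
                        geno_a1 = geno_a1, geno_a2 = geno_a2, traits = traits),
                   class = "cohort")
  validate_cohort(obj)
  obj
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("cohort: %d individuals in %d families, %d markers\n",
              nrow(x$individuals), length(unique(x$individuals$family_id)),
              nrow(x$markers)))
  if (!is.null(x$traits))
    cat(sprintf("traits: %d phenotyped individuals\n", nrow(x$traits)))
  invisible(x)
}

validate_cohort <- function(x) {
  ind <- x$individuals
  if (anyDuplicated(ind$id)) stop("duplicate individual ids")
  for (col in c("father_id", "mother_id")) {
    pp <- ind[[col]]
    has <- !is.na(pp)
    if (any(has)) {
      miss <- !(pp[has] %in% ind$id)
      if (any(miss))
        stop("parent id(s) not present in pedigree: ",
             paste(unique(pp[has][miss]), collapse = ", "))
      pf <- ind$family_id[match(pp[has], ind$id)]
      if (any(pf != ind$family_id[has]))
        stop("parents must belong to the same family as their offspring")
    }
  }
  if (nrow(x$markers) > 1 && any(diff(x$markers$pos_cM) <= 0))
    stop("marker map positions must be strictly increasing (cM)")
  if (!is.null(x$traits)) {
    tr <- x$traits
    if (!all(tr$id %in% ind$id))
      stop("trait table contains ids absent from the pedigree: ",
           paste(setdiff(tr$id, ind$id), collapse = ", "))
    if (all(c("age_onset", "age_last_exam") %in% names(tr))) {
      bad <- !is.na(tr$age_onset) & !is.na(tr$age_last_exam) &
        tr$age_onset > tr$age_last_exam
      if (any(bad))
        stop("age_onset exceeds age_last_exam for id(s): ",
             paste(tr$id[bad], collapse = ", "))
    }
  }
  invisible(x)
}

#' Split a cohort's pedigree into nuclear families
#'
#' @param cohort a [new_cohort()] object.
#' @return Named list (by family id) with elements `family_id`, `parents`
#'   (character, possibly length 0-2), `sibs` (character ids of the
#'   offspring sharing that parent pair).
#' @export
nuclear_families <- function(cohort) {
  ind <- cohort$individuals
  out <- list()
  for (fid in unique(ind$family_id)) {
    fam <- ind[ind$family_id == fid, ]
    kids <- fam[!fam$founder, ]
    if (nrow(kids) == 0) {
      out[[fid]] <- list(family_id = fid, parents = fam$id, sibs = character())
      next
    }
    pp <- unique(paste(kids$father_id, kids$mother_id))
    if (length(pp) > 1)
      stop("family ", fid, " is not nuclear: multiple parent pairs")
    parents <- intersect(c(kids$father_id[1], kids$mother_id[1]), fam$id)
    out[[fid]] <- list(family_id = fid, parents = parents, sibs = kids$id)
  }
  out
}

#' Read a PLINK-style .ped/.map pair
#'
#' The .map file has columns CHR NAME cM BP (the cM column is honored);
#' the .ped file has FID IID PAT MAT SEX PHENO followed by two allele
#' columns per marker, `0` meaning missing.  Allele labels are arbitrary
#' strings, so multiallelic microsatellites are supported.
#'
#' @param ped_path,map_path file paths.
#' @param marker_alleles optional named list of declared allele sets; an
#'   observed allele outside the declared set is a parse error.
#' @return A [new_cohort()] object (no trait table attached).
#' @export
read_ped_map <- function(ped_path, map_path, marker_alleles = NULL) {
  if (!file.exists(ped_path)) stop("no such file: ", ped_path)
  if (!file.exists(map_path)) stop("no such file: ", map_path)
  map <- read.table(map_path, header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("chrom", "name", "pos_cM", "pos_bp"))
  if (nrow(map) > 1 && any(diff(map$pos_cM) <= 0))
    stop("marker map positions must be strictly increasing (cM)")
  ped <- read.table(ped_path, header = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
  m <- nrow(map)
  if (ncol(ped) != 6 + 2 * m)
    stop("ped file has ", ncol(ped), " columns; expected ", 6 + 2 * m,
         " for ", m, " markers")
  key <- paste(ped[[1]], ped[[2]])
  if (anyDuplicated(key))
    stop("duplicate IID within FID: ", key[duplicated(key)][1])
  individuals <- data.frame(
    id = ped[[2]], family_id = ped[[1]],
    father_id = ifelse(ped[[3]] == "0", NA_character_, ped[[3]]),
    mother_id = ifelse(ped[[4]] == "0", NA_character_, ped[[4]]),
    sex = c("male", "female")[match(ped[[5]], c("1", "2"))],
    stringsAsFactors = FALSE)
  n <- nrow(ped)
  a1 <- a2 <- matrix(0L, n, m)
  alleles <- vector("list", m)
  for (k in seq_len(m)) {
    r1 <- ped[[6 + 2 * k - 1]]
    r2 <- ped[[6 + 2 * k]]
    obs <- setdiff(sort(unique(c(r1, r2))), "0")
    lab <- if (!is.null(marker_alleles) && map$name[k] %in% names(marker_alleles)) {
      declared <- as.character(marker_alleles[[map$name[k]]])
      extra <- setdiff(obs, declared)
      if (length(extra) > 0) {
        line <- which(r1 %in% extra | r2 %in% extra)[1]
        stop("marker ", map$name[k], ": allele '", extra[1],
             "' not in declared set (ped line ", line, ")")
      }
      declared
    } else obs
    alleles[[k]] <- lab
    a1[, k] <- ifelse(r1 == "0", 0L, match(r1, lab))
    a2[, k] <- ifelse(r2 == "0", 0L, match(r2, lab))
  }
  map$alleles <- alleles
  new_cohort(individuals, map, a1, a2)
}

#' Write a cohort as a PLINK-style .ped/.map pair
#' @param cohort a cohort.
#' @param ped_path,map_path output paths.
#' @export
write_ped_map <- function(cohort, ped_path, map_path) {
  mk <- cohort$markers
  write.table(mk[, c("chrom", "name", "pos_cM", "pos_bp")], map_path,
              quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t")
  ind <- cohort$individuals
  n <- nrow(ind); m <- nrow(mk)
  gcols <- matrix("0", n, 2 * m)
  for (k in seq_len(m)) {
    lab <- mk$alleles[[k]]
    i1 <- cohort$geno_a1[, k]; i2 <- cohort$geno_a2[, k]
    gcols[, 2 * k - 1] <- ifelse(i1 == 0, "0", lab[pmax(i1, 1)])
    gcols[, 2 * k]     <- ifelse(i2 == 0, "0", lab[pmax(i2, 1)])
  }
  out <- cbind(ind$family_id, ind$id,
               ifelse(is.na(ind$father_id), "0", ind$father_id),
               ifelse(is.na(ind$mother_id), "0", ind$mother_id),
               ifelse(is.na(ind$sex), "0", ifelse(ind$sex == "male", "1", "2")),
               "-9", gcols)
  write.table(out, ped_path, quote = FALSE, row.names = FALSE,
              col.names = FALSE, sep = " ")
  invisible(c(ped = ped_path, map = map_path))
}

#' Read a trait/covariate table
#'
#' @param csv_path CSV path. Numeric cells that fail to parse become `NA`
#'   with a warning.
#' @param cohort optional cohort; if given, ids absent from its pedigree
#'   are an error and the table is attached to the returned cohort.
#' @param col_map named character vector mapping canonical names
#'   (`id`, `trait`, `affected`, `age_last_exam`, `age_onset`, `sex`,
#'   `birth_year`, `admixture`, ...) to the file's header names.
#' @return The typed trait data.frame, or the cohort with `$traits` set.
#' @export
read_traits <- function(csv_path, cohort = NULL, col_map = NULL) {
  if (!file.exists(csv_path)) stop("no such file: ", csv_path)
  raw <- read.table(csv_path, header = TRUE, sep = ",",
                    stringsAsFactors = FALSE, colClasses = "character")
  if (!is.null(col_map)) {
    hit <- match(col_map, names(raw))
    if (anyNA(hit)) stop("column(s) not found: ",
                         paste(col_map[is.na(hit)], collapse = ", "))
    names(raw)[hit] <- names(col_map)
  }
  num_cols <- setdiff(names(raw), c("id", "family_id", "sex", "stratum"))
  for (cc in num_cols) {
    v <- raw[[cc]]
    parsed <- suppressWarnings(as.numeric(v))
    bad <- !is.na(v) & v != "" & is.na(parsed)
    if (any(bad))
      warning(sum(bad), " unparseable value(s) in column '", cc,
              "' set to NA")
    raw[[cc]] <- parsed
  }
  tr <- raw
  if (!is.null(cohort)) {
    missing_ids <- setdiff(tr$id, cohort$individuals$id)
    if (length(missing_ids) > 0)
      stop("trait table contains ids absent from the pedigree: ",
           paste(missing_ids, collapse = ", "))
    cohort$traits <- tr
    validate_cohort(cohort)
    return(cohort)
  }
  if (all(c("age_onset", "age_last_exam") %in% names(tr))) {
    bad <- !is.na(tr$age_onset) & !is.na(tr$age_last_exam) &
      tr$age_onset > tr$age_last_exam
    if (any(bad))
      stop("age_onset exceeds age_last_exam for id(s): ",
           paste(tr$id[bad], collapse = ", "))
  }
  tr
}

#' Write a trait table as CSV
#' @param traits data.frame (or a cohort, whose `$traits` is used).
#' @param csv_path output path.
#' @export
write_traits <- function(traits, csv_path) {
  if (inherits(traits, "cohort")) traits <- traits$traits
  write.table(traits, csv_path, quote = FALSE, row.names = FALSE, sep = ",")
  invisible(csv_path)
}

#' Founder allele frequencies for one marker
#'
#' Counting estimate over non-missing founder alleles; if no founder is
#' genotyped, falls back (with a warning) to all genotyped individuals.
#'
#' @param cohort a cohort.
#' @param marker marker name or index.
#' @return Named numeric vector over the marker's allele labels, summing
#'   to 1.
#' @export
allele_freqs_from_founders <- function(cohort, marker) {
  k <- if (is.character(marker)) match(marker, cohort$markers$name) else marker
  if (is.na(k)) stop("unknown marker: ", marker)
  lab <- cohort$markers$alleles[[k]]
  use <- cohort$individuals$founder
  al <- c(cohort$geno_a1[use, k], cohort$geno_a2[use, k])
  al <- al[al > 0]
  if (length(al) == 0) {
    warning("no genotyped founder for marker ", cohort$markers$name[k],
            "; falling back to all individuals")
    al <- c(cohort$geno_a1[, k], cohort$geno_a2[, k])
    al <- al[al > 0]
  }
  if (length(al) == 0)
    stop("no non-missing alleles for marker ", cohort$markers$name[k])
  counts <- tabulate(al, nbins = length(lab))
  setNames(counts / sum(counts), lab)
}

# Allele-label pair for one individual/marker ("0" when missing).
genotype_labels <- function(cohort, id, marker) {
  i <- match(id, cohort$individuals$id)
  k <- if (is.character(marker)) match(marker, cohort$markers$name) else marker
  lab <- cohort$markers$alleles[[k]]
  g <- c(cohort$geno_a1[i, k], cohort$geno_a2[i, k])
  ifelse(g == 0, "0", lab[pmax(g, 1)])
}
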