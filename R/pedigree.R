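#' Pedigrees and additive relationship matrices
#'
#' A pedigree is stored as a data frame with columns `id`, `sire`, `dam` and
#' optionally `sex` (`"M"`, `"F"` or `NA`) and `generation`. Unknown parents
#' are `NA`. Records are kept topologically sorted so that parents always
#' precede their offspring, which is the ordering the tabular method for the
#' numerator relationship matrix requires.
#'
#' @name pedigree
NULL

.unknown_tokens <- c("", "0", "NA", "na", "*", ".")

.normalise_parent <- function(x) {
  x <- as.character(x)
  x[x %in% .unknown_tokens | is.na(x)] <- NA_character_
  x
}

#' Validate and topologically sort pedigree records
#'
#' Checks uniqueness of identifiers, resolves unknown-parent codes
#' (`NA`, `""`, `"0"`, `"NA"`, `"*"`, `"."`), verifies that every named parent
#' is itself a record, and reorders records so parents precede offspring.
#' Ties are broken by input order, so a sorted pedigree is reproducible.
#'
#' @param records data frame with columns `id`, `sire`, `dam` and optionally
#'   `sex`, `generation`.
#' @return An object of class `pedigree`: the sorted records.
#' @examples
#' ped <- as_pedigree(data.frame(id = c("o1", "s", "d"),
#'                               sire = c("s", NA, NA),
#'                               dam  = c("d", NA, NA)))
#' ped$id  # parents first
#' @export
as_pedigree <- function(records) {
  records <- as.data.frame(records)
  stopifnot(all(c("id", "sire", "dam") %in% names(records)))
  id <- as.character(records$id)
  if (any(is.na(id) | id == "")) stop("pedigree ids must be non-empty")
  if (anyDuplicated(id)) {
    stop("duplicate pedigree id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  sire <- .normalise_parent(records$sire)
  dam <- .normalise_parent(records$dam)
  known <- c(sire, dam)
  known <- known[!is.na(known)]
  missing_parents <- setdiff(known, id)
  if (length(missing_parents) > 0) {
    stop("parent(s) without a pedigree record: ",
         paste(missing_parents, collapse = ", "))
  }

  n <- length(id)
  idx <- seq_len(n)
  names(idx) <- id
  si <- idx[sire]
  di <- idx[dam]

  ## Kahn's algorithm; queue kept in input order for deterministic output.
  indeg <- integer(n)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) {
      if (!is.na(p)) {
        indeg[i] <- indeg[i] + 1L
        children[[p]] <- c(children[[p]], i)
      }
    }
  }
  queue <- which(indeg == 0L)
  order_out <- integer(0)
  while (length(queue) > 0) {
    queue <- sort(queue)
    i <- queue[1]
    queue <- queue[-1]
    order_out <- c(order_out, i)
    for (ch in children[[i]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order_out) < n) {
    bad <- id[setdiff(seq_len(n), order_out)]
    stop("pedigree contains a cycle involving: ", paste(bad, collapse = ", "))
  }

  out <- data.frame(id = id, sire = sire, dam = dam, stringsAsFactors = FALSE)
  out$sex <- if ("sex" %in% names(records)) as.character(records$sex) else NA_character_
  out$generation <- if ("generation" %in% names(records)) {
    as.integer(records$generation)
  } else NA_integer_
  out <- out[order_out, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pedigree", "data.frame")
  out
}

#' @export
print.pedigree <- function(x, ...) {
  cat("pedigree with", nrow(x), "individuals (",
      sum(is.na(x$sire) & is.na(x$dam)), "founders )\n")
  NextMethod()
}

#' Read / write pedigree CSV files
#'
#' Tolerant three-plus-column CSV dialect: `id, sire, dam[, sex, generation]`.
#' `"NA"`, `"0"` and empty fields all parse as unknown parents.
#'
#' @param path file path.
#' @return `read_pedigree` returns a sorted [pedigree]; `write_pedigree`
#'   returns `path` invisibly.
#' @export
read_pedigree <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  as_pedigree(df)
}

#' @rdname read_pedigree
#' @param ped a [pedigree].
#' @export
write_pedigree <- function(ped, path) {
  utils::write.csv(as.data.frame(ped), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Additive (numerator) relationship matrix
#'
#' Builds A by the tabular method: for a pedigree sorted with parents before
#' offspring, `A[i,i] = 1 + 0.5 * A[sire(i), dam(i)]` (the inbreeding term is
#' zero when either parent is unknown) and for `j < i`,
#' `A[i,j] = 0.5 * (A[j, sire(i)] + A[j, dam(i)])`. Unknown parents are
#' treated as unrelated, non-inbred founders.
#'
#' @param ped a [pedigree] (records are re-sorted if needed).
#' @return symmetric matrix with dimnames equal to the individual labels.
#' @examples
#' ped <- simulate_pedigree(n_generations = 1, n_sires = 2, dams_per_sire = 2,
#'                          offspring_per_dam = 2, seed = 1)
#' A <- additive_relationship_matrix(ped)
#' range(diag(A))
#' @export
additive_relationship_matrix <- function(ped) {
  if (!inherits(ped, "pedigree")) ped <- as_pedigree(ped)
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$id
  si <- unname(idx[ped$sire])
  di <- unname(idx[ped$dam])
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    s <- si[i]
    d <- di[i]
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
    if (i > 1L) {
      j <- seq_len(i - 1L)
      aj <- numeric(i - 1L)
      if (!is.na(s)) aj <- aj + A[j, s]
      if (!is.na(d)) aj <- aj + A[j, d]
      aj <- 0.5 * aj
      A[j, i] <- aj
      A[i, j] <- aj
    }
  }
  A
}

#' Monte-Carlo relationship matrix by gene dropping
#'
#' Independent brute-force estimate of the additive relationship matrix:
#' founders receive unique allele labels, alleles are dropped through the
#' pedigree by Mendelian sampling, and relationship is estimated as twice the
#' coefficient of kinship (probability that randomly drawn alleles, one from
#' each individual, are identical by descent; an individual may draw the same
#' allele copy twice, which recovers `1 + F` on the diagonal).
#'
#' @param ped a [pedigree].
#' @param n_reps number of independent allele drops (>= 1000).
#' @param seed integer seed.
#' @return symmetric matrix, same layout as [additive_relationship_matrix()].
#' @export
gene_drop_relationship <- function(ped, n_reps = 10000, seed = 1) {
  if (!inherits(ped, "pedigree")) ped <- as_pedigree(ped)
  stopifnot(n_reps >= 1000)
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$id
  si <- unname(idx[ped$sire])
  di <- unname(idx[ped$dam])
  founder_allele <- max(2L * n, 1L)

  old <- .save_seed()
  on.exit(.restore_seed(old))
  set.seed(seed)

  ## Drop alleles for all replicates, storing per-individual allele labels;
  ## founder alleles are unique within a replicate.
  pick_sire <- matrix(stats::runif(n * n_reps) < 0.5, n, n_reps)
  pick_dam <- matrix(stats::runif(n * n_reps) < 0.5, n, n_reps)
  A1 <- matrix(0L, n, n_reps)
  A2 <- matrix(0L, n, n_reps)
  next_allele <- 1L
  for (i in seq_len(n)) {
    if (is.na(si[i])) {
      A1[i, ] <- next_allele
      next_allele <- next_allele + 1L
    } else {
      A1[i, ] <- ifelse(pick_sire[i, ], A1[si[i], ], A2[si[i], ])
    }
    if (is.na(di[i])) {
      A2[i, ] <- next_allele
      next_allele <- next_allele + 1L
    } else {
      A2[i, ] <- ifelse(pick_dam[i, ], A1[di[i], ], A2[di[i], ])
    }
  }

  ## 2 * kinship: average IBD over the four within-pair allele draws,
  ## including self-pairs (draws with replacement recover 1 + F).
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in i:n) {
      ibd <- (sum(A1[i, ] == A1[j, ]) + sum(A1[i, ] == A2[j, ]) +
                sum(A2[i, ] == A1[j, ]) + sum(A2[i, ] == A2[j, ])) / 2
      A[i, j] <- A[j, i] <- ibd / n_reps
    }
  }
  dimnames(A) <- list(ped$id, ped$id)
  A
}

#' Simulate a nested full-sib / half-sib breeding design
#'
#' Generates a pedigree with maternal full-sib families nested within paternal
#' half-sib groups, the mating structure typical of guppy breeding designs in
#' which one male is circulated among a harem of females. Founders form
#' generation 0; in each later generation, sires and dams are drawn from the
#' previous generation (from distinct full-sib families where possible) and
#' each dam produces a brood by her assigned sire. Offspring sexes are
#' assigned approximately 1:1. A configurable fraction of offspring have their
#' sire recorded as unknown, mimicking broods that cannot be positively
#' assigned to the resident male.
#'
#' @param n_generations number of offspring generations (<= 5 by convention of
#'   the designs this emulates; larger values are allowed but warned about).
#' @param n_sires sires per generation.
#' @param dams_per_sire dams mated to each sire.
#' @param offspring_per_dam brood size per dam.
#' @param unknown_paternity fraction of offspring with sire recorded unknown.
#' @param seed integer seed.
#' @return a sorted [pedigree] with `sex` and `generation` filled in.
#' @export
simulate_pedigree <- function(n_generations = 3, n_sires = 10,
                              dams_per_sire = 3, offspring_per_dam = 8,
                              unknown_paternity = 0, seed = 1) {
  if (n_sires < 1) stop("design needs at least one sire")
  if (dams_per_sire < 1 || offspring_per_dam < 1) {
    stop("dams_per_sire and offspring_per_dam must be positive")
  }
  if (n_generations < 1) stop("need at least one offspring generation")
  if (n_generations > 5) {
    warning("designs deeper than five generations are unusual for this scheme")
  }
  old <- .save_seed()
  on.exit(.restore_seed(old))
  set.seed(seed)

  n_dams <- n_sires * dams_per_sire
  id <- c(sprintf("S0_%03d", seq_len(n_sires)),
          sprintf("D0_%03d", seq_len(n_dams)))
  rec <- data.frame(id = id, sire = NA_character_, dam = NA_character_,
                    sex = rep(c("M", "F"), c(n_sires, n_dams)),
                    generation = 0L, stringsAsFactors = FALSE)
  males <- rec$id[rec$sex == "M"]
  females <- rec$id[rec$sex == "F"]
  family <- stats::setNames(seq_len(nrow(rec)), rec$id)  # founders: own family

  for (g in seq_len(n_generations)) {
    if (length(males) < n_sires || length(females) < n_dams) {
      stop("not enough candidates of each sex to continue the design")
    }
    ## prefer one sire per full-sib family, then recycle
    sires <- .spread_pick(males, family, n_sires)
    dams <- .spread_pick(setdiff(females, character(0)), family, n_dams)
    dam_sire <- rep(sires, each = dams_per_sire)

    n_off <- n_dams * offspring_per_dam
    off_id <- sprintf("G%d_%04d", g, seq_len(n_off))
    off_dam <- rep(dams, each = offspring_per_dam)
    off_sire <- rep(dam_sire, each = offspring_per_dam)
    drop_sire <- stats::runif(n_off) < unknown_paternity
    off_sire[drop_sire] <- NA_character_
    sex <- rep(c("M", "F"), length.out = n_off)[sample.int(n_off)]
    rec <- rbind(rec, data.frame(id = off_id, sire = off_sire, dam = off_dam,
                                 sex = sex, generation = g,
                                 stringsAsFactors = FALSE))
    fam_codes <- as.integer(factor(off_dam)) + max(family)
    family <- c(family, stats::setNames(fam_codes, off_id))
    males <- off_id[sex == "M"]
    females <- off_id[sex == "F"]
  }
  as_pedigree(rec)
}

## pick k individuals spreading across full-sib families (round robin)
.spread_pick <- function(candidates, family, k) {
  fam <- family[candidates]
  split_by_fam <- split(candidates, fam)
  split_by_fam <- split_by_fam[sample.int(length(split_by_fam))]
  picked <- character(0)
  while (length(picked) < k) {
    for (f in seq_along(split_by_fam)) {
      if (length(split_by_fam[[f]]) > 0 && length(picked) < k) {
        take <- sample.int(length(split_by_fam[[f]]), 1)
        picked <- c(picked, split_by_fam[[f]][take])
        split_by_fam[[f]] <- split_by_fam[[f]][-take]
      }
    }
    if (all(lengths(split_by_fam) == 0) && length(picked) < k) {
      stop("not enough candidates to pick from")
    }
  }
  picked
}

#' Write a relationship matrix as labelled CSV
#'
#' @param A square matrix with dimnames.
#' @param path output file.
#' @export
write_relationship_matrix <- function(A, path) {
  utils::write.csv(as.data.frame(A), path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_relationship_matrix
#' @export
read_relationship_matrix <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  as.matrix(df)
}

## -- seed bookkeeping: keep user RNG state untouched by seeded simulators ----
.save_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
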