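## Pedigree ingestion, generation tracing, Meuwissen-Luo inbreeding, the
## tabular numerator relationship matrix A (dense oracle) and its sparse
## inverse by Henderson's rules with inbreeding.

#' Read a 3-column pedigree file
#'
#' @param file path to a delimited text file with columns animal, sire, dam
#'   (header optional; autodetected). Unknown parents are coded 0, empty or
#'   NA.
#' @return data.frame with character columns `animal`, `sire`, `dam`
#'   (`NA` = unknown parent).
#' @export
readPedigree <- function(file) {
  first <- strsplit(trimws(readLines(file, n = 1)), "[,;\t ]+")[[1]]
  header <- any(tolower(first) %in% c("animal", "id", "sire", "dam"))
  sep <- if (grepl(",", readLines(file, n = 1))) "," else ""
  d <- read.table(file, header = header, sep = sep,
                  colClasses = "character", strip.white = TRUE,
                  na.strings = c("NA", ""))
  if (ncol(d) < 3) stop("pedigree file must have 3 columns: animal, sire, dam")
  d <- d[, 1:3]
  names(d) <- c("animal", "sire", "dam")
  for (j in 2:3) d[[j]][d[[j]] %in% c("0", "", NA)] <- NA
  d
}

#' Trace a pedigree back from the phenotyped animals
#'
#' Keeps the phenotyped animals plus their ancestors up to
#' `maxGenerations` (an animal's generation is its shortest ancestral path
#' to a phenotyped descendant; parents count as generation 1). Parents of
#' animals at the cutoff become unknown. Returns a topologically ordered
#' [Pedigree-class] with inbreeding coefficients.
#'
#' @param ped data.frame with character columns `animal`, `sire`, `dam` (as
#'   from [readPedigree()]).
#' @param phenotypedIds character ids of the phenotyped animals.
#' @param maxGenerations ancestral generations to retain.
#' @return a [Pedigree-class].
#' @export
tracePedigree <- function(ped, phenotypedIds, maxGenerations = 5) {
  ped <- normalizePedFrame(ped)
  missing <- setdiff(phenotypedIds, ped$animal)
  if (length(missing))
    ped <- rbind(ped, data.frame(animal = missing, sire = NA_character_,
                                 dam = NA_character_))
  sire <- setNames(ped$sire, ped$animal)
  dam <- setNames(ped$dam, ped$animal)
  gen <- setNames(rep(Inf, nrow(ped)), ped$animal)
  gen[phenotypedIds] <- 0
  frontier <- phenotypedIds
  g <- 0
  while (length(frontier) && g < maxGenerations) {
    g <- g + 1
    par <- unique(stats::na.omit(c(sire[frontier], dam[frontier])))
    par <- par[par %in% names(gen)]
    newer <- par[gen[par] > g]
    gen[newer] <- g
    frontier <- newer
  }
  keep <- names(gen)[is.finite(gen)]
  sub <- ped[ped$animal %in% keep, , drop = FALSE]
  ## parents beyond the cutoff (or outside the kept set) become unknown
  sub$sire[!(sub$sire %in% keep)] <- NA
  sub$dam[!(sub$dam %in% keep)] <- NA
  atCut <- sub$animal[gen[sub$animal] >= maxGenerations]
  sub$sire[sub$animal %in% atCut] <- NA
  sub$dam[sub$animal %in% atCut] <- NA
  newPedigree(sub$animal, sub$sire, sub$dam,
              phenotyped = sub$animal %in% phenotypedIds)
}

normalizePedFrame <- function(ped) {
  ped <- data.frame(animal = as.character(ped[[1]]),
                    sire = as.character(ped[[2]]),
                    dam = as.character(ped[[3]]),
                    stringsAsFactors = FALSE)
  for (j in c("sire", "dam")) ped[[j]][ped[[j]] %in% c("0", "")] <- NA
  if (anyDuplicated(ped$animal)) {
    dup <- ped$animal[duplicated(ped$animal)]
    for (a in unique(dup)) {
      rows <- ped[ped$animal == a, ]
      if (nrow(unique(rows)) > 1)
        stop(sprintf("duplicate rows for animal '%s' with conflicting parents", a))
    }
    ped <- ped[!duplicated(ped$animal), ]
  }
  ## parents that never appear as animals become founders
  par <- setdiff(stats::na.omit(c(ped$sire, ped$dam)), ped$animal)
  if (length(par))
    ped <- rbind(data.frame(animal = par, sire = NA_character_,
                            dam = NA_character_), ped)
  ped
}

#' Construct an ordered Pedigree
#'
#' Topologically sorts the animals (parents first; a cycle is an error
#' naming the animals involved) and computes inbreeding coefficients by the
#' Meuwissen-Luo recursion. Unknown parents are treated as unrelated
#' founders.
#'
#' @param id character animal ids.
#' @param sire,dam character parent ids (`NA` = unknown).
#' @param phenotyped logical, per animal.
#' @return a [Pedigree-class].
#' @export
newPedigree <- function(id, sire, dam, phenotyped = rep(FALSE, length(id))) {
  id <- as.character(id)
  n <- length(id)
  pos <- setNames(seq_len(n), id)
  si <- unname(pos[as.character(sire)])
  di <- unname(pos[as.character(dam)])
  si[is.na(sire)] <- NA; di[is.na(dam)] <- NA
  ## Kahn topological sort
  indeg <- integer(n)
  kids <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) {
      if (!is.na(p)) {
        indeg[i] <- indeg[i] + 1L
        kids[[p]] <- c(kids[[p]], i)
      }
    }
  }
  queue <- integer(n)
  nq <- 0L
  for (v in which(indeg == 0L)) { nq <- nq + 1L; queue[nq] <- v }
  indeg2 <- indeg
  head <- 0L
  order <- integer(0)
  while (head < nq) {
    head <- head + 1L
    v <- queue[head]
    for (k in kids[[v]]) {
      indeg2[k] <- indeg2[k] - 1L
      if (indeg2[k] == 0L) { nq <- nq + 1L; queue[nq] <- k }
    }
  }
  order <- queue[seq_len(nq)]
  if (length(order) < n) {
    cyc <- id[setdiff(seq_len(n), order)]
    stop("pedigree contains a cycle involving: ", paste(cyc, collapse = ", "))
  }
  rank <- integer(n); rank[order] <- seq_len(n)
  id2 <- id[order]
  si2 <- rank[si][order]; di2 <- rank[di][order]
  ph2 <- phenotyped[order]
  Fcoef <- inbreedingML(si2, di2)
  new("Pedigree", id = id2, sire = as.integer(si2), dam = as.integer(di2),
      inbreeding = Fcoef, phenotyped = as.logical(ph2))
}

## Meuwissen-Luo inbreeding for an ordered pedigree (parent indices < own).
inbreedingML <- function(sire, dam) {
  n <- length(sire)
  Fc <- numeric(n)
  Dv <- numeric(n)  # Mendelian-sampling variance coefficient d_i
  for (i in seq_len(n)) {
    s <- sire[i]; d <- dam[i]
    Dv[i] <- if (is.na(s) && is.na(d)) 1 else
      if (is.na(s)) 0.75 - 0.25 * Fc[d] else
      if (is.na(d)) 0.75 - 0.25 * Fc[s] else
      0.5 - 0.25 * (Fc[s] + Fc[d])
    if (is.na(s) || is.na(d)) { Fc[i] <- 0; next }
    ## a_ii = sum over ancestors j of L_j^2 d_j, with L_i = 1
    anc <- collectAncestors(i, sire, dam)
    L <- numeric(n)
    L[i] <- 1
    a_ii <- 0
    for (j in anc) {  # decreasing index: L[j] final when reached
      if (L[j] == 0) next
      a_ii <- a_ii + L[j]^2 * Dv[j]
      if (!is.na(sire[j])) L[sire[j]] <- L[sire[j]] + 0.5 * L[j]
      if (!is.na(dam[j])) L[dam[j]] <- L[dam[j]] + 0.5 * L[j]
    }
    Fc[i] <- a_ii - 1
  }
  Fc
}

collectAncestors <- function(i, sire, dam) {
  seen <- i
  frontier <- i
  while (length(frontier)) {
    par <- c(sire[frontier], dam[frontier])
    par <- unique(par[!is.na(par)])
    par <- setdiff(par, seen)
    seen <- c(seen, par)
    frontier <- par
  }
  sort(seen, decreasing = TRUE)
}

#' Dense numerator relationship matrix (tabular method)
#'
#' Standard tabular recursion; serves as the oracle for [aInverse()].
#'
#' @param ped a [Pedigree-class].
#' @return dense symmetric matrix with `1 + F` on the diagonal, dimnames =
#'   animal ids.
#' @export
aMatrix <- function(ped) {
  stopifnot(is(ped, "Pedigree"))
  n <- nAnimals(ped)
  if (n > 3000) stop("tabular A is a dense oracle; use aInverse() at scale")
  A <- matrix(0, n, n, dimnames = list(ped@id, ped@id))
  s <- ped@sire; d <- ped@dam
  for (i in seq_len(n)) {
    if (i > 1) {
      j <- seq_len(i - 1)
      as_ <- if (is.na(s[i])) numeric(i - 1) else A[s[i], j]
      ad_ <- if (is.na(d[i])) numeric(i - 1) else A[d[i], j]
      A[i, j] <- 0.5 * (as_ + ad_)
      A[j, i] <- A[i, j]
    }
    A[i, i] <- 1 + if (is.na(s[i]) || is.na(d[i])) 0 else 0.5 * A[s[i], d[i]]
  }
  A
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Henderson's rules with inbreeding: the Mendelian-sampling variance
#' coefficient of animal i is `d_i = 0.5 - 0.25 (F_s + F_d)` (0.75 - 0.25 F
#' with one known parent, 1 with none), and `alpha_i = 1 / d_i` is
#' distributed over the animal-parent block.
#'
#' @param ped a [Pedigree-class].
#' @return sparse symmetric `Matrix::dgCMatrix`, dimnames = animal ids.
#' @export
aInverse <- function(ped) {
  stopifnot(is(ped, "Pedigree"))
  n <- nAnimals(ped)
  s <- ped@sire; d <- ped@dam; Fc <- ped@inbreeding
  ii <- integer(9L * n); jj <- integer(9L * n); xx <- numeric(9L * n)
  k <- 0L
  add <- function(i, j, x) {
    k <<- k + 1L
    ii[k] <<- i; jj[k] <<- j; xx[k] <<- x
  }
  for (i in seq_len(n)) {
    di <- if (is.na(s[i]) && is.na(d[i])) 1 else
      if (is.na(s[i])) 0.75 - 0.25 * Fc[d[i]] else
      if (is.na(d[i])) 0.75 - 0.25 * Fc[s[i]] else
      0.5 - 0.25 * (Fc[s[i]] + Fc[d[i]])
    a <- 1 / di
    add(i, i, a)
    for (p in c(s[i], d[i])) {
      if (is.na(p)) next
      add(i, p, -a / 2); add(p, i, -a / 2)
      add(p, p, a / 4)
    }
    if (!is.na(s[i]) && !is.na(d[i])) {
      add(s[i], d[i], a / 4); add(d[i], s[i], a / 4)
    }
  }
  ii <- ii[seq_len(k)]; jj <- jj[seq_len(k)]; xx <- xx[seq_len(k)]
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                       dimnames = list(ped@id, ped@id))
}
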