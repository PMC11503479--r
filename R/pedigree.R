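#' Read and validate a pedigree table
#'
#' Reads a pedigree CSV (one row per individual, with sire/dam links and an
#' optional cohort year), validates it, and appends implicit founders for any
#' parent that is referenced but has no row of its own. Unknown parents are
#' encoded by a configurable sentinel (empty field and `NA` by default).
#'
#' @param path Path to a CSV file with a header row.
#' @param id_col,sire_col,dam_col,cohort_col Column names in the file. The
#'   cohort column is optional; set `cohort_col = NULL` if absent.
#' @param missing Character vector of sentinel values marking an unknown
#'   parent (matched after trimming whitespace). Empty fields and `"NA"` are
#'   always treated as unknown.
#'
#' @return A `cram_pedigree` data frame with columns `id`, `sire`, `dam`
#'   (character, `NA` = unknown) and `cohort` (integer, `NA` = unknown), in
#'   file order with implicit founders appended. Founders are exactly the
#'   rows with both parents unknown.
#'
#' @details Validation enforces that no individual is its own ancestor (the
#'   pedigree must be acyclic), that duplicated ids agree on their parents
#'   (duplicates are then dropped), and that a parent's cohort, when known,
#'   precedes its offspring's.
#' @export
read_pedigree <- function(path, id_col = "id", sire_col = "sire",
                          dam_col = "dam", cohort_col = "cohort",
                          missing = c("", "NA", "*")) {
  if (!file.exists(path)) stopf("pedigree file not found: %s", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, strip.white = TRUE)
  for (col in c(id_col, sire_col, dam_col)) {
    if (!col %in% names(raw)) stopf("pedigree file lacks column '%s'", col)
  }
  clean <- function(x) {
    x <- trimws(x)
    x[x %in% missing | is.na(x)] <- NA_character_
    x
  }
  cohort <- if (!is.null(cohort_col) && cohort_col %in% names(raw)) {
    suppressWarnings(as.integer(clean(raw[[cohort_col]])))
  } else {
    rep(NA_integer_, nrow(raw))
  }
  as_pedigree(data.frame(id = clean(raw[[id_col]]),
                         sire = clean(raw[[sire_col]]),
                         dam = clean(raw[[dam_col]]),
                         cohort = cohort,
                         stringsAsFactors = FALSE))
}

#' Construct a validated pedigree from vectors or a data frame
#'
#' @param x A data frame with columns `id`, `sire`, `dam` and optionally
#'   `cohort`. `NA` marks an unknown parent or cohort.
#' @return A validated `cram_pedigree` data frame (implicit founders appended).
#' @export
as_pedigree <- function(x) {
  stopifnot(is.data.frame(x), all(c("id", "sire", "dam") %in% names(x)))
  ped <- data.frame(id = as.character(x$id),
                    sire = as.character(x$sire),
                    dam = as.character(x$dam),
                    cohort = if ("cohort" %in% names(x))
                      as.integer(x$cohort) else rep(NA_integer_, nrow(x)),
                    stringsAsFactors = FALSE)
  if (anyNA(ped$id)) stopf("pedigree contains missing individual ids")

  # collapse duplicates; conflicting parent links are a data error
  if (anyDuplicated(ped$id)) {
    key <- paste(ped$id, ped$sire, ped$dam)
    ped_u <- ped[!duplicated(ped$id), , drop = FALSE]
    if (length(unique(key)) != nrow(ped_u)) {
      bad <- unique(ped$id[duplicated(ped$id)])
      conflict <- bad[vapply(bad, function(i) {
        sub <- ped[ped$id == i, c("sire", "dam")]
        nrow(unique(sub)) > 1L
      }, logical(1))]
      if (length(conflict)) {
        stopf("duplicate pedigree rows with conflicting parents for: %s",
              paste(conflict, collapse = ", "))
      }
    }
    ped <- ped_u
  }

  # parents referenced but absent become implicit founders
  parents <- unique(stats::na.omit(c(ped$sire, ped$dam)))
  implicit <- setdiff(parents, ped$id)
  if (length(implicit)) {
    ped <- rbind(ped, data.frame(id = implicit, sire = NA_character_,
                                 dam = NA_character_, cohort = NA_integer_,
                                 stringsAsFactors = FALSE))
  }
  rownames(ped) <- NULL
  class(ped) <- c("cram_pedigree", "data.frame")
  check_acyclic(ped)

  kn <- !is.na(ped$cohort)
  for (pcol in c("sire", "dam")) {
    pi <- match(ped[[pcol]], ped$id)
    ok <- is.na(pi) | !kn | !kn[ifelse(is.na(pi), 1L, pi)] |
      ped$cohort[ifelse(is.na(pi), 1L, pi)] < ped$cohort
    if (!all(ok, na.rm = TRUE)) {
      stopf("parent cohort does not precede offspring cohort for: %s",
            paste(ped$id[!ok], collapse = ", "))
    }
  }
  ped
}

check_acyclic <- function(ped) {
  ord <- try(sort_pedigree(ped), silent = TRUE)
  if (inherits(ord, "try-error")) stop(attr(ord, "condition"))
  invisible(TRUE)
}

#' Topologically sort a pedigree
#'
#' Orders records so that every parent precedes all of its offspring, as
#' required by the tabular relationship-matrix recursion. The sort is stable:
#' ties keep input order, and an already-sorted pedigree is returned as is.
#'
#' @param ped A `cram_pedigree` data frame (see [as_pedigree()]).
#' @return The same records, parent-before-offspring ordered.
#' @export
sort_pedigree <- function(ped) {
  n <- nrow(ped)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  placed <- logical(n)
  out <- integer(n)
  k <- 0L
  repeat {
    ready <- which(!placed &
                     (is.na(si) | placed[ifelse(is.na(si), 1L, si)]) &
                     (is.na(di) | placed[ifelse(is.na(di), 1L, di)]))
    if (!length(ready)) break
    out[k + seq_along(ready)] <- ready
    k <- k + length(ready)
    placed[ready] <- TRUE
  }
  if (k < n) {
    cyc <- ped$id[!placed]
    stopf("pedigree contains a cycle involving: %s",
          paste(utils::head(cyc, 10L), collapse = ", "))
  }
  res <- ped[out, , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- class(ped)
  res
}

is_parent_ordered <- function(ped) {
  pos <- seq_len(nrow(ped))
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  all(is.na(si) | si < pos) && all(is.na(di) | di < pos)
}

#' Additive relationship matrix from a pedigree
#'
#' Computes the numerator relationship matrix A — twice the pairwise kinship
#' coefficients — by the recursive tabular method, with founders treated as
#' unrelated and non-inbred and unknown parents contributing zero:
#' \deqn{A_{ii} = 1 + \tfrac12 A_{s(i),d(i)}, \quad
#'       A_{ij} = \tfrac12 (A_{j,s(i)} + A_{j,d(i)}), \; j < i.}
#'
#' @param ped A `cram_pedigree`, parent-before-offspring ordered (error
#'   otherwise; use [sort_pedigree()]).
#' @param sparse Store the result sparsely? Default keeps the dense matrix
#'   when fewer than `dense_max` individuals, mirroring the usual trade-off
#'   for pedigree A matrices (dense below a few thousand, sparse beyond).
#' @param dense_max Size threshold for the dense default.
#' @return A `relatedness_matrix`: list with `ids` (ordering used for
#'   indexing) and `A` (symmetric matrix with `ids` dimnames). Diagonal
#'   entries equal 1 plus the individual's inbreeding coefficient.
#' @export
make_A <- function(ped, sparse = NULL, dense_max = 4000L) {
  if (!is_parent_ordered(ped)) {
    stopf("pedigree must be parent-before-offspring ordered; see sort_pedigree()")
  }
  n <- nrow(ped)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row <- numeric(i - 1L)
      if (!is.na(s)) row <- row + A[s, j]
      if (!is.na(d)) row <- row + A[d, j]
      row <- row / 2
      A[i, j] <- row
      A[j, i] <- row
    }
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
  }
  if (is.null(sparse)) sparse <- n > dense_max
  if (sparse) A <- Matrix::forceSymmetric(Matrix::Matrix(A, sparse = TRUE))
  structure(list(ids = ped$id, A = A), class = "relatedness_matrix")
}

#' @export
print.relatedness_matrix <- function(x, ...) {
  nz <- sum(as.matrix(x$A) != 0)
  cat(sprintf("<relatedness_matrix> %d individuals, %d non-zero entries\n",
              length(x$ids), nz))
  invisible(x)
}

#' @export
as.matrix.relatedness_matrix <- function(x, ...) {
  m <- as.matrix(x$A)
  dimnames(m) <- list(x$ids, x$ids)
  m
}

#' @export
dim.relatedness_matrix <- function(x) c(length(x$ids), length(x$ids))

#' Summarize pairwise relatedness links
#'
#' Counts non-zero off-diagonal relatedness pairs (unordered) among a focal
#' set, and the proportion of those links at or above a threshold — the
#' standard description of close-kin density in a study pedigree.
#'
#' @param A A `relatedness_matrix`.
#' @param focal Ids to restrict to (default: all). Must be non-empty and a
#'   subset of `A$ids`.
#' @param threshold Relatedness cut-off for the "close kin" proportion
#'   (default 0.25, half-sib level).
#' @return List with `n_nonzero_pairs` and `proportion_ge_threshold` (the
#'   proportion among non-zero links; `NaN` when there are none).
#' @export
summarize_links <- function(A, focal = NULL, threshold = 0.25) {
  focal <- focal %||% A$ids
  if (!length(focal)) stopf("`focal` must be a non-empty id set")
  idx <- match(focal, A$ids)
  if (anyNA(idx)) {
    stopf("focal ids absent from relatedness matrix: %s",
          paste(utils::head(focal[is.na(idx)], 5L), collapse = ", "))
  }
  m <- as.matrix(A$A)[idx, idx, drop = FALSE]
  up <- m[upper.tri(m)]
  nz <- up[up != 0]
  list(n_nonzero_pairs = length(nz),
       proportion_ge_threshold = if (length(nz)) mean(nz >= threshold) else NaN)
}

#' Restrict a focal set to genetically informative individuals
#'
#' Drops focal individuals absent from the pedigree, then focal individuals
#' with zero relatedness to every other retained focal individual, iterating
#' to a fixed point. This mirrors the usual pre-filtering of phenotyped sets
#' before an animal-model fit: an individual unrelated to all other
#' phenotyped individuals carries no information about genetic variance.
#'
#' @param ids Focal (phenotyped) individual ids.
#' @param A A `relatedness_matrix`.
#' @return The retained id subset (possibly empty), in input order.
#' @export
prune_informative <- function(ids, A) {
  keep <- ids[ids %in% A$ids]
  repeat {
    if (length(keep) < 2L) return(character(0))
    m <- as.matrix(A$A)[match(keep, A$ids), match(keep, A$ids), drop = FALSE]
    diag(m) <- 0
    linked <- rowSums(m != 0) > 0
    if (all(linked)) return(keep)
    keep <- keep[linked]
  }
}

#' Lower-Cholesky factor of a relatedness matrix
#'
#' Returns lower-triangular `L` with `L %*% t(L) = A` (within `tol`), used
#' for non-centred breeding values `a = sigma_a * L %*% u`. A is positive
#' semidefinite by construction but can be numerically singular (e.g. clones
#' of founders), so a small diagonal jitter is escalated until the
#' factorization succeeds; any jitter used is recorded in the `"jitter"`
#' attribute and signalled as a message.
#'
#' @param A A `relatedness_matrix`.
#' @param tol Reconstruction tolerance (default `1e-8`).
#' @return Lower-triangular matrix with id dimnames; attribute `jitter`.
#' @export
factor_A <- function(A, tol = 1e-8) {
  m <- as.matrix(A$A)
  jitter <- 0
  for (j in c(0, 10^seq(-12, -6))) {
    mj <- m
    if (j > 0) diag(mj) <- diag(mj) + j
    ch <- tryCatch(chol(mj), error = function(e) NULL)
    if (!is.null(ch)) { jitter <- j; break }
    ch <- NULL
  }
  if (is.null(ch)) stopf("Cholesky factorization of A failed even with jitter")
  if (jitter > 0) message(sprintf("factor_A: diagonal jitter %g applied", jitter))
  L <- t(ch)
  err <- max(abs(L %*% t(L) - m))
  if (err > tol) stopf("factorization error %.3g exceeds tolerance %.3g", err, tol)
  dimnames(L) <- list(A$ids, A$ids)
  attr(L, "jitter") <- jitter
  L
}

#' Inverse relationship matrix directly from the pedigree
#'
#' Builds the sparse inverse of A by Henderson's rules with inbreeding
#' accounted for (Mendelian-sampling variances from the diagonal of A),
#' avoiding a dense inverse. Used by the sampler for the conditional prior
#' of individual breeding values.
#'
#' @param ped Parent-ordered `cram_pedigree`.
#' @param A Optional precomputed `make_A(ped)` (reused for the inbreeding
#'   coefficients).
#' @return Sparse symmetric `dsCMatrix` with id dimnames.
#' @export
make_Ainv <- function(ped, A = NULL) {
  if (!is_parent_ordered(ped)) {
    stopf("pedigree must be parent-before-offspring ordered")
  }
  if (is.null(A)) A <- make_A(ped)
  stopifnot(identical(A$ids, ped$id))
  n <- nrow(ped)
  f <- as.numeric(Matrix::diag(A$A)) - 1    # inbreeding coefficients
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  ii <- jj <- integer(0); xx <- numeric(0)
  add <- function(i, j, v) {
    ii <<- c(ii, i); jj <<- c(jj, j); xx <<- c(xx, v)
  }
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    dmi <- if (!is.na(s) && !is.na(d)) {
      0.5 - 0.25 * (f[s] + f[d])
    } else if (!is.na(s)) {
      0.75 - 0.25 * f[s]
    } else if (!is.na(d)) {
      0.75 - 0.25 * f[d]
    } else 1
    w <- 1 / dmi
    add(i, i, w)
    for (p in c(s, d)) {
      if (!is.na(p)) {
        add(p, p, 0.25 * w)
        add(i, p, -0.5 * w); add(p, i, -0.5 * w)
      }
    }
    if (!is.na(s) && !is.na(d)) {
      add(s, d, 0.25 * w); add(d, s, 0.25 * w)
    }
  }
  out <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                              dimnames = list(ped$id, ped$id))
  Matrix::forceSymmetric(out)
}

#' Randomize a relatedness matrix
#'
#' Applies one uniformly random permutation to the id-to-row mapping of A,
#' shuffling its off-diagonal structure relative to the phenotypes while
#' preserving the diagonal and eigenvalue multisets. Refitting with a
#' permuted A is the standard null check that genetic-variance estimates are
#' not spuriously inflated: the permuted fit should concentrate the additive
#' variance near zero.
#'
#' @param A A `relatedness_matrix`.
#' @param seed Integer seed; the same seed always yields the same permutation.
#' @return A `relatedness_matrix` with identical `ids` but permuted values.
#' @export
permute_A <- function(A, seed) {
  n <- length(A$ids)
  perm <- with_seed(seed, sample.int(n))
  m <- A$A[perm, perm, drop = FALSE]
  dimnames(m) <- list(A$ids, A$ids)
  structure(list(ids = A$ids, A = m, permutation = perm),
            class = "relatedness_matrix")
}

#' Write / read a sparse-triplet text representation of A
#'
#' Three-column text format (`i`, `j`, `value`) over id labels, upper
#' triangle including the diagonal.
#'
#' @param A A `relatedness_matrix`.
#' @param path Output / input file path.
#' @return `write_A_triplets()` returns `path` invisibly;
#'   `read_A_triplets()` returns a `relatedness_matrix`.
#' @export
write_A_triplets <- function(A, path) {
  m <- as.matrix(A$A)
  keep <- which(upper.tri(m, diag = TRUE) & m != 0, arr.ind = TRUE)
  df <- data.frame(i = A$ids[keep[, 1]], j = A$ids[keep[, 2]],
                   value = m[keep], stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_A_triplets
#' @export
read_A_triplets <- function(path) {
  df <- utils::read.csv(path, colClasses = c("character", "character", "numeric"))
  ids <- unique(c(df$i, df$j))
  m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  m[cbind(match(df$i, ids), match(df$j, ids))] <- df$value
  m[cbind(match(df$j, ids), match(df$i, ids))] <- df$value
  structure(list(ids = ids, A = m), class = "relatedness_matrix")
}
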