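test_that("read_pedigree validates, deduplicates and adds implicit founders", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,sire,dam,cohort",
               "A,,,2000", "B,,,2000", "C,A,B,2005"), path)
  ped <- read_pedigree(path)
  expect_equal(nrow(ped), 3L)
  founders <- ped$id[is.na(ped$sire) & is.na(ped$dam)]
  expect_setequal(founders, c("A", "B"))

  # referenced-but-absent parent becomes an implicit founder
  writeLines(c("id,sire,dam,cohort",
               "A,,,2000", "B,,,2000", "C,X,B,2005"), path)
  ped <- read_pedigree(path)
  expect_equal(nrow(ped), 4L)
  expect_true("X" %in% ped$id)
  expect_true(is.na(ped$sire[ped$id == "X"]))

  # self-ancestry is a cycle
  writeLines(c("id,sire,dam,cohort", "C,C,,2005"), path)
  expect_error(read_pedigree(path), "cycle")

  # duplicate id with conflicting parents
  writeLines(c("id,sire,dam,cohort",
               "A,,,2000", "B,,,2000", "Z,,,2000",
               "C,A,B,2005", "C,A,Z,2005"), path)
  expect_error(read_pedigree(path), "conflicting")

  # parent cohort must precede offspring cohort
  writeLines(c("id,sire,dam,cohort",
               "A,,,2010", "B,,,2000", "C,A,B,2005"), path)
  expect_error(read_pedigree(path), "cohort")
})

test_that("topological sort puts parents first, is stable, detects cycles", {
  ped <- as_pedigree(data.frame(id = c("C", "A", "B"),
                                sire = c("A", NA, NA),
                                dam = c("B", NA, NA)))
  srt <- sort_pedigree(ped)
  expect_lt(which(srt$id == "A"), which(srt$id == "C"))
  expect_lt(which(srt$id == "B"), which(srt$id == "C"))

  chain <- as_pedigree(data.frame(id = c("A", "B", "C"),
                                  sire = c(NA, "A", "B"),
                                  dam = c(NA, NA, NA)))
  expect_equal(sort_pedigree(chain)$id, c("A", "B", "C"))
  # already sorted input is returned unchanged (stable ties)
  expect_equal(sort_pedigree(chain), chain)

  cyc <- data.frame(id = c("A", "B"), sire = c("B", "A"),
                    dam = c(NA, NA), cohort = NA_integer_)
  class(cyc) <- c("cram_pedigree", "data.frame")
  expect_error(sort_pedigree(cyc), "cycle.*A")
})

test_that("tabular A reproduces textbook relatednesses", {
  A <- make_A(sort_pedigree(trio_pedigree()))
  m <- as.matrix(A)
  expect_equal(m["A", "C"], 0.5)   # parent-offspring
  expect_equal(m["C", "C"], 1)

  sibs <- as_pedigree(data.frame(
    id = c("S", "D", "X", "Y", "H"),
    sire = c(NA, NA, "S", "S", "S"),
    dam = c(NA, NA, "D", "D", NA)))
  m <- as.matrix(make_A(sort_pedigree(sibs)))
  expect_equal(m["X", "Y"], 0.5)    # full sibs
  expect_equal(m["X", "H"], 0.25)   # half sibs

  # offspring of a full-sib mating is inbred: diagonal 1.25
  fsm <- as_pedigree(data.frame(
    id = c("S", "D", "X", "Y", "Z"),
    sire = c(NA, NA, "S", "S", "X"),
    dam = c(NA, NA, "D", "D", "Y")))
  m <- as.matrix(make_A(sort_pedigree(fsm)))
  expect_equal(m["Z", "Z"], 1.25)

  expect_error(make_A(trio_pedigree()[c(3, 1, 2), ]), "ordered")
})

test_that("A equals twice the recursive kinship on random pedigrees", {
  for (seed in 1:5) {
    ped <- random_pedigree(50L, seed)
    A <- as.matrix(make_A(ped))
    expect_equal(A, oracle_kinship_matrix(ped), tolerance = 1e-12)
  }
})

test_that("A is positive semidefinite on larger simulated pedigrees", {
  ped <- sort_pedigree(simulate_pedigree(120L, 3L, 2.5, seed = 21))
  expect_lte(nrow(ped), 900L)
  A <- make_A(ped)
  ev <- eigen(as.matrix(A), symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8)
})

test_that("link summaries count unordered nonzero pairs", {
  A <- make_A(sort_pedigree(trio_pedigree()))
  s <- summarize_links(A, threshold = 0.25)
  expect_equal(s$n_nonzero_pairs, 2L)
  expect_equal(s$proportion_ge_threshold, 1)

  founders <- as_pedigree(data.frame(id = c("A", "B"), sire = NA, dam = NA))
  s0 <- summarize_links(make_A(founders))
  expect_equal(s0$n_nonzero_pairs, 0L)
  expect_true(is.nan(s0$proportion_ge_threshold))
  expect_error(summarize_links(A, focal = character(0)), "non-empty")

  # dense brute-force recount on a simulated pedigree
  ped <- sort_pedigree(simulate_pedigree(40L, 2L, 2.2, seed = 9))
  A <- make_A(ped)
  m <- as.matrix(A)
  up <- m[upper.tri(m)]
  s <- summarize_links(A, threshold = 0.25)
  expect_equal(s$n_nonzero_pairs, sum(up != 0))
  expect_equal(s$proportion_ge_threshold, mean(up[up != 0] >= 0.25))
})

test_that("pruning drops unlinked focal individuals and is idempotent", {
  ped <- as_pedigree(data.frame(
    id = c("S", "D", "X", "Y", "L"),
    sire = c(NA, NA, "S", "S", NA),
    dam = c(NA, NA, "D", "D", NA)))
  A <- make_A(sort_pedigree(ped))
  kept <- prune_informative(c("X", "Y", "L", "NOPED"), A)
  expect_setequal(kept, c("X", "Y"))  # loner and non-pedigree id dropped
  expect_equal(prune_informative(kept, A), kept)
  # all-founder focal set collapses to nothing
  expect_equal(prune_informative(c("S", "L"), A), character(0))
})

test_that("Cholesky factor reconstructs A", {
  founders <- as_pedigree(data.frame(id = c("A", "B", "C"), sire = NA,
                                     dam = NA))
  L <- factor_A(make_A(founders))
  expect_equal(L, diag(3), ignore_attr = TRUE)

  A <- make_A(sort_pedigree(trio_pedigree()))
  L <- factor_A(A)
  expect_lt(max(abs(L %*% t(L) - as.matrix(A))), 1e-10)

  ped <- sort_pedigree(simulate_pedigree(60L, 3L, 2.2, seed = 4))
  A <- make_A(ped)
  L <- factor_A(A)
  expect_lt(max(abs(L %*% t(L) - as.matrix(A))), 1e-8)
})

test_that("pedigree A-inverse inverts A, including inbred pedigrees", {
  fsm <- sort_pedigree(as_pedigree(data.frame(
    id = c("S", "D", "X", "Y", "Z", "W"),
    sire = c(NA, NA, "S", "S", "X", NA),
    dam = c(NA, NA, "D", "D", "Y", NA))))
  A <- make_A(fsm)
  Ai <- make_Ainv(fsm, A)
  expect_lt(max(abs(as.matrix(Ai %*% A$A) - diag(nrow(fsm)))), 1e-10)

  ped <- sort_pedigree(simulate_pedigree(50L, 3L, 2.5, seed = 12))
  A <- make_A(ped)
  Ai <- make_Ainv(ped, A)
  expect_lt(max(abs(as.matrix(Ai %*% A$A) - diag(nrow(ped)))), 1e-8)
})

test_that("permuting A preserves spectra and is seed-deterministic", {
  ped <- sort_pedigree(simulate_pedigree(30L, 2L, 2.2, seed = 5))
  A <- make_A(ped)
  P1 <- permute_A(A, seed = 11)
  P2 <- permute_A(A, seed = 11)
  expect_equal(as.matrix(P1), as.matrix(P2))
  expect_equal(sort(unname(diag(as.matrix(P1)))),
               sort(unname(diag(as.matrix(A)))))
  ev <- function(m) sort(eigen(m, symmetric = TRUE, only.values = TRUE)$values)
  expect_equal(ev(as.matrix(P1)), ev(as.matrix(A)), tolerance = 1e-10)

  I3 <- make_A(as_pedigree(data.frame(id = c("A", "B", "C"), sire = NA,
                                      dam = NA)))
  expect_equal(as.matrix(permute_A(I3, 3)), as.matrix(I3))
})

test_that("triplet round trip preserves A", {
  A <- make_A(sort_pedigree(trio_pedigree()))
  path <- withr::local_tempfile(fileext = ".csv")
  write_A_triplets(A, path)
  A2 <- read_A_triplets(path)
  expect_equal(as.matrix(A2)[A$ids, A$ids], as.matrix(A))
})
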