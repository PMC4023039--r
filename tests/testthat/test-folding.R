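test_that("ensemble enumeration lists exactly the legal structures", {
  en <- enumerate_ensemble("AAAA")
  expect_equal(nrow(en), 1L)
  expect_equal(en$weight, 1)
  en2 <- enumerate_ensemble("GAAAC")
  expect_equal(nrow(en2), 2L)
  expect_setequal(vapply(en2$pairs, nrow, integer(1)), c(0L, 1L))
  # counts match an independent nesting recursion on random sequences
  set.seed(5)
  for (i in 1:15) {
    sq <- paste(sample(c("A", "C", "G", "U"), sample(6:14, 1), TRUE), collapse = "")
    expect_equal(nrow(enumerate_ensemble(sq)), count_structures(sq))
  }
  expect_error(enumerate_ensemble(strrep("A", 30)), "refused")
})

test_that("partition function reproduces closed-form and oracle probabilities", {
  b <- partition_bpp("AAAA")
  expect_true(all(b$p == 0))
  expect_equal(b$q, rep(1, 4))
  # two-structure ensemble: p15 = e^3 / (1 + e^3)
  b2 <- partition_bpp("GAAAC")
  expect_equal(b2$p[1, 5], exp(3) / (1 + exp(3)), tolerance = 1e-12)
  expect_error(partition_bpp("GXC"), "RNA string")
})

test_that("DP matches exhaustive enumeration within 1e-9 on random sequences", {
  set.seed(17)
  worst <- 0
  for (i in 1:40) {
    sq <- paste(sample(c("A", "C", "G", "U"), sample(5:20, 1), TRUE), collapse = "")
    o <- oracle_bpp(sq)
    d <- partition_bpp(sq)
    worst <- max(worst, max(abs(o$p - d$p)), max(abs(o$q - d$q)))
  }
  expect_lt(worst, 1e-9)
})

test_that("BPP normalisation holds on every input", {
  set.seed(23)
  for (i in 1:10) {
    sq <- paste(sample(c("A", "C", "G", "U"), sample(10:60, 1), TRUE), collapse = "")
    b <- partition_bpp(sq)
    expect_lt(max(abs(b$q + rowSums(b$p) - 1)), 1e-12)
    expect_true(isSymmetric(b$p))
    expect_true(all(b$p >= 0 & b$p <= 1))
  }
})

test_that("MFE structure is a minimum with deterministic tie-breaking", {
  expect_equal(nrow(mfe_structure("AAAA")$pairs), 0L)
  m <- mfe_structure("GGGAAACCC")
  expect_equal(dotbracket_string(m), "(((...)))")
  expect_equal(attr(m, "energy"), 3 * (-3) + 2 * (-1))
  # enumeration confirms minimality on random sequences
  set.seed(41)
  for (i in 1:15) {
    sq <- paste(sample(c("A", "C", "G", "U"), sample(6:16, 1), TRUE), collapse = "")
    en <- enumerate_ensemble(sq)
    expect_equal(attr(mfe_structure(sq), "energy"), min(en$energy))
  }
  # engineered tie: C AAA G AAA C has two single-pair minima; the
  # tie-break takes the lexicographically smallest pair set
  sq <- "CAAAGAAAC"
  en <- enumerate_ensemble(sq)
  minima <- en$pairs[abs(en$energy - min(en$energy)) < 1e-9]
  expect_gt(length(minima), 1)
  expect_equal(unname(mfe_structure(sq)$pairs), cbind(1L, 5L))
})

test_that("morphospace statistics match hand computations", {
  st <- morphospace_stats(c(a = "AAAA"))
  expect_equal(st$Q, 0)
  expect_equal(st$P, 0)
  expect_equal(st$S, 0)
  st2 <- morphospace_stats(c(a = "GGGAAACCC"))
  expect_equal(st2$P, 6 / 9)
  expect_equal(st2$S, 3)
  # closed-form entropy of the two-structure GAAAC ensemble
  p <- exp(3) / (1 + exp(3))
  q <- 1 - p
  hand_Q <- -(p * log2(p) +                       # the pair term
              (3 * 1 * log2(1) * 0 +              # three always-unpaired sites
               2 * q * log2(q))) / 5              # ends unpaired with prob q
  st3 <- morphospace_stats(c(a = "GAAAC"))
  expect_equal(st3$Q, hand_Q, tolerance = 1e-12)
})

test_that("Q is zero exactly for single-structure ensembles", {
  expect_equal(morphospace_stats(c(x = "AAAAAA"))$Q, 0)
  expect_gt(morphospace_stats(c(x = "GAAAC"))$Q, 0)
})

test_that("statistics are invariant to name and row order", {
  seqs <- tibble::tibble(name = c("m1", "m2"),
                         sequence = c("GGGAAACCC", "GCAAAAGC"))
  a <- morphospace_stats(seqs)
  b <- morphospace_stats(seqs[2:1, ])
  expect_equal(dplyr::arrange(a, name), dplyr::arrange(b, name))
})

test_that("per-region statistics restrict to the template ranges", {
  scaf <- trna_scaffold()
  st <- morphospace_stats(tibble::tibble(name = "scaf", sequence = scaf$sequence),
                          template = cloverleaf_template())
  expect_setequal(unique(st$region),
                  c("all", "acceptor", "d_arm", "anticodon_arm",
                    "variable_loop", "t_arm"))
  expect_true(all(st$P >= 0 & st$P <= 1))
  expect_true(all(st$Q >= 0))
  # weighted variant stays in range and differs from MFE-based P in general
  stw <- morphospace_stats(tibble::tibble(name = "scaf", sequence = scaf$sequence),
                           weighted = TRUE)
  expect_true(all(stw$P >= 0 & stw$P <= 1))
})
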