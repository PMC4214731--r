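test_that("one-sided Fisher matches hand-enumerated hypergeometric tails", {
  expect_equal(fisherExactOneSided(matrix(c(3, 1, 1, 3), 2, byrow = TRUE)),
               17 / 70, tolerance = 1e-12)
  expect_equal(fisherExactOneSided(matrix(c(0, 5, 0, 7), 2, byrow = TRUE)),
               1.0)
  expect_equal(fisherExactOneSided(matrix(c(4, 0, 0, 4), 2, byrow = TRUE)),
               1 / 70, tolerance = 1e-12)
  expect_error(fisherExactOneSided(matrix(c(-1, 1, 1, 1), 2)),
               "non-negative")
})

test_that("Fisher tail matches full enumeration over fixed margins", {
  # independent oracle: enumerate every table with the observed margins
  enumTail <- function(a, b, c, d) {
    r1 <- a + b; c1 <- a + c; n <- a + b + c + d
    ks <- max(0, c1 - (n - r1)):min(r1, c1)
    p <- exp(lchoose(r1, ks) + lchoose(n - r1, c1 - ks) - lchoose(n, c1))
    sum(p[ks >= a])
  }
  withr::with_seed(3, for (i in 1:50) {
    m <- matrix(sample(0:15, 4, replace = TRUE), 2)
    expect_equal(fisherExactOneSided(m),
                 enumTail(m[1, 1], m[1, 2], m[2, 1], m[2, 2]),
                 tolerance = 1e-10)
  })
})

test_that("coverage reports build the right table, fraction and p-value", {
  mkPairs <- function(keys) {
    parts <- strsplit(keys, "_", fixed = TRUE)
    data.frame(drug = vapply(parts, `[[`, "", 1L),
               disease = vapply(parts, `[[`, "", 2L))
  }
  u <- mkPairs(paste0("d", 1:20, "_p1"))
  pred <- u[1:10, ]; val <- u[c(1, 2, 3, 15), ]
  rep <- coverageReport(pred, val, u)
  expect_equal(rep$coverage, 3 / 4)
  expect_equal(as.vector(rep$table), c(3, 1, 7, 9))  # column-major
  expect_equal(rep$pValue,
               fisherExactOneSided(matrix(c(3, 7, 1, 9), 2, byrow = TRUE)))

  full <- coverageReport(u, u, u)
  expect_equal(full$coverage, 1.0)
  expect_equal(full$pValue, 1.0)
  disjoint <- coverageReport(u[1:5, ], u[6:9, ], u)
  expect_equal(disjoint$coverage, 0.0)
  expect_error(coverageReport(mkPairs("dX_p9"), val, u), "universe")
})

test_that("coverage p-value is invariant under universe relabeling", {
  u <- data.frame(drug = rep(sprintf("d%d", 1:6), each = 3),
                  disease = rep(sprintf("p%d", 1:3), 6))
  pred <- u[c(1, 4, 7, 10), ]; val <- u[c(1, 4, 13), ]
  base <- coverageReport(pred, val, u)
  perm <- withr::with_seed(2, sample.int(nrow(u)))
  relab <- function(df) {
    key <- paste(u$drug, u$disease)
    idx <- match(paste(df$drug, df$disease), key)
    data.frame(drug = sprintf("D%02d", perm[idx]), disease = "x")
  }
  moved <- coverageReport(relab(pred), relab(val), relab(u))
  expect_equal(moved$pValue, base$pValue)
  expect_equal(moved$coverage, base$coverage)
})

test_that("Tanimoto similarity behaves as set overlap", {
  expect_equal(tanimoto(c(1, 5, 9), c(1, 5, 9)), 1.0)
  expect_equal(tanimoto(1:3, 4:6), 0.0)
  expect_equal(tanimoto(1:3, 2:4), 0.5)
  expect_equal(tanimoto(2:4, 1:3), 0.5)      # symmetric
  expect_error(tanimoto(integer(), integer()), "non-empty")
  # equality iff identical sets
  expect_lt(tanimoto(1:3, 1:4), 1.0)
})

test_that("fraction-similar screens pairs at a strict threshold", {
  fps <- list(a = 1:10, b = 1:10, c = 11:20, d = c(1:7, 11:13))
  pairs <- data.frame(x = c("a", "a", "c", "a"), y = c("b", "c", "d", "d"))
  # a-b: 1.0 (> 0.7); a-c: 0; c-d: 3/17; a-d: 7/13 -> one of four passes
  expect_equal(fractionSimilar(pairs, fps), 0.25)
  expect_equal(fractionSimilar(pairs, fps, threshold = 0), 0.75)
  expect_error(fractionSimilar(data.frame(x = "a", y = "zz"), fps),
               "missing fingerprint")
})

test_that("fingerprint files parse in both dialects", {
  f <- tempfile()
  writeLines(c("# drug\tbits", "d1\t1,5,9", "d2\t2,3"), f)
  fps <- readFingerprints(f)
  expect_equal(fps$d1, c(1L, 5L, 9L))
  fh <- tempfile()
  writeLines("d1\ta1", fh)          # 1010 0001 -> bits 1, 3, 8
  expect_equal(readFingerprints(fh, hex = TRUE)$d1, c(1L, 3L, 8L))
})
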