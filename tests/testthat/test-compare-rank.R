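test_that("CI overlap decides distinguishability and grouping", {
  r <- rank_tissues(list(fake_estimate("a", 1, 2), fake_estimate("b", 3, 4)))
  expect_true(r$distinguishable["a", "b"])
  expect_length(r$groups, 2)
  expect_identical(r$table$tissue, c("a", "b"))

  r2 <- rank_tissues(list(fake_estimate("a", 1, 3), fake_estimate("b", 2, 4)))
  expect_false(r2$distinguishable["a", "b"])
  expect_length(r2$groups, 1)

  # matrix is symmetric with a false diagonal, and ordering is by geometric
  # midpoint
  ests <- list(fake_estimate("x", 4, 9), fake_estimate("y", 0.5, 2),
               fake_estimate("z", 1, 30))
  r3 <- rank_tissues(ests)
  expect_true(isSymmetric(r3$distinguishable))
  expect_false(any(diag(r3$distinguishable)))
  expect_identical(r3$table$tissue,
                   c("y", "z", "x")) # midpoints 1, 5.48, 6
})

test_that("a constructed seven-tissue fixture reproduces the three-block
           grouping", {
  blocks <- list(
    SI = c(0.6, 1.1),
    BM = c(2.8, 4.0), Sp = c(3.0, 4.3),
    Kd = c(9, 13), Lv = c(10, 14.5), Lg = c(11, 16), GS = c(12, 17)
  )
  ests <- lapply(names(blocks), function(t) {
    fake_estimate(t, blocks[[t]][1], blocks[[t]][2])
  })
  r <- rank_tissues(ests)
  g <- lapply(r$groups, sort)
  expect_length(g, 3)
  expect_identical(g[[1]], "SI")
  expect_identical(g[[2]], c("BM", "Sp"))
  expect_identical(g[[3]], sort(c("Kd", "Lv", "Lg", "GS")))
})

test_that("ranking rejects mixed endpoints and is permutation invariant", {
  e1 <- fake_estimate("a", 1, 2)
  e2 <- fake_estimate("b", 3, 4, endpoint = "mn_ret")
  expect_error(rank_tissues(list(e1, e2)), "mixed endpoints")

  ests <- lapply(1:5, function(i) fake_estimate(letters[i], i, i + 1.5))
  r1 <- rank_tissues(ests)
  r2 <- rank_tissues(rev(ests))
  expect_identical(r1$table, r2$table)
  expect_identical(r1$groups, r2$groups)
})

test_that("cross-endpoint comparison sorts by midpoint and reports the
           maximum-response parameter only for saturating models", {
  ests <- list(
    fake_estimate("bm", 0.08, 0.2, endpoint = "dna_adducts",
                  params = list(a = 1, b = 2, c = 200)),
    fake_estimate("bm", 250, 400, endpoint = "mn_ret", model_id = "m2",
                  params = list(a = 1, b = 0.01)),
    fake_estimate("bm", 2, 5, endpoint = "lacz_mf",
                  params = list(a = 1, b = 0.1, c = 8))
  )
  cmp <- compare_endpoints(ests)
  expect_identical(cmp$endpoint, c("dna_adducts", "lacz_mf", "mn_ret"))
  expect_equal(cmp$max_response_c, c(200, 8, NA))
})

test_that("exact proportionality is recovered with the unity slope accepted,
           and the offset matches a brute-force one-parameter fit", {
  bx <- c(0.05, 0.12, 0.2, 0.5, 1.5, 4, 9)
  tis <- paste0("t", 1:7)
  ex <- Map(function(t, b) fake_estimate(t, b / 1.3, b * 1.3,
                                         endpoint = "dna_adducts", bmd = b),
            tis, bx)
  ey <- Map(function(t, b) fake_estimate(t, b / 1.2, b * 1.2, bmd = b),
            tis, 3 * bx)
  pr <- proportionality(ex, ey)
  expect_equal(pr$proportionality_constant, 3.0, tolerance = 1e-10)
  expect_equal(pr$slope_free, 1.0, tolerance = 1e-10)
  expect_true(pr$unity_adequate)

  # brute-force 1-parameter least squares over the offset
  lx <- log10(bx); ly <- log10(3 * bx)
  oracle <- optimize(function(o) sum((ly - lx - o)^2), c(-5, 5),
                     tol = 1e-12)$minimum
  expect_equal(pr$log10_offset, oracle, tolerance = 1e-6)

  # scale equivariance: dividing every bmd_x by k multiplies the constant
  ex_k <- Map(function(t, b) fake_estimate(t, b / 1.3, b * 1.3,
                                           endpoint = "dna_adducts", bmd = b),
              tis, bx / 10)
  pr_k <- proportionality(ex_k, ey)
  expect_equal(pr_k$proportionality_constant, 30, tolerance = 1e-8)
  expect_equal(pr_k$slope_free, pr$slope_free, tolerance = 1e-8)
})

test_that("a true slope of two on the double-log scale rejects unity", {
  set.seed(27)
  bx <- 10^seq(-1.2, 1.0, length.out = 7)
  tis <- paste0("t", 1:7)
  rejections <- 0
  for (i in 1:20) {
    by <- 10^(2 * log10(bx) + rnorm(7, 0, 0.02))
    ex <- Map(function(t, b) fake_estimate(t, b / 1.2, b * 1.2,
                                           endpoint = "dna_adducts", bmd = b),
              tis, bx)
    ey <- Map(function(t, b) fake_estimate(t, b / 1.2, b * 1.2, bmd = b),
              tis, by)
    pr <- proportionality(ex, ey)
    rejections <- rejections + !pr$unity_adequate
  }
  expect_gte(rejections, 19)
  expect_error(proportionality(list(fake_estimate("a", 1, 2)),
                               list(fake_estimate("b", 1, 2))),
               "unmatched|tissue-matched|pairs")
})

test_that("Ki-67 correlation handles the exact, degenerate and small-sample
           cases", {
  tis <- c("liver", "lung", "small_intestine")
  ki <- c(liver = 1, lung = 4, small_intestine = 12)
  ex <- Map(function(t, b) fake_estimate(t, b * 0.9, b * 1.1,
                                         endpoint = "dna_adducts", bmd = b),
            tis, ki / 100) # ratio bmd_x / bmd_y exactly proportional to ki67
  ey <- Map(function(t) fake_estimate(t, 0.9, 1.1, bmd = 1), tis)
  res <- ki67_correlation(ki, ex, ey)
  expect_equal(res$r, 1.0, tolerance = 1e-10)
  expect_match(res$caveat, "3 tissues")

  ex_const <- Map(function(t) fake_estimate(t, 0.9, 1.1, bmd = 1,
                                            endpoint = "dna_adducts"), tis)
  res2 <- ki67_correlation(ki, ex_const, ey)
  expect_true(res2$degenerate)
  expect_true(is.na(res2$r))

  expect_error(ki67_correlation(ki[1:2], ex[1:2], ey[1:2]), "at least 3")

  # permuting the Ki-67 labels destroys the alignment on average
  set.seed(3)
  rs <- replicate(100, {
    ki_p <- stats::setNames(sample(ki), names(ki))
    ki67_correlation(ki_p, ex, ey)$r
  })
  expect_lt(mean(abs(rs)), 0.999)
})
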