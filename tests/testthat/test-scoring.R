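test_that("normalization scales to the median library and log-transforms", {
  # equal libraries: scaling is the identity, every entry log1p(count)
  m <- matrix(3, 4, 5, dimnames = list(paste0("s", 1:4), paste0("g", 1:5)))
  expect_equal(unname(as.matrix(normalize_counts(m))),
               matrix(log1p(3), 4, 5))

  # a spot with a doubled library normalizes onto the reference spot
  ref <- c(2, 4, 0, 6)
  m2 <- rbind(s1 = ref, s2 = 2 * ref, s3 = ref)
  colnames(m2) <- paste0("g", 1:4)
  n2 <- as.matrix(normalize_counts(m2))
  expect_lt(max(abs(n2["s2", ] - n2["s1", ])), 1e-9)

  # zero-count spot is dropped with a warning
  m3 <- rbind(m2, s4 = c(0, 0, 0, 0))
  expect_warning(n3 <- normalize_counts(m3), "zero total counts")
  expect_equal(nrow(n3), 3)
})

test_that("module score equals the mean of per-gene z-scores", {
  set.seed(42)
  n <- 80; g <- 30
  m <- matrix(rpois(n * g, 4), n, g,
              dimnames = list(sprintf("s%02d", 1:n), sprintf("g%02d", 1:g)))
  norm <- normalize_counts(m)
  sig <- sample(colnames(m), 20)

  # brute-force oracle: z-score each gene independently, then average
  oracle <- rowMeans(sapply(sig, function(gn) {
    v <- as.numeric(norm[, gn])
    if (sd(v) == 0) rep(0, n) else (v - mean(v)) / sd(v)
  }))
  got <- module_score(norm, sig, "random20")
  expect_equal(unname(as.numeric(got)), unname(oracle), tolerance = 1e-12)

  # singleton signature is the z-score of that gene
  g1 <- sig[1]
  z1 <- (as.numeric(norm[, g1]) - mean(norm[, g1])) / sd(norm[, g1])
  expect_equal(unname(as.numeric(module_score(norm, g1, "one"))), z1,
               tolerance = 1e-12)

  # a constant gene contributes 0 everywhere (zero variance => z defined as 0)
  nc <- cbind(as.matrix(norm), flat = 2)
  s_with <- module_score(nc, c(g1, "flat"), "withflat")
  expect_equal(unname(as.numeric(s_with)), z1 / 2, tolerance = 1e-12)

  # invariant to genes absent from the matrix
  expect_message(s_extra <- module_score(norm, c(sig, "NOT_A_GENE"), "x"),
                 "absent")
  expect_equal(as.numeric(s_extra), as.numeric(got))
  expect_error(module_score(norm, c("NOPE1", "NOPE2"), "ghost"), "ghost")
})

test_that("control-bin mode subtracts matched controls deterministically", {
  set.seed(7)
  m <- matrix(rpois(100 * 60, 3), 100, 60,
              dimnames = list(sprintf("s%03d", 1:100), sprintf("g%02d", 1:60)))
  norm <- normalize_counts(m)
  sig <- colnames(m)[1:5]
  a <- module_score(norm, sig, "s", mode = "control_bins", seed = 3)
  b <- module_score(norm, sig, "s", mode = "control_bins", seed = 3)
  expect_identical(as.numeric(a), as.numeric(b))
  plain <- module_score(norm, sig, "s")
  expect_false(isTRUE(all.equal(as.numeric(a), as.numeric(plain))))
})

test_that("quartile tiers follow the stated percentile rule", {
  v <- setNames(c(1, 2, 3, 4), paste0("s", 1:4))
  expect_identical(unname(tier_quartiles(v)$tiers), 0:3)

  # constant vector: every value <= Q1, all tier 0
  vc <- setNames(rep(2.5, 10), paste0("s", 1:10))
  expect_true(all(tier_quartiles(vc)$tiers == 0L))

  # 1000 uniforms: each tier holds 250 +/- 1
  set.seed(11)
  vu <- setNames(runif(1000), sprintf("s%04d", 1:1000))
  tt <- table(tier_quartiles(vu)$tiers)
  expect_true(all(abs(tt - 250) <= 1))

  expect_error(tier_quartiles(setNames(1:3, c("a", "b", "c"))), "at least 4")
})

test_that("tiers match a sort-and-threshold oracle and are monotone", {
  for (seed in 1:100) {
    set.seed(seed)
    n <- sample(10:200, 1)
    v <- setNames(rnorm(n), sprintf("s%03d", 1:n))
    got <- tier_quartiles(v)
    ora <- oracle_tiers(as.numeric(v))
    expect_identical(unname(got$tiers), as.integer(ora$tiers))
    expect_equal(unname(got$thresholds), ora$thresholds)
    # monotone: v_i <= v_j => tier_i <= tier_j
    o <- order(v)
    expect_true(all(diff(got$tiers[o]) >= 0))
  }
})

test_that("tiering respects an explicit scope", {
  v <- setNames(c(0, 0, 0, 1, 2, 3, 4), paste0("s", 1:7))
  tv <- tier_quartiles(v, scope = paste0("s", 4:7))
  expect_identical(unname(tv$tiers), 0:3)
  expect_identical(names(tv$tiers), paste0("s", 4:7))
  expect_error(tier_quartiles(v, scope = c("s4", "zz")), "absent")
})

test_that("IHC semi-quantitative score multiplies density and intensity bins", {
  expect_identical(ihc_score(100, "strong"), 16L)
  expect_identical(ihc_score(10, "negative"), 1L)
  expect_identical(ihc_score(40, "moderate"), 6L)

  # full image over the 16 bin combinations
  grid <- expand.grid(d = c(10, 30, 60, 90),
                      i = c("negative", "weak", "moderate", "strong"),
                      stringsAsFactors = FALSE)
  img <- ihc_score(grid$d, grid$i)
  expect_setequal(img, c(1L, 2L, 3L, 4L, 6L, 8L, 9L, 12L, 16L))
  expect_identical(range(img), c(1L, 16L))

  expect_error(ihc_score(101, "weak"), "\\[0, 100\\]")
  expect_error(ihc_score(-1, "weak"), "\\[0, 100\\]")
  expect_error(ihc_score(50, "faint"), "intensity")
})
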