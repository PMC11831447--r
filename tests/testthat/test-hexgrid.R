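test_that("hex neighbourhoods have the lattice-forced sizes", {
  st <- make_lattice(9, 18)
  interior <- st$spot_id[st$array_row == 4 & st$array_col == 8]
  expect_length(hex_neighbors(st, interior, k = 1), 6)
  expect_length(hex_neighbors(st, interior, k = 2), 18)

  corner <- st$spot_id[st$array_row == 0 & st$array_col == 0]
  expect_length(hex_neighbors(st, corner, k = 1), 2)
  edge <- st$spot_id[st$array_row == 0 & st$array_col == 4]
  expect_length(hex_neighbors(st, edge, k = 1), 4)

  expect_error(hex_neighbors(st, "nope"), "unknown spot")
})

test_that("hex adjacency is symmetric and matches a Euclidean oracle", {
  for (seed in 1:20) {
    set.seed(seed)
    st <- make_lattice(sample(4:7, 1), 2 * sample(4:7, 1))
    st <- st[sample(nrow(st), ceiling(0.8 * nrow(st))), ]   # ragged tissue
    pitch <- 100
    ids <- st$spot_id
    nb <- lapply(ids, function(s) hex_neighbors(st, s, k = 1))
    names(nb) <- ids
    for (i in seq_along(ids)) {
      # Euclidean oracle: neighbours are spots within 1.2 * pitch
      d <- sqrt((st$x - st$x[i])^2 + (st$y - st$y[i])^2)
      ora <- ids[d > 0 & d < 1.2 * pitch]
      expect_setequal(nb[[i]], ora)
      for (j in nb[[i]]) expect_true(ids[i] %in% nb[[j]])
    }
  }
})

test_that("co-localization products obey the tier algebra exhaustively", {
  # pairwise: all 16 combinations
  g2 <- expand.grid(a = 0:3, b = 0:3)
  ids <- sprintf("p%02d", seq_len(nrow(g2)))
  cm2 <- coloc(fake_tiers(g2$a, ids), fake_tiers(g2$b, ids))
  expect_identical(unname(cm2$product), as.integer(g2$a * g2$b))
  expect_true(all(cm2$product %in% c(0L, 1L, 2L, 3L, 4L, 6L, 9L)))
  expect_true(all(cm2$product[g2$a == 0 | g2$b == 0] == 0L))
  expect_identical(max(cm2$product), 9L)
  expect_identical(cm2$product[[which(g2$a == 3 & g2$b == 3)]], 9L)

  # triple: all 64 combinations
  g3 <- expand.grid(a = 0:3, b = 0:3, c = 0:3)
  ids3 <- sprintf("q%02d", seq_len(nrow(g3)))
  cm3 <- coloc(fake_tiers(g3$a, ids3), fake_tiers(g3$b, ids3),
               fake_tiers(g3$c, ids3))
  expect_identical(unname(cm3$product), as.integer(g3$a * g3$b * g3$c))
  expect_true(all(cm3$product >= 0L & cm3$product <= 27L))
  expect_identical(cm3$product[[which(g3$a == 2 & g3$b == 3 & g3$c == 1)]], 6L)

  # monotone non-decreasing in each component tier
  for (lvl in 0:2) {
    expect_true(all(cm3$product[g3$a == lvl + 1 & g3$b == 3 & g3$c == 3] >=
                    cm3$product[g3$a == lvl & g3$b == 3 & g3$c == 3]))
  }

  expect_error(coloc(fake_tiers(0:3)), "2 or 3")
  expect_error(coloc(fake_tiers(0:3, letters[1:4]), fake_tiers(0:3, letters[5:8])),
               "scope")
})

test_that("enriched spots are the top-quartile tier within an optional mask", {
  vc <- setNames(rep(1, 8), sprintf("s%d", 1:8))
  expect_length(enriched_spots(tier_quartiles(vc)), 0)

  set.seed(2)
  vu <- setNames(runif(1000), sprintf("u%04d", 1:1000))
  es <- enriched_spots(tier_quartiles(vu))
  expect_true(abs(length(es) - 250) <= 1)
  expect_length(enriched_spots(tier_quartiles(vu), mask = character(0)), 0)
  masked <- enriched_spots(tier_quartiles(vu), mask = es[1:10])
  expect_setequal(masked, es[1:10])
})

test_that("neighbourhood correlation handles degenerate and permuted input", {
  st <- make_lattice(6, 12)
  ids <- st$spot_id
  set.seed(3)
  fs <- setNames(rnorm(length(ids)), ids)
  resp <- setNames(rep(2, length(ids)), ids)
  focal <- ids[1:10]
  expect_warning(r0 <- neighborhood_correlation(focal, fs, resp, st, B = 99),
                 "zero variance")
  expect_true(is.na(r0$rho))
  expect_true(all(r0$table$neighborhood_mean[r0$table$n_neighbors_used > 0] == 2))

  resp2 <- setNames(rnorm(length(ids)), ids)
  a <- neighborhood_correlation(focal, fs, resp2, st, B = 199, seed = 7)
  b <- neighborhood_correlation(rev(focal), fs, resp2, st, B = 199, seed = 7)
  expect_equal(a$rho, b$rho)
  expect_equal(a$p_perm, b$p_perm)

  # invariant to spots outside the mask
  m1 <- neighborhood_correlation(focal, fs, resp2, st, B = 99, seed = 1,
                                 neighbor_mask = ids[1:40])
  m2 <- neighborhood_correlation(focal, fs, resp2[1:40], st, B = 99, seed = 1,
                                 neighbor_mask = ids[1:40])
  expect_equal(m1$rho, m2$rho)

  expect_error(neighborhood_correlation(character(0), fs, resp2, st), "empty")
  expect_error(neighborhood_correlation(focal, fs, resp2, st,
                                        neighbor_mask = character(0)),
               "eligible")
  expect_equal(max(a$table$n_neighbors_used), 6)   # <= 6k for k = 1
})
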