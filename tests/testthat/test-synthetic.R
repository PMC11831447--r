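test_that("generation is deterministic given the config and seeded otherwise", {
  a <- simulate_visium(small_config(seed = 5))
  b <- simulate_visium(small_config(seed = 5))
  expect_identical(as.matrix(a$counts), as.matrix(b$counts))
  expect_identical(a$truth, b$truth)

  c2 <- simulate_visium(small_config(seed = 6))
  expect_false(identical(as.matrix(a$counts), as.matrix(c2$counts)))
  # same planted architecture, different draws
  expect_identical(a$truth$region, c2$truth$region)
  expect_identical(a$truth$niche_id, c2$truth$niche_id)
})

test_that("planted truth satisfies its structural invariants", {
  sim <- simulate_visium(small_config(seed = 1))
  tr <- sim$truth
  expect_identical(is.na(tr$niche_id), is.na(tr$layer_depth))
  expect_true(all(tr$region[tr$triad] == "stroma"))
  expect_true(all(tr$layer_depth >= 1, na.rm = TRUE))

  # proliferation mean non-increasing in depth within each niche
  for (k in unique(na.omit(tr$niche_id))) {
    sub <- tr[!is.na(tr$niche_id) & tr$niche_id == k, ]
    mins <- tapply(sub$prolif_mu, sub$layer_depth, min)
    maxs <- tapply(sub$prolif_mu, sub$layer_depth, max)
    d <- as.integer(names(mins))
    for (i in seq_along(d)[-1]) {
      expect_gte(mins[[i - 1]], maxs[[i]])
    }
  }

  # spot table is a valid pseudo-hex lattice with recoverable pitch
  expect_s3_class(sim$spots, "spot_table")
  expect_equal(spot_pitch(sim$spots), 100, tolerance = 0.01)

  # signatures are exactly the planted module gene lists, all in the matrix
  expect_true(all(unlist(sim$signatures) %in% colnames(sim$counts)))
  expect_named(sim$signatures, c("tumor_marker", "hepatocyte", "fibro",
                                 "endo", "spp1_mac", "prolif"))
})

test_that("every stroma spot is within reach of a niche or the interface", {
  cfg <- sim_config(seed = 2)
  sim <- simulate_visium(cfg)
  tr <- sim$truth
  st <- sim$spots
  half <- cfg$grid_cols %/% 2
  niche_rows <- which(!is.na(tr$niche_id))
  stroma_rows <- which(tr$region == "stroma")
  # oracle: explicit hex distances to every niche spot / the interface line
  for (i in stroma_rows[seq(1, length(stroma_rows), by = 7)]) {
    d_niche <- min(hex_distance(st$array_row[i], st$array_col[i],
                                st$array_row[niche_rows], st$array_col[niche_rows]))
    d_iface <- (st$array_col[i] - half) %/% 2 + 1
    expect_lte(min(d_niche, d_iface), cfg$stroma_width)
  }
})

test_that("negative-binomial moments match the formula on background genes", {
  cfg <- sim_config(seed = 3)
  sim <- simulate_visium(cfg)
  bg <- as.matrix(sim$counts[, sprintf("BG%04d", 1:10)])   # 36k spot-gene pairs
  mu <- cfg$baseline_mean
  v_expect <- mu + mu^2 / cfg$nb_dispersion
  expect_lt(abs(mean(bg) - mu) / mu, 0.05)
  expect_lt(abs(var(as.numeric(bg)) - v_expect) / v_expect, 0.15)
})

test_that("the planted gradient puts the strongest proliferation at the rim", {
  sim <- simulate_visium(sim_config(gradient_beta = 0.5, seed = 4))
  tr <- sim$truth
  for (k in unique(na.omit(tr$niche_id))) {
    sub <- tr[!is.na(tr$niche_id) & tr$niche_id == k, ]
    m <- tapply(sub$prolif_mu, sub$layer_depth, mean)
    expect_gt(m[["1"]], m[[as.character(max(sub$layer_depth))]])
  }
})

test_that("a null configuration plants no expression structure", {
  # module_fold = 1, no gradient, no coupling: truth labels exist but genes
  # are exchangeable between regions
  pvals <- sapply(0:19, function(s) {
    sim <- simulate_visium(small_config(seed = s, module_fold = 1,
                                        gradient_beta = 0, coupling_rho = 0))
    norm <- normalize_counts(sim$counts)
    sc <- module_score(norm, sim$signatures$tumor_marker, "tm")
    tum <- sim$truth$spot_id[sim$truth$region == "tumor_side"]
    non <- sim$truth$spot_id[sim$truth$region == "non_tumor_side"]
    t.test(sc[intersect(tum, names(sc))], sc[intersect(non, names(sc))])$p.value
  })
  expect_lte(sum(pvals < 0.01), 2)   # at most binomial noise at alpha = 0.01
})

test_that("invalid or degenerate configurations are handled", {
  expect_error(sim_config(grid_rows = 20, grid_cols = 40, niche_radius = 12),
               "overlap|fit")
  sim0 <- simulate_visium(small_config(n_niches = 0))
  expect_true(all(is.na(sim0$truth$niche_id)))
  expect_true(all(sim0$truth$region[sim0$truth$spot_id %in%
    sim0$spots$spot_id[sim0$spots$array_col >= 24]] == "stroma"))
})
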