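# Small fixtures built in code.

# filled hex disk of radius R as a spot table (pitch 100)
make_disk <- function(R, r0 = R + 2, c0 = NULL) {
  if (is.null(c0)) c0 <- 2 * R + 2 + ((2 * R + 2 + r0) %% 2)
  rows <- integer(0); cols <- integer(0)
  for (r in (r0 - R):(r0 + R)) {
    for (cc in seq(c0 - 2 * R, c0 + 2 * R)) {
      if ((r %% 2) != (cc %% 2)) next
      if (hex_distance(r, cc, r0, c0) <= R) {
        rows <- c(rows, r); cols <- c(cols, cc)
      }
    }
  }
  spot_table(sprintf("d%03d", seq_along(rows)), rows, cols,
             x = cols * 50, y = rows * 50 * sqrt(3))
}

# full rectangular pseudo-hex lattice
make_lattice <- function(nrow, ncol2) {
  rows <- integer(0); cols <- integer(0)
  for (r in 0:(nrow - 1)) {
    cc <- seq(r %% 2, ncol2 - 2 + r %% 2, by = 2)
    rows <- c(rows, rep(r, length(cc)))
    cols <- c(cols, cc)
  }
  spot_table(sprintf("s%04d", seq_along(rows)), rows, cols,
             x = cols * 50, y = rows * 50 * sqrt(3))
}

# small random dataset for I/O round-trips
random_dataset <- function(seed, n_row = 6, n_col2 = 10, n_genes = 12) {
  set.seed(seed)
  st <- make_lattice(n_row, n_col2)
  st$spot_id <- sprintf("BC%04d-%d", seq_len(nrow(st)), seed %% 10)
  st$in_tissue <- runif(nrow(st)) > 0.1
  st$x <- st$x + rnorm(nrow(st), sd = 1e-3)   # exercise float round-trip
  counts <- matrix(rpois(nrow(st) * n_genes, 1.5), nrow(st), n_genes,
                   dimnames = list(st$spot_id, sprintf("G%03d", seq_len(n_genes))))
  list(counts = Matrix::Matrix(counts, sparse = TRUE), spots = st)
}

# quick generator config: smaller lattice, one niche, everything else default
small_config <- function(seed = 0, ...) {
  args <- list(grid_rows = 24, grid_cols = 48, n_niches = 1, niche_radius = 3,
               stroma_width = 12, n_genes_background = 60,
               module_genes = c(tumor_marker = 8, hepatocyte = 8, fibro = 8,
                                endo = 8, spp1_mac = 8, prolif = 8),
               seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

# constructed tier_vector with given integer tiers (bypasses quartiles)
fake_tiers <- function(tiers, ids = sprintf("t%02d", seq_along(tiers))) {
  structure(list(tiers = stats::setNames(as.integer(tiers), ids),
                 thresholds = c(Q1 = 0.5, Q2 = 1.5, Q3 = 2.5)),
            class = "tier_vector")
}
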