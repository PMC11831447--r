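#' Configuration for the synthetic leading-edge Visium generator
#'
#' Defines the planted architecture: a pseudo-hex lattice whose left half is
#' non-tumor (hepatocyte-marker dominated) and whose right half is the tumor
#' side, containing compact tumor niches (hex disks of `niche_radius`)
#' encircled by a stromal ring of `stroma_width` hex steps; a stromal band of
#' the same width runs along the tumor/non-tumor interface. A `triad_fraction`
#' subset of stroma spots additionally carries an SPP1+ macrophage signal of
#' latent strength `u ~ Uniform(0, 1)`; the proliferation mean of their ring-1
#' niche neighbours is multiplied by `module_fold^(coupling_rho * u)`,
#' planting a positive focal/neighbourhood association (no boost when
#' `coupling_rho = 0`). Within each niche the
#' proliferation mean decays from the rim inward as
#' `baseline_mean * (1 + (module_fold - 1) * exp(-gradient_beta * (depth - 1)))`.
#' Counts are negative binomial with `variance = mean + mean^2 / nb_dispersion`.
#'
#' The stromal compartment is every tumor-side spot within `stroma_width`
#' hex steps of a niche or of the interface. The default width (15) makes
#' the stroma an extended field dispersing between and around the niches,
#' as at a real leading edge, rather than a thin capsule; with the default
#' geometry it reaches essentially every tumor-side spot outside the
#' niches, so the tumor side decomposes into marker-positive niches
#' embedded in stroma.
#'
#' The defaults generate a 60 x 120-array lattice (3600 spots), 200
#' background genes plus 20 genes for each of six modules (tumor_marker,
#' hepatocyte, fibro, endo, spp1_mac, prolif), 3 niches of radius 4,
#' module_fold 6, gradient_beta 0.5, triad_fraction 0.5, coupling_rho 0.6,
#' nb_dispersion 2 — a dataset that runs through the whole pipeline in
#' seconds.
#'
#' @param grid_rows,grid_cols lattice extent in array rows / (doubled)
#'   array columns; each row holds `grid_cols / 2` spots.
#' @param n_genes_background number of background (no-module) genes.
#' @param module_genes named integer vector: genes per module.
#' @param n_niches,niche_radius number and hex radius of tumor niches.
#' @param stroma_width stromal ring/band width in hex steps.
#' @param triad_fraction fraction of stroma spots carrying the SPP1+
#'   macrophage module.
#' @param gradient_beta per-layer decay rate of the proliferation mean.
#' @param baseline_mean,module_fold,nb_dispersion negative-binomial count
#'   model: baseline mean, fold-change of active module genes, dispersion.
#' @param coupling_rho strength in \[-1, 1\] of the planted association
#'   between a triad spot's latent SPP1 level and its neighbours'
#'   proliferation.
#' @param seed integer RNG seed; generation is deterministic given the
#'   config.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(grid_rows = 60, grid_cols = 120,
                       n_genes_background = 200,
                       module_genes = c(tumor_marker = 20, hepatocyte = 20,
                                        fibro = 20, endo = 20,
                                        spp1_mac = 20, prolif = 20),
                       n_niches = 3, niche_radius = 4, stroma_width = 15,
                       triad_fraction = 0.5, gradient_beta = 0.5,
                       baseline_mean = 2, module_fold = 6,
                       nb_dispersion = 2, coupling_rho = 0.6, seed = 0) {
  cfg <- list(grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
              n_genes_background = as.integer(n_genes_background),
              module_genes = module_genes,
              n_niches = as.integer(n_niches),
              niche_radius = as.integer(niche_radius),
              stroma_width = as.integer(stroma_width),
              triad_fraction = triad_fraction,
              gradient_beta = gradient_beta,
              baseline_mean = baseline_mean,
              module_fold = module_fold,
              nb_dispersion = nb_dispersion,
              coupling_rho = coupling_rho,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$grid_rows >= 1, cfg$grid_cols >= 2, cfg$grid_cols %% 2 == 0,
            cfg$n_genes_background >= 0, all(cfg$module_genes >= 1),
            cfg$n_niches >= 0, cfg$niche_radius >= 1, cfg$stroma_width >= 0,
            cfg$triad_fraction >= 0, cfg$triad_fraction <= 1,
            cfg$gradient_beta >= 0, cfg$baseline_mean > 0,
            cfg$module_fold >= 1, cfg$nb_dispersion > 0,
            abs(cfg$coupling_rho) <= 1)
  need <- c("tumor_marker", "hepatocyte", "fibro", "endo", "spp1_mac", "prolif")
  miss <- setdiff(need, names(cfg$module_genes))
  if (length(miss)) stop("module_genes must name: ", paste(miss, collapse = ", "))
  if (cfg$n_niches > 0) niche_centers(cfg)   # errors if niches do not fit
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic Visium config:", x$grid_rows, "x", x$grid_cols, "lattice (",
      x$grid_rows * x$grid_cols / 2, "spots ),", x$n_niches,
      "niche(s) of radius", x$niche_radius, "\n")
  cat("  genes:", x$n_genes_background, "background +",
      sum(x$module_genes), "module;  fold", x$module_fold,
      " dispersion", x$nb_dispersion, "\n")
  cat("  gradient_beta", x$gradient_beta, " triad_fraction", x$triad_fraction,
      " coupling_rho", x$coupling_rho, " seed", x$seed, "\n")
  invisible(x)
}

## deterministic niche placement: centres stacked vertically in the middle of
## the tumor half, clear of the interface band and the lattice border
niche_centers <- function(cfg) {
  half <- cfg$grid_cols %/% 2L
  margin <- cfg$niche_radius + cfg$stroma_width
  rows <- round((seq_len(cfg$n_niches) - 0.5) / cfg$n_niches * cfg$grid_rows - 0.5)
  ccol <- half + (cfg$grid_cols %/% 4L)
  centers <- cbind(row = as.integer(rows),
                   col = as.integer(ccol + ((rows + ccol) %% 2L)))
  if (any(centers[, "col"] - 2L * cfg$niche_radius < half)) {
    stop("niche of radius ", cfg$niche_radius, " would overlap the non-tumor side")
  }
  if (any(centers[, "row"] - cfg$niche_radius < 0) ||
      any(centers[, "row"] + cfg$niche_radius > cfg$grid_rows - 1L) ||
      any(centers[, "col"] + 2L * cfg$niche_radius > cfg$grid_cols - 1L)) {
    stop("niches do not fit inside the lattice; shrink niche_radius or n_niches")
  }
  if (cfg$n_niches > 1) {
    d <- hex_distance(centers[-1, "row"], centers[-1, "col"],
                      centers[-nrow(centers), "row"], centers[-nrow(centers), "col"])
    if (any(d <= 2L * cfg$niche_radius)) {
      stop("niches overlap each other; shrink niche_radius or n_niches")
    }
  }
  centers
}

#' Generate a synthetic leading-edge Visium dataset with ground truth
#'
#' Draws negative-binomial counts over the architecture described in
#' [sim_config()] and returns the dataset together with the planted truth:
#' per-spot region (tumor_side / non_tumor_side / stroma), niche id and
#' onion-layer depth (1 = rim), triad membership with its latent SPP1 level,
#' and the latent proliferation mean. The returned signatures are exactly
#' the planted module gene lists.
#'
#' @param cfg a [sim_config()].
#' @return A list of class `visium_sim`: `counts` (spots x genes
#'   `dgCMatrix`), `spots` ([spot_table()]), `truth` (data.frame),
#'   `signatures` (named list), `config`.
#' @export
simulate_visium <- function(cfg = sim_config()) {
  cfg <- validate_sim_config(cfg)
  half <- cfg$grid_cols %/% 2L
  pitch <- 100

  rows <- rep(seq_len(cfg$grid_rows) - 1L, each = half)
  cols_in_row <- function(r) seq.int(r %% 2L, cfg$grid_cols - 2L + r %% 2L, by = 2L)
  cols <- unlist(lapply(seq_len(cfg$grid_rows) - 1L, cols_in_row))
  n <- length(rows)
  st <- spot_table(
    spot_id = sprintf("SPOT-%05d", seq_len(n)),
    array_row = rows, array_col = cols,
    x = cols * pitch / 2, y = rows * pitch * sqrt(3) / 2,
    in_tissue = TRUE)

  region <- ifelse(cols < half, "non_tumor_side", "tumor_side")
  niche_id <- rep(NA_integer_, n)
  depth <- rep(NA_integer_, n)
  dist_to_niche <- rep(Inf, n)
  if (cfg$n_niches > 0) {
    centers <- niche_centers(cfg)
    for (k in seq_len(cfg$n_niches)) {
      d <- hex_distance(rows, cols, centers[k, "row"], centers[k, "col"])
      inside <- d <= cfg$niche_radius
      niche_id[inside] <- k
      depth[inside] <- cfg$niche_radius - d[inside] + 1L
      dist_to_niche <- pmin(dist_to_niche, d)
    }
  }
  interface_steps <- ifelse(cols >= half, (cols - half) %/% 2L + 1L, Inf)
  if (cfg$n_niches > 0) {
    stroma <- region == "tumor_side" & is.na(niche_id) &
      (dist_to_niche <= cfg$niche_radius + cfg$stroma_width |
         interface_steps <= cfg$stroma_width)
  } else {
    stroma <- region == "tumor_side"   # no tumor: bare stromal field
  }
  region[stroma] <- "stroma"

  gene_names <- c(sprintf("BG%04d", seq_len(cfg$n_genes_background)),
                  unlist(lapply(names(cfg$module_genes), function(m) {
                    sprintf("%s_%03d", toupper(m), seq_len(cfg$module_genes[[m]]))
                  })))
  signatures <- stats::setNames(lapply(names(cfg$module_genes), function(m) {
    sprintf("%s_%03d", toupper(m), seq_len(cfg$module_genes[[m]]))
  }), names(cfg$module_genes))

  out <- with_seed(cfg$seed, {
    triad <- rep(FALSE, n)
    u <- rep(NA_real_, n)
    stroma_idx <- which(stroma)
    if (length(stroma_idx) && cfg$triad_fraction > 0) {
      n_triad <- round(cfg$triad_fraction * length(stroma_idx))
      pick <- sample(stroma_idx, n_triad)
      triad[pick] <- TRUE
      u[pick] <- stats::runif(n_triad)
    }

    prolif_mu <- rep(cfg$baseline_mean, n)
    in_niche <- !is.na(niche_id)
    prolif_mu[in_niche] <- cfg$baseline_mean *
      (1 + (cfg$module_fold - 1) * exp(-cfg$gradient_beta * (depth[in_niche] - 1L)))
    # coupling: a niche spot's proliferation mean is boosted by its strongest
    # adjacent SPP1+ (triad) spot -- a saturating paracrine response, monotone
    # in the macrophage latent level and scaled by coupling_rho
    idx <- spot_index(st)
    u_max <- rep(0, n)
    for (i in which(triad)) {
      for (off in hex_offsets()) {
        j <- idx_lookup(idx, rows[i] + off[1], cols[i] + off[2])
        if (!is.na(j) && in_niche[j]) u_max[j] <- max(u_max[j], u[i])
      }
    }
    boosted <- u_max > 0
    prolif_mu[boosted] <- prolif_mu[boosted] *
      cfg$module_fold^(cfg$coupling_rho * u_max[boosted])

    mu <- matrix(cfg$baseline_mean, nrow = n, ncol = length(gene_names),
                 dimnames = list(st$spot_id, gene_names))
    gcols <- function(m) match(signatures[[m]], gene_names)
    fold <- cfg$module_fold
    mu[region == "non_tumor_side", gcols("hepatocyte")] <- cfg$baseline_mean * fold
    mu[in_niche, gcols("tumor_marker")] <- cfg$baseline_mean * fold
    mu[region == "stroma", gcols("fibro")] <- cfg$baseline_mean * fold
    mu[region == "stroma", gcols("endo")] <- cfg$baseline_mean * fold
    if (any(triad)) {
      mu[triad, gcols("spp1_mac")] <- cfg$baseline_mean *
        (1 + (fold - 1) * u[triad])
    }
    mu[, gcols("prolif")] <- prolif_mu

    counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = cfg$nb_dispersion),
                     nrow = n, dimnames = dimnames(mu))
    list(counts = counts, triad = triad, u = u, prolif_mu = prolif_mu)
  })

  truth <- data.frame(
    spot_id = st$spot_id,
    region = region,
    niche_id = niche_id,
    layer_depth = depth,
    triad = out$triad,
    spp1_u = out$u,
    prolif_mu = out$prolif_mu,
    stringsAsFactors = FALSE)

  structure(list(counts = methods::as(Matrix::Matrix(out$counts, sparse = TRUE),
                                      "CsparseMatrix"),
                 spots = st, truth = truth, signatures = signatures,
                 config = cfg),
            class = "visium_sim")
}

#' @export
print.visium_sim <- function(x, ...) {
  cat("Synthetic Visium dataset:", nrow(x$counts), "spots x", ncol(x$counts),
      "genes\n")
  print(table(region = x$truth$region))
  cat(sum(!is.na(x$truth$niche_id)), "niche spots in",
      length(unique(stats::na.omit(x$truth$niche_id))), "niche(s);",
      sum(x$truth$triad), "triad stroma spots\n")
  invisible(x)
}
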