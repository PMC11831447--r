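#' End-to-end leading-edge microstructure analysis
#'
#' Runs the full analysis on one Visium-style dataset: normalization,
#' signature scoring, quartile tiering, region partitioning (tumor side /
#' non-tumor side / stroma), niche detection, onion layering with a
#' per-layer proliferation profile and trend test, tri-signal
#' co-localization (fibro x endo x SPP1-mac), and the hex-neighbourhood
#' correlation between elevated SPP1-mac spots (outside the detected tumor
#' niches) and the proliferation signal of their in-niche hex neighbours.
#'
#' @param counts spots-by-genes count matrix with dimnames.
#' @param spots a [spot_table()] aligned with the matrix rows.
#' @param signatures named list of gene sets; must contain the signature
#'   names referenced by the `sig_*` arguments.
#' @param sig_tumor,sig_hepato,sig_stroma,sig_spp1,sig_prolif signature
#'   names used for the respective stages; `sig_stroma` may name several
#'   sets (their union is used).
#' @param min_z side-call threshold passed to [assign_regions()].
#' @param min_niche_size minimum connected-component size for a niche.
#' @param layer_mode `"hull_peel"` or `"hex_erosion"` (see [peel_layers()]).
#' @param k neighbourhood ring order for the correlation stage.
#' @param B permutations for the trend and correlation tests.
#' @param seed RNG seed for control-bin sampling and permutations.
#' @param score_mode passed to [module_score()].
#' @return An object of class `leading_edge` bundling all stage results:
#'   `scores`, `tiers`, `regions`, `niches`, `layerings`, `profiles`,
#'   `pooled_trend`, `tricoloc`, `spp1_focal`, `neighborhood`, `params`.
#' @examples
#' sim <- simulate_visium(sim_config(grid_rows = 20, grid_cols = 40,
#'                                   n_niches = 1, niche_radius = 3,
#'                                   stroma_width = 2, n_genes_background = 50,
#'                                   module_genes = c(tumor_marker = 5,
#'                                     hepatocyte = 5, fibro = 5, endo = 5,
#'                                     spp1_mac = 5, prolif = 5)))
#' fit <- leading_edge(sim$counts, sim$spots, sim$signatures, B = 99)
#' print(fit)
#' @export
leading_edge <- function(counts, spots, signatures,
                         sig_tumor = "tumor_marker", sig_hepato = "hepatocyte",
                         sig_stroma = c("fibro", "endo"),
                         sig_spp1 = "spp1_mac", sig_prolif = "prolif",
                         min_z = 0, min_niche_size = 10,
                         layer_mode = "hull_peel", k = 1, B = 1000, seed = 0,
                         score_mode = "plain") {
  spots <- validate_spot_table(spots)
  need <- c(sig_tumor, sig_hepato, sig_stroma, sig_spp1, sig_prolif)
  miss <- setdiff(need, names(signatures))
  if (length(miss)) stop("signatures missing: ", paste(miss, collapse = ", "))

  norm <- normalize_counts(counts)
  stroma_genes <- unique(unlist(signatures[sig_stroma]))
  score_of <- function(genes, nm) {
    module_score(norm, genes, signature_name = nm, mode = score_mode, seed = seed)
  }
  scores <- list(
    tumor  = score_of(signatures[[sig_tumor]], sig_tumor),
    hepato = score_of(signatures[[sig_hepato]], sig_hepato),
    stroma = score_of(stroma_genes, paste(sig_stroma, collapse = "+")),
    spp1   = score_of(signatures[[sig_spp1]], sig_spp1),
    prolif = score_of(signatures[[sig_prolif]], sig_prolif),
    fibro  = score_of(signatures[[sig_stroma[1]]], sig_stroma[1]),
    endo   = score_of(signatures[[if (length(sig_stroma) > 1) sig_stroma[2]
                                  else sig_stroma[1]]],
                      sig_stroma[min(2, length(sig_stroma))]))
  tiers <- lapply(scores, tier_quartiles)

  regions <- assign_regions(scores$tumor, scores$hepato, scores$stroma,
                            min_z = min_z)
  niches <- find_niches(regions, spots, min_size = min_niche_size)
  # drop chance-attached pendant members (fewer than 3 in-niche neighbours):
  # isolated mislabeled spots that latch onto a component corrupt the rim
  niches <- lapply(niches, prune_pendants, st = spots)
  niches <- niches[lengths(niches) >= min_niche_size]
  layerings <- lapply(niches, peel_layers, st = spots, mode = layer_mode)
  profiles <- lapply(layerings, layer_profile, score = scores$prolif,
                     B = B, seed = seed)
  pooled_trend <- pooled_layer_trend(layerings, scores$prolif, B = B, seed = seed)

  tricoloc <- coloc(tiers$fibro, tiers$endo, tiers$spp1)

  # tumor-cell response field: spots inside detected niches (compact tumor
  # aggregates), not isolated tumor-labeled spots; focal macrophage areas are
  # elevated SPP1-mac spots outside the niches
  tumor_ids <- unique(unlist(niches))
  focal <- enriched_spots(tiers$spp1,
                          mask = setdiff(names(regions), tumor_ids))
  neighborhood <- NULL
  if (length(focal) && length(tumor_ids)) {
    neighborhood <- tryCatch(
      neighborhood_correlation(focal, scores$spp1, scores$prolif, spots,
                               k = k, neighbor_mask = tumor_ids,
                               B = B, seed = seed),
      error = function(e) NULL)
  }

  structure(list(scores = scores, tiers = tiers, regions = regions,
                 niches = niches, layerings = layerings, profiles = profiles,
                 pooled_trend = pooled_trend, tricoloc = tricoloc,
                 spp1_focal = focal, neighborhood = neighborhood,
                 spots = spots,
                 params = list(min_z = min_z, min_niche_size = min_niche_size,
                               layer_mode = layer_mode, k = k, B = B,
                               seed = seed, score_mode = score_mode)),
            class = "leading_edge")
}

## iteratively remove niche members with fewer than 3 in-niche hex
## neighbours; compact aggregates (hex disks of radius >= 1) are unaffected
prune_pendants <- function(ids, st) {
  sub <- st[match(ids, st$spot_id), , drop = FALSE]
  keep <- rep(TRUE, nrow(sub))
  repeat {
    idx <- spot_index(sub[keep, , drop = FALSE])
    deg <- vapply(which(keep), function(i) {
      sum(vapply(hex_offsets(), function(off) {
        !is.na(idx_lookup(idx, sub$array_row[i] + off[1], sub$array_col[i] + off[2]))
      }, logical(1)))
    }, integer(1))
    drop <- which(keep)[deg < 3L]
    if (!length(drop) || sum(keep) <= length(drop)) break
    keep[drop] <- FALSE
  }
  sub$spot_id[keep]
}

## pooled across niches: per-layer means and one trend test on all layered
## spots (layer index vs score)
pooled_layer_trend <- function(layerings, score, B = 1000, seed = 0) {
  if (!length(layerings)) return(NULL)
  l <- unlist(lapply(layerings, `[[`, "layer"))
  if (!length(l) || max(l) < 2) return(NULL)
  v <- as.numeric(score[names(l)])
  means <- tapply(v, l, mean)
  if (stats::sd(v) == 0) {
    return(list(layer_means = means, rho = 0, p_value = 1))
  }
  rho <- stats::cor(as.integer(l), v, method = "spearman")
  perm <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      stats::cor(as.integer(l), sample(v), method = "spearman")
    }, numeric(1))
  })
  list(layer_means = means,
       rho = rho,
       p_value = (1 + sum(abs(perm) >= abs(rho))) / (B + 1))
}

#' @export
print.leading_edge <- function(x, ...) {
  cat("Leading-edge microstructure analysis\n")
  cat("  spots:", nrow(x$spots), " regions:",
      paste(sprintf("%s=%d", levels(x$regions), table(x$regions)), collapse = " "),
      "\n")
  cat("  niches detected:", length(x$niches),
      if (length(x$niches)) paste0("(sizes ",
        paste(lengths(x$niches), collapse = ", "), ")") else "", "\n")
  if (!is.null(x$pooled_trend)) {
    cat(sprintf("  proliferation vs layer depth: rho = %.3f (perm p = %.4g)\n",
                x$pooled_trend$rho, x$pooled_trend$p_value))
  }
  if (!is.null(x$neighborhood)) {
    cat(sprintf("  SPP1-mac vs neighbour proliferation: %s rho = %.3f (perm p = %.4g), %d focal spots\n",
                x$neighborhood$method, x$neighborhood$rho,
                x$neighborhood$p_perm, x$neighborhood$n_focal_used))
  }
  invisible(x)
}

#' @export
summary.leading_edge <- function(object, ...) {
  out <- list(
    n_spots = nrow(object$spots),
    region_counts = table(object$regions),
    n_niches = length(object$niches),
    niche_sizes = lengths(object$niches),
    layer_profiles = lapply(object$profiles, `[[`, "profile"),
    pooled_trend = object$pooled_trend,
    tricoloc_table = table(object$tricoloc$product),
    neighborhood = if (!is.null(object$neighborhood)) {
      list(rho = object$neighborhood$rho, p_perm = object$neighborhood$p_perm,
           n_focal = object$neighborhood$n_focal_used)
    })
  class(out) <- "summary.leading_edge"
  out
}

#' @export
print.summary.leading_edge <- function(x, ...) {
  cat("Leading-edge analysis of", x$n_spots, "spots\n\nRegions:\n")
  print(x$region_counts)
  cat("\nNiches:", x$n_niches, "(sizes:", paste(x$niche_sizes, collapse = ", "),
      ")\n")
  if (!is.null(x$pooled_trend)) {
    cat("\nPer-layer proliferation means (pooled over niches):\n")
    print(round(x$pooled_trend$layer_means, 3))
    cat(sprintf("trend rho = %.3f, perm p = %.4g\n",
                x$pooled_trend$rho, x$pooled_trend$p_value))
  }
  if (!is.null(x$neighborhood)) {
    cat(sprintf("\nSPP1-mac / proliferation neighbourhood correlation: rho = %.3f, p = %.4g (n = %d)\n",
                x$neighborhood$rho, x$neighborhood$p_perm, x$neighborhood$n_focal))
  }
  invisible(x)
}

#' Plot a leading-edge analysis
#'
#' Spot map coloured by region label, with niche onion layers shaded by
#' depth (darker = deeper) and focal SPP1-enriched spots circled.
#'
#' @param x a [leading_edge()] result.
#' @param which `"regions"` (default) or `"layers"`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.leading_edge <- function(x, which = c("regions", "layers"), ...) {
  which <- match.arg(which)
  st <- x$spots
  if (which == "regions") {
    pal <- c(tumor_side = "#d62728", non_tumor_side = "#1f77b4",
             stroma = "#2ca02c", unassigned = "grey85")
    col <- pal[as.character(x$regions[st$spot_id])]
    graphics::plot(st$x, st$y, col = col, pch = 16, cex = 0.5, asp = 1,
                   xlab = "x", ylab = "y", main = "Region labels", ...)
    graphics::legend("topleft", legend = names(pal), col = pal, pch = 16,
                     cex = 0.7, bty = "n")
    if (length(x$spp1_focal)) {
      i <- match(x$spp1_focal, st$spot_id)
      graphics::points(st$x[i], st$y[i], pch = 1, cex = 0.9)
    }
  } else {
    graphics::plot(st$x, st$y, col = "grey90", pch = 16, cex = 0.4, asp = 1,
                   xlab = "x", ylab = "y", main = "Niche onion layers", ...)
    for (lay in x$layerings) {
      i <- match(names(lay$layer), st$spot_id)
      shade <- grDevices::grey(0.8 - 0.7 * (lay$layer - 1) / max(1, lay$n_layers - 1))
      graphics::points(st$x[i], st$y[i], col = shade, pch = 16, cex = 0.6)
    }
  }
  invisible(x)
}
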