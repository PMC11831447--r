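#' Hex-ring neighbours of a spot
#'
#' Returns all in-tissue spots within `k` hex steps of a focal spot
#' (breadth-first expansion over the six pseudo-hex offsets), excluding the
#' focal spot itself. An interior spot has 6 ring-1 and 18 ring-<=2
#' neighbours; lattice-border spots have fewer.
#'
#' @param st a [spot_table()].
#' @param spot focal spot id (must be in the table).
#' @param k ring order (>= 1).
#' @return Character vector of neighbour spot ids.
#' @export
hex_neighbors <- function(st, spot, k = 1) {
  st <- validate_spot_table(st)
  i <- match(spot, st$spot_id)
  if (is.na(i)) stop("unknown spot: ", spot)
  tissue <- st[st$in_tissue, , drop = FALSE]
  idx <- spot_index(tissue)
  f0 <- match(spot, tissue$spot_id)
  if (is.na(f0)) return(character(0))   # focal spot itself not in tissue
  tissue$spot_id[ring_neighbors(tissue, idx, f0, k)]
}

## BFS over hex offsets from row index f0 of `tissue`; returns row indices
## of all spots within k steps, excluding f0. `idx` from spot_index(tissue).
ring_neighbors <- function(tissue, idx, f0, k) {
  frontier <- f0
  seen <- f0
  for (step in seq_len(k)) {
    cand <- integer(0)
    for (off in hex_offsets()) {
      j <- idx_lookup(idx, tissue$array_row[frontier] + off[1],
                      tissue$array_col[frontier] + off[2])
      cand <- c(cand, j[!is.na(j)])
    }
    frontier <- setdiff(unique(cand), seen)
    seen <- c(seen, frontier)
    if (!length(frontier)) break
  }
  setdiff(seen, f0)
}

#' Multiplicative co-localization of two or three tiered signals
#'
#' Quantifies spot-level co-occurrence by multiplying the quartile tiers
#' (0-3) of the component signals at identical locations: the product is 0
#' whenever any component is absent (tier 0) and maximal (9 pairwise, 27
#' three-way) only when every component is in its top quartile.
#'
#' @param ... two or three [tier_quartiles()] results sharing one scope.
#' @return An object of class `coloc_map`: list with `product` (named
#'   integer vector) and `tiers` (matrix of the component tiers).
#' @export
coloc <- function(...) {
  tvs <- list(...)
  if (length(tvs) == 1 && is.list(tvs[[1]]) && !inherits(tvs[[1]], "tier_vector")) {
    tvs <- tvs[[1]]
  }
  if (!length(tvs) %in% c(2, 3)) stop("coloc takes 2 or 3 tier vectors")
  if (!all(vapply(tvs, inherits, logical(1), "tier_vector"))) {
    stop("all inputs must be tier_vector objects (see tier_quartiles)")
  }
  ids <- do.call(check_same_scope, lapply(tvs, `[[`, "tiers"))
  tiers <- vapply(tvs, function(tv) tv$tiers[ids], integer(length(ids)))
  structure(list(product = stats::setNames(as.integer(apply(tiers, 1, prod)), ids),
                 tiers = tiers),
            class = "coloc_map")
}

#' @export
print.coloc_map <- function(x, ...) {
  cat("Co-localization of", ncol(x$tiers), "signals over", length(x$product),
      "spots\n")
  print(table(product = x$product))
  invisible(x)
}

#' Spots with elevated signal (top quartile tier)
#'
#' "Elevated" is formalized as tier 3 — the top quartile of the tiering
#' scope — optionally intersected with a mask of eligible spots (for
#' example one compartment of the region labels).
#'
#' @param tiers a [tier_quartiles()] result.
#' @param mask optional character vector of eligible spot ids.
#' @return Character vector of enriched spot ids (possibly empty).
#' @export
enriched_spots <- function(tiers, mask = NULL) {
  stopifnot(inherits(tiers, "tier_vector"))
  ids <- names(tiers$tiers)[tiers$tiers == 3L]
  if (!is.null(mask)) ids <- intersect(ids, as.character(mask))
  ids
}

#' Correlation between focal spots and their hex-neighbourhood response
#'
#' For each focal spot (for example spots with an elevated SPP1+ macrophage
#' signature) the response signal (for example a proliferation score) is
#' averaged over its ring-<=k hex neighbours, optionally restricted to a
#' mask (for example tumor-side spots). The association between the focal
#' score and the neighbourhood mean is then measured over all focal spots
#' with at least one eligible neighbour, with a permutation p-value
#' (neighbourhood means permuted across focal spots, two-sided, seeded).
#'
#' @param focal character vector of focal spot ids (non-empty).
#' @param focal_score,response_score named per-spot score vectors; the
#'   focal score must cover `focal`, the response all potential neighbours.
#' @param st a [spot_table()].
#' @param k neighbourhood ring order.
#' @param neighbor_mask optional character vector restricting which
#'   neighbours contribute to the mean.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param B number of permutations.
#' @param seed RNG seed for the permutations.
#' @return An object of class `neighborhood_result`: list with `table`
#'   (data.frame: spot_id, focal_score, neighborhood_mean,
#'   n_neighbors_used), `method`, `rho`, `p_perm`. `rho` is `NA` (with a
#'   warning) when either vector has zero variance.
#' @export
neighborhood_correlation <- function(focal, focal_score, response_score, st,
                                     k = 1, neighbor_mask = NULL,
                                     method = c("spearman", "pearson"),
                                     B = 1000, seed = 0) {
  method <- match.arg(method)
  focal <- as.character(focal)
  if (!length(focal)) stop("focal spot set is empty")
  missing <- setdiff(focal, names(focal_score))
  if (length(missing)) stop("focal_score missing for ",
                            length(missing), " focal spot(s)")
  st <- validate_spot_table(st)

  tissue <- st[st$in_tissue, , drop = FALSE]
  idx <- spot_index(tissue)
  eligible <- names(response_score)
  if (!is.null(neighbor_mask)) eligible <- intersect(eligible, as.character(neighbor_mask))
  ok <- tissue$spot_id %in% eligible

  nb_mean <- rep(NA_real_, length(focal))
  n_used <- integer(length(focal))
  f0 <- match(focal, tissue$spot_id)
  for (i in seq_along(focal)) {
    if (is.na(f0[i])) next
    nb <- ring_neighbors(tissue, idx, f0[i], k)
    nb <- nb[ok[nb]]
    n_used[i] <- length(nb)
    if (length(nb)) nb_mean[i] <- mean(response_score[tissue$spot_id[nb]])
  }
  keep <- n_used > 0
  if (!any(keep)) stop("no focal spot has an eligible neighbour")
  tab <- data.frame(spot_id = focal, focal_score = as.numeric(focal_score[focal]),
                    neighborhood_mean = nb_mean, n_neighbors_used = n_used,
                    stringsAsFactors = FALSE)
  # canonical pair order so the permutation p-value is invariant to the
  # order in which focal spots were supplied
  kept <- tab[keep, , drop = FALSE]
  kept <- kept[order(kept$spot_id), , drop = FALSE]
  x <- kept$focal_score
  y <- kept$neighborhood_mean
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance in focal or neighbourhood signal; correlation undefined")
    rho <- NA_real_
    p <- NA_real_
  } else {
    rho <- stats::cor(x, y, method = method)
    perm <- with_seed(seed, {
      vapply(seq_len(B), function(b) stats::cor(x, sample(y), method = method),
             numeric(1))
    })
    p <- (1 + sum(abs(perm) >= abs(rho))) / (B + 1)
  }
  structure(list(table = tab, method = method, rho = rho, p_perm = p,
                 k = k, n_focal_used = sum(keep)),
            class = "neighborhood_result")
}

#' @export
print.neighborhood_result <- function(x, ...) {
  cat("Neighbourhood correlation (ring <=", x$k, "):", nrow(x$table),
      "focal spots,", x$n_focal_used, "with eligible neighbours\n")
  if (is.na(x$rho)) {
    cat("correlation undefined (zero variance)\n")
  } else {
    cat(sprintf("%s rho = %.3f, permutation p = %.4g\n", x$method, x$rho, x$p_perm))
  }
  invisible(x)
}
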