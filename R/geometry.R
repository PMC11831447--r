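#' Detect tumor niches as connected components
#'
#' Tumor niches (compact aggregates of tumor-labeled spots, typically
#' encircled by stroma) are found as connected components of `tumor_side`
#' spots under hex adjacency, replacing manual spot selection. Components
#' smaller than `min_size` are discarded; the result is sorted by size,
#' largest first.
#'
#' @param labels named region factor from [assign_regions()] (or any named
#'   vector; spots labeled `"tumor_side"` are used).
#' @param st a [spot_table()] covering the labeled spots.
#' @param min_size minimum component size to keep.
#' @return List of character vectors of spot ids (possibly empty).
#' @export
find_niches <- function(labels, st, min_size = 10) {
  st <- validate_spot_table(st)
  ids <- names(labels)[labels == "tumor_side"]
  ids <- intersect(ids, st$spot_id)
  if (!length(ids)) return(list())
  sub <- st[match(ids, st$spot_id), , drop = FALSE]
  idx <- spot_index(sub)
  n <- nrow(sub)
  comp <- integer(n)
  ncomp <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    ncomp <- ncomp + 1L
    queue <- s
    comp[s] <- ncomp
    while (length(queue)) {
      i <- queue[1]; queue <- queue[-1]
      for (off in hex_offsets()) {
        j <- idx_lookup(idx, sub$array_row[i] + off[1], sub$array_col[i] + off[2])
        if (!is.na(j) && comp[j] == 0L) {
          comp[j] <- ncomp
          queue <- c(queue, j)
        }
      }
    }
  }
  comps <- split(sub$spot_id, comp)
  comps <- comps[lengths(comps) >= min_size]
  comps <- comps[order(lengths(comps), decreasing = TRUE)]
  unname(comps)
}

#' Concave hull of a point set (concaveman scheme)
#'
#' Starts from the convex hull and recursively digs each edge toward the
#' interior point nearest to it, whenever the edge is longer than
#' `length_threshold` and longer than `concavity` times the decision
#' distance (the candidate's distance to the nearer edge endpoint), and the
#' dig keeps the polygon simple. `concavity = Inf` (or any very large
#' value) therefore returns the convex hull; smaller values hug the points
#' more tightly. The output polygon always contains all input points.
#'
#' @param points two-column matrix or data.frame of (x, y) coordinates;
#'   at least 3 non-collinear points.
#' @param concavity relative dig threshold (> 0); default 2.
#' @param length_threshold edges not longer than this are never dug.
#' @return Matrix of polygon vertices (x, y), in order, not repeating the
#'   first vertex; class `niche_polygon`.
#' @export
concave_hull <- function(points, concavity = 2, length_threshold = 0) {
  pts <- unique(as.matrix(points)[, 1:2, drop = FALSE])
  storage.mode(pts) <- "double"
  if (nrow(pts) < 3) stop("concave hull needs at least 3 distinct points")
  hull <- grDevices::chull(pts[, 1], pts[, 2])
  if (length(hull) < 3) stop("all points are collinear; hull is degenerate")
  verts <- hull                      # ordered vertex indices into pts
  interior <- setdiff(seq_len(nrow(pts)), verts)

  # Dig the admissible edge with the LARGEST length/decision-distance ratio
  # first, repeatedly. Because the selection rule does not depend on the
  # concavity threshold, the hull at a larger concavity is an intermediate
  # state of the process at a smaller one; polygon area is therefore
  # non-decreasing in the concavity parameter by construction.
  while (length(interior)) {
    nv <- length(verts)
    best <- NULL
    best_ratio <- concavity
    for (pos in seq_len(nv)) {
      a <- verts[pos]
      b <- verts[pos %% nv + 1L]
      len <- sqrt(sum((pts[a, ] - pts[b, ])^2))
      if (len <= length_threshold) next
      d <- point_segment_distance(pts[interior, , drop = FALSE], pts[a, ], pts[b, ])
      cand <- interior[which.min(d)]
      dd <- min(sqrt(sum((pts[cand, ] - pts[a, ])^2)),
                sqrt(sum((pts[cand, ] - pts[b, ])^2)))
      if (dd <= 0 || len / dd <= best_ratio) next
      # locality (Park-Oh): the candidate must belong to this edge, i.e. be
      # no nearer to either adjacent hull edge
      prev <- verts[(pos - 2L) %% nv + 1L]
      nxt2 <- verts[(pos + 1L) %% nv + 1L]
      d_here <- min(d)
      if (d_here > point_segment_distance(pts[cand, , drop = FALSE],
                                          pts[prev, ], pts[a, ]) ||
          d_here > point_segment_distance(pts[cand, , drop = FALSE],
                                          pts[b, ], pts[nxt2, ])) next
      # keep the polygon simple: the two new edges may not cross existing ones
      crosses <- FALSE
      for (k in seq_len(nv)) {
        u <- verts[k]; v <- verts[k %% nv + 1L]
        if (u %in% c(a, b, cand) || v %in% c(a, b, cand)) next
        if (segments_intersect(pts[a, ], pts[cand, ], pts[u, ], pts[v, ]) ||
            segments_intersect(pts[cand, ], pts[b, ], pts[u, ], pts[v, ])) {
          crosses <- TRUE
          break
        }
      }
      if (crosses) next
      best <- list(pos = pos, cand = cand)
      best_ratio <- len / dd
    }
    if (is.null(best)) break
    verts <- append(verts, best$cand, after = best$pos)
    interior <- setdiff(interior, best$cand)
  }
  structure(pts[verts, , drop = FALSE],
            dimnames = list(NULL, c("x", "y")), class = "niche_polygon")
}

## vectorised distance from points (n x 2) to segment a-b
point_segment_distance <- function(p, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) return(sqrt((p[, 1] - a[1])^2 + (p[, 2] - a[2])^2))
  t <- ((p[, 1] - a[1]) * ab[1] + (p[, 2] - a[2]) * ab[2]) / len2
  t <- pmin(1, pmax(0, t))
  sqrt((p[, 1] - (a[1] + t * ab[1]))^2 + (p[, 2] - (a[2] + t * ab[2]))^2)
}

## proper or improper crossing of segments p1-p2 and p3-p4
segments_intersect <- function(p1, p2, p3, p4) {
  o <- function(a, b, c) sign((b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1]))
  o1 <- o(p1, p2, p3); o2 <- o(p1, p2, p4)
  o3 <- o(p3, p4, p1); o4 <- o(p3, p4, p2)
  if (o1 != o2 && o3 != o4) return(TRUE)
  on_seg <- function(a, b, c) {
    o(a, b, c) == 0 &&
      min(a[1], b[1]) <= c[1] && c[1] <= max(a[1], b[1]) &&
      min(a[2], b[2]) <= c[2] && c[2] <= max(a[2], b[2])
  }
  on_seg(p1, p2, p3) || on_seg(p1, p2, p4) || on_seg(p3, p4, p1) || on_seg(p3, p4, p2)
}

## min distance from each point to the closed polygon boundary
dist_to_polygon <- function(p, poly) {
  p <- as.matrix(p)[, 1:2, drop = FALSE]
  poly <- as.matrix(poly)
  d <- rep(Inf, nrow(p))
  nv <- nrow(poly)
  for (k in seq_len(nv)) {
    a <- poly[k, ]
    b <- poly[if (k == nv) 1 else k + 1, ]
    d <- pmin(d, point_segment_distance(p, a, b))
  }
  d
}

#' Peel a niche into onion layers
#'
#' Stratifies a niche's spots into concentric layers indexed from the rim
#' inward (layer 1 = outermost). Two modes:
#' \describe{
#'   \item{`hull_peel`}{iteratively builds the concave hull of the
#'     remaining spots and peels every spot within
#'     `epsilon_factor * pitch` of the polygon boundary; stops when at most
#'     3 spots remain (they form the final layer). The default
#'     `epsilon_factor = 0.6` captures exactly the rim row of a hex
#'     lattice per peel.}
#'   \item{`hex_erosion`}{grid-native erosion: spots with fewer than 6
#'     in-niche hex neighbours form the current layer; iterate.}
#' }
#'
#' @param niche character vector of spot ids (at least 1).
#' @param st a [spot_table()] covering the niche.
#' @param mode `"hull_peel"` (default) or `"hex_erosion"`.
#' @param epsilon_factor boundary-capture tolerance, as a fraction of the
#'   lattice pitch (hull_peel only).
#' @param concavity passed to [concave_hull()] (hull_peel only).
#' @return An object of class `niche_layering`: list with `layer` (named
#'   integer vector, 1 = outermost) and `n_layers`.
#' @export
peel_layers <- function(niche, st, mode = c("hull_peel", "hex_erosion"),
                        epsilon_factor = 0.6, concavity = 2) {
  mode <- match.arg(mode)
  st <- validate_spot_table(st)
  niche <- as.character(niche)
  if (!length(niche)) stop("cannot layer an empty niche")
  if (!all(niche %in% st$spot_id)) stop("niche contains spots absent from the spot table")
  sub <- st[match(niche, st$spot_id), , drop = FALSE]
  layer <- stats::setNames(rep(NA_integer_, length(niche)), niche)

  if (mode == "hex_erosion") {
    remaining <- rep(TRUE, nrow(sub))
    l <- 0L
    while (any(remaining)) {
      l <- l + 1L
      idx <- spot_index(sub[remaining, , drop = FALSE])
      deg <- vapply(which(remaining), function(i) {
        sum(vapply(hex_offsets(), function(off) {
          !is.na(idx_lookup(idx, sub$array_row[i] + off[1], sub$array_col[i] + off[2]))
        }, logical(1)))
      }, integer(1))
      cur <- which(remaining)[deg < 6L]
      if (!length(cur)) cur <- which(remaining)   # safeguard; cannot occur on finite sets
      layer[cur] <- l
      remaining[cur] <- FALSE
    }
  } else {
    pitch <- if (nrow(st) >= 2) spot_pitch(st) else 1
    remaining <- rep(TRUE, nrow(sub))
    l <- 0L
    while (any(remaining)) {
      l <- l + 1L
      ridx <- which(remaining)
      pts <- as.matrix(sub[ridx, c("x", "y")])
      if (length(ridx) <= 3 || collinear_points(pts)) {
        layer[ridx] <- l
        break
      }
      poly <- concave_hull(pts, concavity = concavity)
      d <- dist_to_polygon(pts, poly)
      cur <- ridx[d <= epsilon_factor * pitch]
      if (!length(cur)) cur <- ridx               # safeguard; hull vertices are at 0
      layer[cur] <- l
      remaining[cur] <- FALSE
    }
  }
  structure(list(layer = layer, n_layers = max(layer)), class = "niche_layering")
}

collinear_points <- function(pts) {
  if (nrow(pts) < 3) return(TRUE)
  a <- pts[1, ]
  v <- sweep(pts[-1, , drop = FALSE], 2, a)
  cross <- v[1, 1] * v[, 2] - v[1, 2] * v[, 1]
  all(abs(cross) < 1e-9 * max(1, max(abs(v))))
}

#' @export
print.niche_layering <- function(x, ...) {
  cat("Niche layering:", length(x$layer), "spots in", x$n_layers, "layer(s)\n")
  print(table(layer = x$layer))
  invisible(x)
}

#' Per-layer signature profile with a trend test
#'
#' Averages a per-spot score within each onion layer and tests for a
#' monotone trend of score versus layer index with a Spearman correlation
#' and a permutation p-value (scores permuted across the niche's spots,
#' two-sided). With a single layer the trend is undefined (`NA`); with a
#' constant score the correlation is reported as 0.
#'
#' @param layering a [peel_layers()] result.
#' @param score named per-spot score vector covering all layered spots.
#' @param B number of permutations.
#' @param seed RNG seed for the permutations.
#' @return An object of class `layer_profile`: list with `profile`
#'   (data.frame: layer, n_spots, mean_score) and `trend` (list: method,
#'   rho, p_value).
#' @export
layer_profile <- function(layering, score, B = 1000, seed = 0) {
  stopifnot(inherits(layering, "niche_layering"))
  ids <- names(layering$layer)
  missing <- setdiff(ids, names(score))
  if (length(missing)) stop("scores missing for ",
                            length(missing), " layered spot(s)")
  v <- as.numeric(score[ids])
  l <- as.integer(layering$layer)
  profile <- data.frame(
    layer = sort(unique(l)),
    n_spots = as.integer(table(l)),
    mean_score = as.numeric(tapply(v, l, mean)))
  if (layering$n_layers < 2) {
    trend <- list(method = "spearman", rho = NA_real_, p_value = NA_real_)
  } else if (stats::sd(v) == 0) {
    trend <- list(method = "spearman", rho = 0, p_value = 1)
  } else {
    rho <- stats::cor(l, v, method = "spearman")
    perm <- with_seed(seed, {
      vapply(seq_len(B), function(b) {
        stats::cor(l, sample(v), method = "spearman")
      }, numeric(1))
    })
    p <- (1 + sum(abs(perm) >= abs(rho))) / (B + 1)
    trend <- list(method = "spearman", rho = rho, p_value = p)
  }
  structure(list(profile = profile, trend = trend), class = "layer_profile")
}

#' @export
print.layer_profile <- function(x, ...) {
  print(x$profile, row.names = FALSE)
  if (is.na(x$trend$rho)) {
    cat("trend: undefined (single layer)\n")
  } else {
    cat(sprintf("trend: Spearman rho = %.3f, permutation p = %.4g\n",
                x$trend$rho, x$trend$p_value))
  }
  invisible(x)
}
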