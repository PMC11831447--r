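#' Library-size normalization of spot counts
#'
#' Scales every spot to the median library size and applies `log(1 + x)`.
#' Spots with zero total counts cannot be scaled and are dropped with a
#' warning. Downstream stages of this package consume only ranks and
#' quartiles of signature scores, which are insensitive to the precise
#' normalization family.
#'
#' @param counts spots-by-genes count matrix (sparse or dense) with
#'   dimnames.
#' @return A `dgCMatrix` of the same shape (minus any dropped spots) with
#'   finite entries.
#' @export
normalize_counts <- function(counts) {
  counts <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  lib <- Matrix::rowSums(counts)
  if (any(lib == 0)) {
    warning("dropping ", sum(lib == 0), " spot(s) with zero total counts")
    counts <- counts[lib > 0, , drop = FALSE]
    lib <- lib[lib > 0]
  }
  if (!nrow(counts)) stop("no spots left after dropping empty libraries")
  sf <- stats::median(lib) / lib
  out <- Matrix::Diagonal(x = sf) %*% counts
  out@x <- log1p(out@x)
  dimnames(out) <- dimnames(counts)
  methods::as(out, "CsparseMatrix")
}

#' Per-spot signature (module) score
#'
#' Scores a gene set at every spot as the mean of scaled and centered
#' (z-scored across spots) expression of the signature genes. z-scores are
#' capped at +/-10 to bound outlier influence; a zero-variance gene
#' contributes 0. Signature genes absent from the matrix are dropped with a
#' message (signatures typically come from a different modality).
#'
#' `mode = "control_bins"` additionally subtracts the mean z-score of
#' expression-matched control genes: all genes are ranked by mean
#' normalized expression into `n_bins` bins and `n_ctrl` controls per
#' signature gene are sampled (seeded) from the matching bin.
#'
#' @param norm normalized spots-by-genes matrix (see [normalize_counts()]).
#' @param genes character vector of signature genes.
#' @param signature_name label carried on the result.
#' @param mode `"plain"` (default) or `"control_bins"`.
#' @param n_bins,n_ctrl,seed control-gene matching parameters.
#' @return A named numeric vector (one score per spot) with attributes
#'   `signature` and `mode`.
#' @export
module_score <- function(norm, genes, signature_name = "signature",
                         mode = c("plain", "control_bins"),
                         n_bins = 24, n_ctrl = 50, seed = 0) {
  mode <- match.arg(mode)
  genes <- unique(genes)
  present <- intersect(genes, colnames(norm))
  if (!length(present)) {
    stop("no gene of signature '", signature_name, "' is present in the matrix")
  }
  if (length(present) < length(genes)) {
    message("signature '", signature_name, "': dropping ",
            length(genes) - length(present), " gene(s) absent from the matrix")
  }
  score <- rowMeans(zscore_genes(norm, present))
  if (mode == "control_bins") {
    mu <- Matrix::colMeans(norm)
    bins <- cut(rank(mu, ties.method = "first"), breaks = n_bins, labels = FALSE)
    names(bins) <- colnames(norm)
    ctrl <- with_seed(seed, {
      unique(unlist(lapply(present, function(g) {
        pool <- names(bins)[bins == bins[[g]]]
        pool <- setdiff(pool, present)
        if (!length(pool)) return(character(0))
        sample(pool, min(n_ctrl, length(pool)))
      })))
    })
    if (length(ctrl)) score <- score - rowMeans(zscore_genes(norm, ctrl))
  }
  structure(score, names = rownames(norm),
            signature = signature_name, mode = mode)
}

## column-wise z-scores with zero-variance columns set to 0, capped at +/-10
zscore_genes <- function(norm, genes, cap = 10) {
  m <- as.matrix(norm[, genes, drop = FALSE])
  mu <- colMeans(m)
  sd <- apply(m, 2, stats::sd)
  z <- sweep(m, 2, mu, "-")
  nz <- sd > 0
  z[, nz] <- sweep(z[, nz, drop = FALSE], 2, sd[nz], "/")
  z[, !nz] <- 0
  z[z > cap] <- cap
  z[z < -cap] <- -cap
  z
}

#' Quartile tiers (0-3) of a per-spot signal
#'
#' Computes the 25th/50th/75th percentiles (linear interpolation between
#' order statistics) of the score over a scope of spots and assigns each
#' spot a tier: 0 if `v <= Q1`, 1 if `Q1 < v <= Q2`, 2 if `Q2 < v <= Q3`,
#' 3 otherwise. Boundary values go to the lower tier, so a constant vector
#' is all tier 0.
#'
#' @param score named numeric vector of per-spot scores.
#' @param scope optional character vector of spot ids over which both the
#'   thresholds and the tiers are computed (default: all spots of `score`).
#' @return An object of class `tier_vector`: list with `tiers` (named
#'   integer vector in 0..3) and `thresholds` (Q1, Q2, Q3).
#' @export
tier_quartiles <- function(score, scope = NULL) {
  if (is.null(names(score))) stop("score vector must carry spot ids as names")
  if (!is.null(scope)) {
    missing <- setdiff(scope, names(score))
    if (length(missing)) stop("scope spots absent from score: ",
                              paste(utils::head(missing, 5), collapse = ", "))
    score <- score[scope]
  }
  if (length(score) < 4) stop("tiering requires a scope of at least 4 spots")
  q <- stats::quantile(score, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  tiers <- (score > q[1]) + (score > q[2]) + (score > q[3])
  structure(list(tiers = stats::setNames(as.integer(tiers), names(score)),
                 thresholds = stats::setNames(q, c("Q1", "Q2", "Q3"))),
            class = "tier_vector")
}

#' @export
print.tier_vector <- function(x, ...) {
  cat("Quartile tiers over", length(x$tiers), "spots\n")
  cat("thresholds: Q1 =", signif(x$thresholds[1], 4),
      " Q2 =", signif(x$thresholds[2], 4),
      " Q3 =", signif(x$thresholds[3], 4), "\n")
  print(table(tier = x$tiers))
  invisible(x)
}

#' Semi-quantitative IHC score
#'
#' Immunohistochemistry staining is scored by binning the stained-cell
#' density (0-25 / 26-50 / 51-75 / 76-100 percent -> 1-4) and the staining
#' intensity (negative / weak / moderate / strong -> 1-4) and multiplying
#' the two, giving a score between 1 and 16.
#'
#' @param density_pct stained density in percent, in \[0, 100\] (vectorised).
#' @param intensity one of `"negative"`, `"weak"`, `"moderate"`, `"strong"`
#'   (vectorised, recycled against `density_pct`).
#' @return Integer score(s) in \{1, 2, 3, 4, 6, 8, 9, 12, 16\}.
#' @export
ihc_score <- function(density_pct, intensity) {
  if (any(!is.finite(density_pct)) || any(density_pct < 0) || any(density_pct > 100)) {
    stop("density_pct must lie in [0, 100]")
  }
  levels <- c("negative", "weak", "moderate", "strong")
  ii <- match(intensity, levels)
  if (anyNA(ii)) stop("intensity must be one of: ", paste(levels, collapse = ", "))
  dens <- 1L + (density_pct > 25) + (density_pct > 50) + (density_pct > 75)
  as.integer(dens * ii)
}
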