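#' Partition spots into tumor side, non-tumor side and stroma
#'
#' Implements the marker-based compartment rule for a leading-edge slice:
#' a spot is called `stroma` when its stromal (fibroblast + endothelial)
#' signature sits in the top quartile tier over the shared scope — stroma is
#' a distinct compartment that may overlap the tumor side, so it takes
#' precedence. Otherwise the spot goes to the side (tumor vs non-tumor)
#' whose marker score is larger, provided that maximum reaches `min_z`;
#' below the threshold the spot stays `unassigned`. Exact tumor/hepatocyte
#' ties go to `tumor_side` (deterministic tie-break, reported via message).
#'
#' @param tumor_score,hepato_score,stroma_score named per-spot score
#'   vectors sharing the same scope (e.g. from [module_score()]).
#' @param min_z minimum score for a side call; the default 0 means "above
#'   the scope mean" on the z-score scale.
#' @return Named factor with levels `tumor_side`, `non_tumor_side`,
#'   `stroma`, `unassigned`.
#' @export
assign_regions <- function(tumor_score, hepato_score, stroma_score, min_z = 0) {
  ids <- check_same_scope(tumor_score, hepato_score, stroma_score)
  hepato_score <- hepato_score[ids]
  stroma_score <- stroma_score[ids]
  tumor_score <- tumor_score[ids]

  stroma_tier <- tier_quartiles(stroma_score)$tiers
  label <- rep("unassigned", length(ids))
  side_max <- pmax(tumor_score, hepato_score)
  is_tie <- tumor_score == hepato_score & side_max >= min_z
  if (any(is_tie)) {
    message(sum(is_tie), " exact tumor/hepatocyte tie(s) resolved to tumor_side")
  }
  label[side_max >= min_z & tumor_score >= hepato_score] <- "tumor_side"
  label[side_max >= min_z & tumor_score < hepato_score] <- "non_tumor_side"
  label[stroma_tier == 3L] <- "stroma"
  factor(stats::setNames(label, ids),
         levels = c("tumor_side", "non_tumor_side", "stroma", "unassigned"))
}
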