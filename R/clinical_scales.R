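# Composite neurological-exam subpanels relevant to each balance test,
# aggregated from app-derived panel scores (panel scoring itself is taken
# as given; the synthetic cohort supplies the panel values).

#' Postural-sway exam subpanel
#'
#' Square root of the sum of the stance-and-gait panel, the
#' lower-extremity cerebellar dysfunction panel, and the lower-extremity
#' proprioceptive dysfunction panel.
#'
#' @param stance_gait,cerebellar_le,proprioceptive_le Nonnegative scores
#'   (vectorized).
#' @return `sqrt(stance_gait + cerebellar_le + proprioceptive_le)`.
#' @export
neurex_postural_sway <- function(stance_gait, cerebellar_le,
                                 proprioceptive_le) {
  if (any(c(stance_gait, cerebellar_le, proprioceptive_le) < 0, na.rm = TRUE))
    stop("panel scores must be nonnegative")
  sqrt(stance_gait + cerebellar_le + proprioceptive_le)
}

#' Pronator-drift exam subpanel
#'
#' Sums, over both hands, the per-hand motoric dysfunction (muscle
#' strength + reflexes + spasticity panels), cerebellar dysfunction and
#' proprioceptive dysfunction scores.
#'
#' @param per_hand Named list with elements `left` and `right`, each a
#'   numeric vector/list with components `motoric`, `cerebellar`,
#'   `proprioceptive` (motoric already summed from its three panels; see
#'   [motoric_dysfunction()]).
#' @return Total score.
#' @export
neurex_pronator_drift <- function(per_hand) {
  if (!all(c("left", "right") %in% names(per_hand)))
    stop("both hands required")
  total <- 0
  for (h in c("left", "right")) {
    v <- unlist(per_hand[[h]][c("motoric", "cerebellar", "proprioceptive")])
    if (any(v < 0, na.rm = TRUE)) stop("panel scores must be nonnegative")
    total <- total + sum(v)
  }
  total
}

#' Per-hand motoric dysfunction score
#'
#' Sum of the muscle strength (panel 8), reflexes (panel 10) and
#' spasticity (panel 7) scores for one hand.
#' @param panel8,panel10,panel7 Nonnegative scores (vectorized).
#' @return Summed motoric score.
#' @export
motoric_dysfunction <- function(panel8, panel10, panel7) {
  if (any(c(panel8, panel10, panel7) < 0, na.rm = TRUE))
    stop("panel scores must be nonnegative")
  panel8 + panel10 + panel7
}

#' Append composite subpanel columns to a cohort table
#'
#' Adds `neurex_postural_sway`, `neurex_pronator_drift` and per-hand
#' `motoric_left/right`, plus a summed infratentorial MRI score, computed
#' from the cohort's panel and MRI columns.
#'
#' @param subjects Cohort data.frame from [generate_cohort()].
#' @return The cohort with subpanel columns appended.
#' @export
add_subpanel_scores <- function(subjects) {
  s <- subjects
  s$motoric_left <- motoric_dysfunction(s$panel8_left, s$panel10_left, s$panel7_left)
  s$motoric_right <- motoric_dysfunction(s$panel8_right, s$panel10_right, s$panel7_right)
  s$neurex_postural_sway <- neurex_postural_sway(
    s$panel16, s$panel12_le, s$panel14_le)
  s$neurex_pronator_drift <- vapply(seq_len(nrow(s)), function(i) {
    neurex_pronator_drift(list(
      left = c(motoric = s$motoric_left[i], cerebellar = s$panel12_left[i],
               proprioceptive = s$panel14_left[i]),
      right = c(motoric = s$motoric_right[i], cerebellar = s$panel12_right[i],
                proprioceptive = s$panel14_right[i])))
  }, numeric(1))
  mri_cols <- grep("^mri_", names(s), value = TRUE)
  s$mri_infratentorial <- rowSums(s[, mri_cols, drop = FALSE])
  s
}
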