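#' Default MPS biomarker panels
#'
#' Encodes the urinary GAG-NRE biomarker panels per MPS subtype as an
#' auditable rule set over an [nre_profile()]:
#'
#' * **MPS I** (iduronidase deficiency): presence of IdoAGlcNS(6S), IdoAGlcNS,
#'   IdoAGalNAc4S.
#' * **MPS II** (iduronate-2-sulfatase deficiency): presence of the
#'   2-O-sulfated markers IdoA2SGlcNS(6S), IdoA2SGlcNS, IdoA2SGalNAc4S; the
#'   2-O-sulfation distinguishes these from the MPS I markers.
#' * **MPS IIIc** (N-acetyltransferase deficiency): presence of the unique
#'   free-amine trisaccharides GlcNH2UAGlcNAc(6S), GlcNH2UAGlcNS(6S),
#'   GlcNH2(6S)UAGlcNS(6S).
#' * **MPS IVa** (GalNAc-6-sulfatase deficiency): GalNAc6S/GalNAc4S ratio
#'   above `ratio_cutoff` (default 0.95 = control mean 0.45 + 2 x SD 0.25).
#' * **MPS VI** (arylsulfatase B deficiency): GalNAc4S elevated on the
#'   NRE/dp2S1 scale. GalNAc4S is present in controls too, so this panel uses
#'   a higher threshold and, when a control reference is given, a fold-change
#'   condition instead of the absence condition.
#'
#' Presence markers are measured on the NRE/dp2S1 percentage scale; a marker
#' fires when it exceeds its threshold and (when a control reference profile
#' is provided) the control is below `control_max` (or below `value /
#' fold_vs_control` for fold-type rules). Thresholds are configuration
#' defaults pending calibration in larger cohorts. No panels are defined for
#' subtypes without patient data (IIIa/b/d, IVb, VII, IX).
#'
#' @param presence_threshold Default presence threshold (% of dp2S1).
#' @param control_max Maximum control-reference value for presence markers
#'   (% of dp2S1).
#' @param ratio_cutoff MPS IVa GalNAc6S/GalNAc4S cutoff.
#' @param vi_threshold MPS VI GalNAc4S threshold (% of dp2S1).
#' @param vi_fold Fold over control required for MPS VI when a control
#'   reference is provided.
#' @return A named list of panel definitions.
#' @export
default_panels <- function(presence_threshold = 1, control_max = 0.1,
                           ratio_cutoff = 0.95, vi_threshold = 4,
                           vi_fold = 2) {
  list(
    MPS_I = list(subtype = "MPS_I", rule = "presence",
                 markers = c("IdoAGlcNS(6S)", "IdoAGlcNS", "IdoAGalNAc4S"),
                 threshold = presence_threshold, control_max = control_max,
                 fold_vs_control = NA_real_, min_fired = 2),
    MPS_II = list(subtype = "MPS_II", rule = "presence",
                  markers = c("IdoA2SGlcNS(6S)", "IdoA2SGlcNS", "IdoA2SGalNAc4S"),
                  threshold = presence_threshold, control_max = control_max,
                  fold_vs_control = NA_real_, min_fired = 2),
    MPS_IIIc = list(subtype = "MPS_IIIc", rule = "presence",
                    markers = c("GlcNH2UAGlcNAc(6S)", "GlcNH2UAGlcNS(6S)",
                                "GlcNH2(6S)UAGlcNS(6S)"),
                    threshold = presence_threshold, control_max = control_max,
                    fold_vs_control = NA_real_, min_fired = 2),
    MPS_IVa = list(subtype = "MPS_IVa", rule = "ratio",
                   markers = "GalNAc6S/GalNAc4S",
                   threshold = ratio_cutoff, control_max = NA_real_,
                   fold_vs_control = NA_real_, min_fired = 1),
    MPS_VI = list(subtype = "MPS_VI", rule = "presence",
                  markers = "GalNAc4S",
                  threshold = vi_threshold, control_max = Inf,
                  fold_vs_control = vi_fold, min_fired = 1)
  )
}

.profile_marker <- function(profile, marker) {
  v <- profile$nre_over_dp2s1[marker]
  if (is.null(v) || length(v) == 0 || is.na(v)) 0 else unname(v)
}

#' Evaluate the biomarker panels on a sample profile
#'
#' Applies each panel's rules, scores subtypes by the fraction of fired
#' markers, and returns the verdict: the highest-scoring subtype among those
#' reaching their minimum fired-rule count, or `"no call"`. Deterministic:
#' ties break by fired-rule count, then panel order.
#'
#' @param profile An [nre_profile()] (typically a replicate summary).
#' @param panels Panel definitions, see [default_panels()].
#' @param control_reference Optional [nre_profile()] of an age-matched
#'   control; when given, presence markers must also satisfy the panel's
#'   control condition.
#' @return An object of class `subtype_call`: sample id, per-subtype scores,
#'   fired rules, `verdict`, and notes.
#' @export
evaluate_panels <- function(profile, panels = default_panels(),
                            control_reference = NULL) {
  stopifnot(inherits(profile, "nre_profile"))
  scores <- stats::setNames(numeric(length(panels)), names(panels))
  n_fired <- stats::setNames(integer(length(panels)), names(panels))
  fired_rules <- character(0)
  notes <- character(0)
  for (pn in names(panels)) {
    p <- panels[[pn]]
    if (p$rule == "ratio") {
      r <- profile$galnac_ratio
      fired <- !is.na(r) && r > p$threshold
      if (is.na(r))
        notes <- c(notes, sprintf("%s: ratio undefined (%s)", pn,
                                  attr(profile$galnac_ratio, "reason") %||% "missing"))
      if (fired)
        fired_rules <- c(fired_rules,
                         sprintf("%s: %s = %.2f > %.2f", pn, p$markers, r, p$threshold))
      n_fired[pn] <- as.integer(fired)
      scores[pn] <- as.numeric(fired)
    } else {
      for (mk in p$markers) {
        v <- .profile_marker(profile, mk)
        ok <- v > p$threshold
        if (ok && !is.null(control_reference)) {
          cv <- .profile_marker(control_reference, mk)
          ok <- if (!is.na(p$fold_vs_control))
            cv == 0 || v / cv >= p$fold_vs_control
          else cv <= p$control_max
          if (!ok)
            notes <- c(notes, sprintf("%s: %s elevated but not vs control (%.2f vs %.2f)",
                                      pn, mk, v, cv))
        }
        if (ok) {
          n_fired[pn] <- n_fired[pn] + 1L
          fired_rules <- c(fired_rules,
                           sprintf("%s: %s = %.2f%% of dp2S1 > %.2f%%",
                                   pn, mk, v, p$threshold))
        }
      }
      scores[pn] <- n_fired[pn] / length(p$markers)
    }
  }
  eligible <- vapply(names(panels), function(pn)
    n_fired[pn] >= panels[[pn]]$min_fired, logical(1))
  verdict <- if (!any(eligible)) "no call" else {
    idx <- which(eligible)
    idx <- idx[order(-scores[idx], -n_fired[idx])]
    names(panels)[idx[1]]
  }
  structure(list(sample_id = profile$sample_id, scores = scores,
                 n_fired = n_fired, fired_rules = fired_rules,
                 verdict = verdict, notes = notes,
                 used_control = !is.null(control_reference)),
            class = "subtype_call")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.subtype_call <- function(x, ...) {
  cat(sprintf("<subtype_call> %s: %s\n", x$sample_id, x$verdict))
  for (r in x$fired_rules) cat("  fired:", r, "\n")
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}

#' Compare baseline and follow-up profiles of one subject
#'
#' Per-marker fold change on the NRE/dp2S1 percentage scale between a
#' baseline (e.g. naive) and a follow-up (e.g. post-HSCT/ERT) profile, with a
#' `normalized` flag when the follow-up value falls below the panel's
#' presence threshold. Markers detected in neither profile are reported as
#' not detected, not as a zero fold change.
#'
#' @param profile_before,profile_after [nre_profile()] objects of the same
#'   subject.
#' @param panel One panel definition from [default_panels()].
#' @return A tibble with `marker`, `before`, `after`, `fold_change`,
#'   `normalized`, `status`.
#' @export
compare_followup <- function(profile_before, profile_after, panel) {
  stopifnot(inherits(profile_before, "nre_profile"),
            inherits(profile_after, "nre_profile"))
  markers <- if (panel$rule == "ratio") c("GalNAc6S", "GalNAc4S") else panel$markers
  rows <- lapply(markers, function(mk) {
    b <- .profile_marker(profile_before, mk)
    a <- .profile_marker(profile_after, mk)
    if (b == 0 && a == 0)
      return(tibble::tibble(marker = mk, before = 0, after = 0,
                            fold_change = NA_real_, normalized = NA,
                            status = "not detected"))
    fc <- if (b > 0) a / b else NA_real_
    thr <- if (panel$rule == "ratio") NA_real_ else panel$threshold
    norm <- if (is.na(thr)) NA else a < thr
    tibble::tibble(marker = mk, before = b, after = a, fold_change = fc,
                   normalized = norm,
                   status = if (isTRUE(norm)) "normalized" else "detected")
  })
  do.call(rbind, rows)
}
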