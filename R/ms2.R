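#' Construct an MS2 spectrum object
#'
#' @param precursor_mz Precursor m/z (Th).
#' @param precursor_z Precursor charge magnitude (1-4, negative mode).
#' @param mz,intensity Fragment peak vectors (same length).
#' @param rt Retention time in minutes (optional).
#' @param sample_id Sample identifier (optional).
#' @return An object of class `ms2_spectrum`; peaks are stored sorted by m/z.
#' @export
ms2_spectrum <- function(precursor_mz, precursor_z, mz, intensity,
                         rt = NA_real_, sample_id = NA_character_) {
  stopifnot(length(mz) == length(intensity), precursor_z %in% 1:4)
  if (any(intensity < 0)) stop("negative fragment intensity", call. = FALSE)
  ord <- order(mz)
  structure(list(precursor_mz = precursor_mz, precursor_z = as.integer(precursor_z),
                 peaks = tibble::tibble(mz = mz[ord], intensity = intensity[ord]),
                 rt = rt, sample_id = sample_id),
            class = "ms2_spectrum")
}

#' @export
print.ms2_spectrum <- function(x, ...) {
  cat(sprintf("<ms2_spectrum> precursor %.4f (%d-), %d peaks\n",
              x$precursor_mz, x$precursor_z, nrow(x$peaks)))
  invisible(x)
}

#' Read MS2 peak lists from an MGF file
#'
#' Minimal Mascot Generic Format reader covering BEGIN/END IONS blocks with
#' PEPMASS, CHARGE and RTINSECONDS headers and mz/intensity peak rows.
#'
#' @param path MGF file path.
#' @return A list of [ms2_spectrum()] objects.
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) stop("MGF file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^BEGIN IONS", lines)
  ends <- grep("^END IONS", lines)
  if (length(starts) != length(ends) || any(ends < starts))
    stop("MGF parse error: unbalanced BEGIN/END IONS", call. = FALSE)
  lapply(seq_along(starts), function(k) {
    block <- lines[(starts[k] + 1L):(ends[k] - 1L)]
    hdr <- grepl("=", block, fixed = TRUE)
    get <- function(key) {
      h <- block[hdr][grepl(paste0("^", key, "="), block[hdr])]
      if (length(h)) sub(paste0("^", key, "="), "", h[1]) else NA_character_
    }
    pep <- as.numeric(strsplit(get("PEPMASS"), "\\s+")[[1]][1])
    zs <- get("CHARGE")
    z <- if (is.na(zs)) 1L else as.integer(gsub("[^0-9]", "", zs))
    rts <- get("RTINSECONDS")
    rt <- if (is.na(rts)) NA_real_ else as.numeric(rts) / 60
    pk <- block[!hdr]
    pk <- pk[nzchar(trimws(pk))]
    if (length(pk)) {
      mat <- do.call(rbind, lapply(strsplit(trimws(pk), "\\s+"), function(v)
        as.numeric(v[1:2])))
      if (anyNA(mat)) stop(sprintf("MGF parse error: bad peak row in spectrum %d", k),
                           call. = FALSE)
    } else mat <- matrix(numeric(0), ncol = 2)
    ms2_spectrum(pep, z, mat[, 1], mat[, 2], rt = rt,
                 sample_id = get("TITLE"))
  })
}

#' Annotate the diagnostic fragment ions of an MS2 spectrum
#'
#' Matches the negative-mode diagnostic fragments (saturated-UA C/B ions at
#' 193.04 and 175.02, sulfated-UA B ion at 254.98, 2-AB-retaining HexNAc(S)
#' Y ions at 420.11 and 340.15, and the free-amine hexosamine C ions) within
#' a ppm tolerance and reports their intensities relative to the base peak.
#'
#' @param spectrum An [ms2_spectrum()].
#' @param frag_tol_ppm Fragment mass tolerance in ppm (default 20; MS2 is
#'   acquired at lower resolution than MS1).
#' @return A tibble with one row per diagnostic kind found: `fragment_kind`,
#'   `mz_theoretical`, `mz_observed`, `ppm_error`, `rel_intensity` (fraction
#'   of base peak).
#' @export
annotate_fragments <- function(spectrum, frag_tol_ppm = 20) {
  stopifnot(inherits(spectrum, "ms2_spectrum"))
  empty <- tibble::tibble(fragment_kind = character(), mz_theoretical = numeric(),
                          mz_observed = numeric(), ppm_error = numeric(),
                          rel_intensity = numeric())
  if (nrow(spectrum$peaks) == 0) {
    warning("empty MS2 peak list")
    return(empty)
  }
  base <- max(spectrum$peaks$intensity)
  if (base <= 0) return(empty)
  frags <- fragment_kinds()
  rows <- lapply(names(frags), function(kind) {
    theo <- frags[[kind]]
    d <- abs(spectrum$peaks$mz - theo)
    j <- which.min(d)
    ppm <- 1e6 * (spectrum$peaks$mz[j] - theo) / theo
    if (abs(ppm) > frag_tol_ppm) return(NULL)
    tibble::tibble(fragment_kind = kind, mz_theoretical = theo,
                   mz_observed = spectrum$peaks$mz[j], ppm_error = ppm,
                   rel_intensity = spectrum$peaks$intensity[j] / base)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) empty else out
}

.frag_rel <- function(annotations, kind) {
  i <- match(kind, annotations$fragment_kind)
  if (is.na(i)) 0 else annotations$rel_intensity[i]
}

#' Default thresholds for the MS2 isomer rules
#'
#' @param epimer_threshold Intensity-ratio threshold for the 193.04/175.02
#'   uronic epimer call (GlcA when the ratio exceeds it).
#' @param epimer_dead_band Multiplicative dead band around the threshold
#'   inside which the call is `unknown`.
#' @param presence_floor Relative intensity (fraction of base peak) below
#'   which a fragment counts as absent.
#' @param pos_cutoff Relative-intensity cutoff on the 420.11 ion for the
#'   4S/6S call.
#' @param pos_dead_band Additive dead band around `pos_cutoff`.
#' @param pos_polarity `"high_is_4S"` or `"high_is_6S"`. The assay
#'   demonstrates that the 420.11 abundance separates the positional isomers
#'   but its direction must be calibrated against standards
#'   (see [calibrate_sulfation()]).
#' @return A list of rule parameters.
#' @export
ms2_rule_config <- function(epimer_threshold = 1.0, epimer_dead_band = 0.2,
                            presence_floor = 0.01, pos_cutoff = 0.30,
                            pos_dead_band = 0.05,
                            pos_polarity = c("high_is_4S", "high_is_6S")) {
  list(epimer_threshold = epimer_threshold, epimer_dead_band = epimer_dead_band,
       presence_floor = presence_floor, pos_cutoff = pos_cutoff,
       pos_dead_band = pos_dead_band, pos_polarity = match.arg(pos_polarity))
}

#' Call the uronic-acid epimer from fragment intensity ratios
#'
#' The intact-UA C ion (193.04) is relatively more intense for GlcA-terminated
#' NREs, the dehydrated UA B ion (175.02) for IdoA-terminated NREs.
#'
#' @param annotations Output of [annotate_fragments()].
#' @param config Rule parameters, see [ms2_rule_config()].
#' @return `"GlcA"`, `"IdoA"`, or `"unknown"` (inside the dead band or when
#'   neither fragment is present).
#' @export
call_uronic_epimer <- function(annotations, config = ms2_rule_config()) {
  i193 <- .frag_rel(annotations, "C1_UA")
  i175 <- .frag_rel(annotations, "B1_UA")
  if (i193 < config$presence_floor && i175 < config$presence_floor)
    return("unknown")
  if (i175 == 0) return("GlcA")
  ratio <- i193 / i175
  upper <- config$epimer_threshold * (1 + config$epimer_dead_band)
  lower <- config$epimer_threshold / (1 + config$epimer_dead_band)
  if (ratio > upper) "GlcA" else if (ratio < lower) "IdoA" else "unknown"
}

#' Call a 2-O-sulfated uronic acid
#'
#' Fires when the sulfated-UA B ion (254.98) is present while the sulfated
#' HexNAc Y ion (420.11) is absent; when both are present the spectrum is
#' mixed (e.g. a disulfated species sulfated on both residues) and the call
#' is `FALSE` with a warning.
#'
#' @inheritParams call_uronic_epimer
#' @return Logical.
#' @export
call_2S_uronic <- function(annotations, config = ms2_rule_config()) {
  has_ua2s <- .frag_rel(annotations, "B1_UA2S") >= config$presence_floor
  has_hexnacs <- .frag_rel(annotations, "Y1_HexNAcS_2AB") >= config$presence_floor
  if (has_ua2s && has_hexnacs) {
    warning("mixed spectrum: both sulfated-UA and sulfated-HexNAc ions present")
    return(FALSE)
  }
  has_ua2s && !has_hexnacs
}

#' Call the HexNAc O-sulfation position (4S vs 6S)
#'
#' Thresholded decision on the relative abundance of the sulfated HexNAc Y
#' ion at 420.11 with configurable polarity and dead band; returns `unknown`
#' inside the dead band or when the fragment is absent.
#'
#' @inheritParams call_uronic_epimer
#' @return `"4S"`, `"6S"`, or `"unknown"`.
#' @export
call_sulfation_position <- function(annotations, config = ms2_rule_config()) {
  rel <- .frag_rel(annotations, "Y1_HexNAcS_2AB")
  if (rel < config$presence_floor) return("unknown")
  if (rel > config$pos_cutoff + config$pos_dead_band)
    return(if (config$pos_polarity == "high_is_4S") "4S" else "6S")
  if (rel < config$pos_cutoff - config$pos_dead_band)
    return(if (config$pos_polarity == "high_is_4S") "6S" else "4S")
  "unknown"
}

#' Calibrate the 4S/6S polarity and cutoff from labeled spectra
#'
#' Given spectra of known positional isomers (standards), sets the cutoff to
#' the midpoint of the two class means of the 420.11 relative abundance and
#' the polarity to the observed direction.
#'
#' @param spectra List of [ms2_spectrum()] objects.
#' @param positions Character vector (`"4S"`/`"6S"`), one per spectrum.
#' @param config Starting rule parameters.
#' @return An updated [ms2_rule_config()] list.
#' @export
calibrate_sulfation <- function(spectra, positions, config = ms2_rule_config()) {
  stopifnot(length(spectra) == length(positions),
            all(positions %in% c("4S", "6S")))
  rel <- vapply(spectra, function(s)
    .frag_rel(annotate_fragments(s), "Y1_HexNAcS_2AB"), numeric(1))
  m4 <- mean(rel[positions == "4S"]); m6 <- mean(rel[positions == "6S"])
  if (!is.finite(m4) || !is.finite(m6) || m4 == m6)
    stop("calibration requires spectra of both positional isomers with distinct 420.11 abundance",
         call. = FALSE)
  config$pos_cutoff <- (m4 + m6) / 2
  config$pos_polarity <- if (m4 > m6) "high_is_4S" else "high_is_6S"
  config
}

#' Call a free-amine glucosamine (GlcNH2) non-reducing terminus
#'
#' For dp3 NRE candidates, checks that (i) the precursor mass is consistent
#' with a composition carrying a free-amine hexosamine (fewer N-acetyl plus
#' N-sulfo groups than backbone units) and (ii) at least one annotated
#' fragment retains the glucosamine terminus (free-amine hexosamine C ions by
#' default). With mass evidence but no retaining fragment the call is
#' downgraded to tentative.
#'
#' @param spectrum An [ms2_spectrum()].
#' @param comp The candidate `gag_composition` (dp3 NRE).
#' @param mass_tol_ppm Precursor-mass tolerance (ppm).
#' @param retaining_kinds Fragment kinds accepted as terminus evidence.
#' @param config Rule parameters.
#' @return A list with `call` (logical) and `confidence`
#'   (`"diagnostic"`/`"tentative"`/`"none"`).
#' @export
call_glcnh2_terminus <- function(spectrum, comp, mass_tol_ppm = 15,
                                 retaining_kinds = c("C1_HexN", "C1_HexNS"),
                                 config = ms2_rule_config()) {
  stopifnot(inherits(spectrum, "ms2_spectrum"), inherits(comp, "gag_composition"))
  if (comp$terminus != "NRE" || comp$dp != 3)
    stop("GlcNH2-terminus rule applies to dp3 NRE compositions", call. = FALSE)
  # a free amine requires an unsubstituted backbone nitrogen; N-sulfation is
  # part of the shared SO3 count, so require acetyls alone not to fill the
  # backbone and the mass to match the composition as given
  free_amine_possible <- comp$n_acetyl < comp$n_hexN
  theo <- ion_mz(comp, z = spectrum$precursor_z)
  mass_ok <- abs(1e6 * (spectrum$precursor_mz - theo) / theo) <= mass_tol_ppm
  if (!free_amine_possible || !mass_ok)
    return(list(call = FALSE, confidence = "none"))
  ann <- annotate_fragments(spectrum)
  retained <- any(ann$fragment_kind %in% retaining_kinds &
                    ann$rel_intensity >= config$presence_floor)
  list(call = TRUE, confidence = if (retained) "diagnostic" else "tentative")
}

#' Assign an isomer-level structure from an MS2 spectrum
#'
#' Runs the diagnostic rules (uronic epimer, 2-O-sulfated uronic acid,
#' HexNAc sulfation position, HexNAc-sulfated presence) and scores the named
#' candidate structures of the spectrum's composition: +1 per agreeing
#' attribute, -1 per contradicted attribute, `unknown` calls neutral. The
#' top-scoring candidate is returned with `diagnostic` confidence when unique
#' with at least one rule fired, `tentative` otherwise.
#'
#' @param spectrum An [ms2_spectrum()].
#' @param record_id Composition record id the precursor was matched to.
#' @param structures Structure reference table, see [gag_structures()].
#' @param config Rule parameters.
#' @return A list with `structure`, `confidence`, and `evidence` (named list
#'   of rule outputs).
#' @export
call_isomer <- function(spectrum, record_id, structures = gag_structures(),
                        config = ms2_rule_config()) {
  cand <- structures[structures$record_id == record_id, , drop = FALSE]
  if (!nrow(cand))
    stop("no named isomers for composition ", record_id, call. = FALSE)
  ann <- annotate_fragments(spectrum)
  epimer <- call_uronic_epimer(ann, config)
  ua2s <- suppressWarnings(call_2S_uronic(ann, config))
  pos <- call_sulfation_position(ann, config)
  hexnac_sulfated <- .frag_rel(ann, "Y1_HexNAcS_2AB") >= config$presence_floor
  score <- numeric(nrow(cand))
  fired <- 0L
  sc <- function(called, truth) ifelse(truth == called, 1, -1)
  if (epimer != "unknown") {
    fired <- fired + 1L
    known <- cand$epimer %in% c("GlcA", "IdoA")
    score[known] <- score[known] + sc(epimer, cand$epimer[known])
  }
  if (pos != "unknown") {
    fired <- fired + 1L
    known <- cand$hexnac_pos %in% c("4S", "6S")
    score[known] <- score[known] + sc(pos, cand$hexnac_pos[known])
  }
  if (isTRUE(ua2s)) {
    fired <- fired + 1L
    score <- score + ifelse(cand$ua_2s, 1, -1)
  }
  # absence of the sulfated-HexNAc ion contradicts 4S/6S candidates
  score <- score + ifelse((cand$hexnac_pos %in% c("4S", "6S")) == hexnac_sulfated,
                          0.5, -0.5)
  top <- which(score == max(score))
  confidence <- if (length(top) == 1 && fired >= 1) "diagnostic" else "tentative"
  list(structure = cand$structure[top[1]], confidence = confidence,
       evidence = list(epimer = epimer, ua_2s = ua2s, position = pos,
                       hexnac_sulfated = hexnac_sulfated, rules_fired = fired))
}
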