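#' Phenotype models for the synthetic-data generator
#'
#' Each model fixes the expected relative-intensity vector over named NRE
#' structures, the internal-disaccharide background, the expected NRE share
#' of total identified saccharide intensity, the 2-AB labeling efficiency,
#' and the subtype call the profiler is expected to return. The vectors are
#' qualitative transcriptions of the published urinary profiles (which
#' markers are elevated, reduced or absent per subtype), not digitized bar
#' heights: the control model reproduces the reported control statistics
#' (NRE fraction 10.3%, GalNAc6S/GalNAc4S 0.45, labeling yield 91%); patient
#' models add the subtype's diagnostic markers at levels qualitatively
#' consistent with the reported profiles; treated models attenuate them
#' (post-HSCT MPS VI is modeled as normalized and expects "no call").
#'
#' @param name One of `phenotype_names()`.
#' @return A `phenotype_model` list with `name`, `nre_abundance`,
#'   `internal_abundance` (named, normalized internally), `nre_total_fraction`
#'   (percent), `labeling_efficiency`, `expected_call`.
#' @export
phenotype_model <- function(name = phenotype_names()) {
  name <- match.arg(name)
  control_nre <- c(
    "GlcAGalNAc4S" = 0.18, "GlcAGalNAc6S" = 0.21, "UAGalNAc" = 0.10,
    "UAGlcNAc" = 0.12, "UAGlcNS" = 0.07, "UAGlcNS(6S)" = 0.05,
    "UA2SGlcNS" = 0.02, "GalNAc4S" = 0.13, "GalNAc6S" = 0.0585,
    "GlcNS" = 0.05, "GlcNH2" = 0.01, "GlcNS(6S)" = 0.02
  )
  control_internal <- c(
    "dUAGalNAc4S" = 0.40, "dUAGalNAc6S" = 0.34, "dUAGalNAc" = 0.08,
    "dUAGlcNAc" = 0.06, "dUAGlcNS" = 0.05, "dUAGlcNS(6S)" = 0.02,
    "dUA2SGalNAc4S" = 0.05
  )
  add <- function(base, extra, keep = 1 - sum(extra)) c(base * keep, extra)
  m <- switch(name,
    control = list(nre = control_nre, internal = control_internal, frac = 10.3),
    MPS_I_naive = list(
      nre = add(control_nre, c("IdoAGalNAc4S" = 0.25, "IdoAGlcNS" = 0.10,
                               "IdoAGlcNS(6S)" = 0.08, "IdoAGalNAc6S" = 0.04)),
      internal = control_internal, frac = 18),
    MPS_I_treated = list(
      nre = add(control_nre, c("IdoAGalNAc4S" = 0.12, "IdoAGlcNS" = 0.09,
                               "IdoAGlcNS(6S)" = 0.08, "IdoAGalNAc6S" = 0.02)),
      internal = control_internal, frac = 13),
    MPS_II = list(
      nre = add(control_nre, c("IdoA2SGalNAc4S" = 0.12, "IdoA2SGlcNS" = 0.09,
                               "IdoA2SGlcNS(6S)" = 0.10, "IdoA2SGalNAc" = 0.03)),
      internal = control_internal, frac = 16),
    MPS_IIIc = list(
      nre = add(control_nre, c("GlcNH2UAGlcNAc(6S)" = 0.15,
                               "GlcNH2UAGlcNS(6S)" = 0.12,
                               "GlcNH2(6S)UAGlcNS(6S)" = 0.08)),
      internal = c("dUAGalNAc4S" = 0.25, "dUAGalNAc6S" = 0.20,
                   "dUAGalNAc" = 0.08, "dUAGlcNAc" = 0.08, "dUAGlcNS" = 0.20,
                   "dUAGlcNS(6S)" = 0.14, "dUA2SGalNAc4S" = 0.05),
      frac = 30),
    MPS_IVa = list(
      nre = local({
        v <- control_nre
        v[["GalNAc4S"]] <- 0.10
        v[["GalNAc6S"]] <- 0.15  # ratio 1.5, as reported for treated patients
        v
      }),
      internal = control_internal, frac = 14),
    MPS_VI_naive = list(
      nre = local({
        v <- control_nre
        v[["GalNAc4S"]] <- 0.44  # three-fold elevation on the NRE/dp2S1 scale
        v[["GalNAc6S"]] <- 0     # not detected in the naive patient
        v
      }),
      internal = control_internal, frac = 11.3),
    MPS_VI_treated = list(
      nre = local({
        v <- control_nre
        v[["GalNAc4S"]] <- 0.14
        v[["GalNAc6S"]] <- 0.06
        v
      }),
      internal = control_internal, frac = 10.3)
  )
  expected <- c(control = "no call", MPS_I_naive = "MPS_I",
                MPS_I_treated = "MPS_I", MPS_II = "MPS_II",
                MPS_IIIc = "MPS_IIIc", MPS_IVa = "MPS_IVa",
                MPS_VI_naive = "MPS_VI", MPS_VI_treated = "no call")
  structure(list(name = name,
                 nre_abundance = m$nre / sum(m$nre),
                 internal_abundance = m$internal / sum(m$internal),
                 nre_total_fraction = m$frac,
                 labeling_efficiency = 0.91,
                 expected_call = unname(expected[name])),
            class = "phenotype_model")
}

#' @rdname phenotype_model
#' @export
phenotype_names <- function() {
  c("control", "MPS_I_naive", "MPS_I_treated", "MPS_II", "MPS_IIIc",
    "MPS_IVa", "MPS_VI_naive", "MPS_VI_treated")
}

#' Simulation configuration
#'
#' @param seed Integer seed; every draw of a simulation run derives from it.
#' @param n_replicates Technical replicates per sample (default 3).
#' @param ppm_sigma Gaussian m/z error, ppm (default 3, ~5 sigma inside the
#'   15 ppm matching gate).
#' @param intensity_cv Lognormal intensity coefficient of variation
#'   (default 0.15).
#' @param adduct_fraction Fraction of each species' intensity appearing as
#'   the co-eluting DBA-adduct satellite.
#' @param sulfate_loss_fraction Fraction appearing as the co-eluting
#'   one-sulfate-loss satellite (sulfated species only).
#' @param decoy_rate Decoy features per true feature (Poisson mean factor).
#' @param charge_weights Unnormalized weights for charge states 1-4; each
#'   species uses the weights of its feasible charges.
#' @param rt_jitter_sd Retention-time jitter SD, minutes.
#' @param run_length Chromatographic run length, minutes.
#' @param total_intensity Expected summed internal-disaccharide intensity
#'   (abundance units).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_replicates = 3L, ppm_sigma = 3,
                       intensity_cv = 0.15, adduct_fraction = 0.15,
                       sulfate_loss_fraction = 0.10, decoy_rate = 0.5,
                       charge_weights = c(0.55, 0.30, 0.10, 0.05),
                       rt_jitter_sd = 0.03, run_length = 60,
                       total_intensity = 1e9) {
  stopifnot(ppm_sigma >= 0, intensity_cv >= 0, n_replicates >= 1)
  list(seed = as.integer(seed), n_replicates = as.integer(n_replicates),
       ppm_sigma = ppm_sigma, intensity_cv = intensity_cv,
       adduct_fraction = adduct_fraction,
       sulfate_loss_fraction = sulfate_loss_fraction,
       decoy_rate = decoy_rate, charge_weights = charge_weights,
       rt_jitter_sd = rt_jitter_sd, run_length = run_length,
       total_intensity = total_intensity)
}

# lognormal noise with mean 1 and coefficient of variation cv
.lognoise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# composition object for a structure-table row id
.record_composition <- function(record_id, structures = gag_structures()) {
  parts <- regmatches(record_id,
    regexec("^(int|nre)-dp(\\d+)-ac(\\d+)-s(\\d+)-(2ab|free)$", record_id))[[1]]
  if (!length(parts)) stop("unparseable record id: ", record_id, call. = FALSE)
  dp <- as.integer(parts[3])
  terminus <- if (parts[2] == "int") "internal" else "NRE"
  layout <- .residue_layout(terminus, dp)
  glycan_composition(layout$n_dUA, layout$n_UA, layout$n_hexN,
                     as.integer(parts[4]), as.integer(parts[5]),
                     parts[6] == "2ab")
}

#' Simulate the MS1 feature table of one sample
#'
#' For each structure with nonzero expected intensity, draws a lognormal true
#' intensity, splits it over feasible charge states, adds co-eluting
#' DBA-adduct and one-sulfate-loss satellite features, perturbs every m/z by
#' Gaussian ppm error and retention times by Gaussian jitter, splits the
#' internal dp2S2 QC species into labeled and unlabeled according to the
#' labeling efficiency, and appends decoy features at random m/z. The
#' ground-truth assignment of every feature is attached as the `"truth"`
#' attribute.
#'
#' The caller controls the random state: [simulate_cohort()] seeds once from
#' `config$seed`; call `set.seed()` first for a standalone reproducible
#' sample.
#'
#' @param model A [phenotype_model()].
#' @param config A [sim_config()].
#' @param sample_id Sample identifier for the feature table.
#' @param structures Structure reference table.
#' @return Feature tibble (`feature_id`, `sample_id`, `rt_min`, `mz`,
#'   `charge`, `intensity`, `sn`) with a `"truth"` tibble attribute.
#' @export
simulate_sample <- function(model, config = sim_config(),
                            sample_id = model$name,
                            structures = gag_structures()) {
  stopifnot(inherits(model, "phenotype_model"))
  nre_total <- config$total_intensity *
    model$nre_total_fraction / (100 - model$nre_total_fraction)
  species <- list()
  plan <- function(structure, expected) {
    if (expected <= 0) return()
    row <- structures[structures$structure == structure, , drop = FALSE]
    if (nrow(row) != 1)
      stop("structure not in reference table: ", structure, call. = FALSE)
    species[[length(species) + 1]] <<- list(structure = structure,
                                            record_id = row$record_id,
                                            rt = row$rt_ref, expected = expected)
  }
  for (s in names(model$internal_abundance)) {
    e <- model$internal_abundance[[s]] * config$total_intensity
    if (s == "dUA2SGalNAc4S") {  # dp2S2 QC pair: labeled / unlabeled split
      plan(s, e * model$labeling_efficiency)
      plan("dUA2SGalNAc4S(unlabeled)", e * (1 - model$labeling_efficiency))
    } else plan(s, e)
  }
  for (s in names(model$nre_abundance))
    plan(s, model$nre_abundance[[s]] * nre_total)

  rows <- list()
  truth <- list()
  emit <- function(structure, record_id, comp, z, n_DBA, n_SO3_lost, rt, intensity) {
    mz <- ion_mz(comp, z, n_DBA, n_SO3_lost) *
      (1 + stats::rnorm(1, 0, config$ppm_sigma) * 1e-6)
    rows[[length(rows) + 1]] <<- c(rt_min = rt + stats::rnorm(1, 0, config$rt_jitter_sd),
                                   mz = mz, charge = z, intensity = intensity,
                                   sn = stats::rlnorm(1, log(100), 0.5))
    truth[[length(truth) + 1]] <<- tibble::tibble(
      structure = structure, record_id = record_id, z = z, n_DBA = n_DBA,
      n_SO3_lost = n_SO3_lost, decoy = FALSE)
  }
  for (sp in species) {
    comp <- .record_composition(sp$record_id, structures)
    total <- sp$expected * .lognoise(1, config$intensity_cv)
    zmax <- .max_charge(comp$n_SO3, comp$n_UA, comp$n_dUA)
    w <- config$charge_weights[1:zmax]
    w <- w / sum(w)
    for (z in 1:zmax) {
      base <- total * w[z]
      if (base <= 0) next
      sat_loss <- if (comp$n_SO3 >= 1) base * config$sulfate_loss_fraction else 0
      sat_add <- base * config$adduct_fraction
      parent <- base - sat_loss - sat_add
      emit(sp$structure, sp$record_id, comp, z, 0L, 0L, sp$rt,
           parent * .lognoise(1, config$intensity_cv))
      if (sat_add > 0)
        emit(sp$structure, sp$record_id, comp, z, 1L, 0L, sp$rt,
             sat_add * .lognoise(1, config$intensity_cv))
      if (sat_loss > 0 && z <= .max_charge(comp$n_SO3 - 1L, comp$n_UA, comp$n_dUA))
        emit(sp$structure, sp$record_id, comp, z, 0L, 1L, sp$rt,
             sat_loss * .lognoise(1, config$intensity_cv))
    }
  }
  n_true <- length(rows)
  n_decoy <- stats::rpois(1, config$decoy_rate * n_true)
  for (k in seq_len(n_decoy)) {
    rows[[length(rows) + 1]] <- c(
      rt_min = stats::runif(1, 2, config$run_length - 2),
      mz = stats::runif(1, 220, 2000),
      charge = sample(1:2, 1),
      intensity = stats::rlnorm(1, log(config$total_intensity * 1e-3), 1),
      sn = stats::rlnorm(1, log(10), 0.5))
    truth[[length(truth) + 1]] <- tibble::tibble(
      structure = NA_character_, record_id = NA_character_, z = NA_integer_,
      n_DBA = NA_integer_, n_SO3_lost = NA_integer_, decoy = TRUE)
  }
  mat <- do.call(rbind, rows)
  features <- tibble::tibble(
    feature_id = seq_len(nrow(mat)), sample_id = sample_id,
    rt_min = mat[, "rt_min"], mz = mat[, "mz"],
    charge = as.integer(mat[, "charge"]), intensity = mat[, "intensity"],
    sn = mat[, "sn"])
  tt <- do.call(rbind, truth)
  tt$feature_id <- features$feature_id
  tt$sample_id <- sample_id
  attr(features, "truth") <- tt[, c("feature_id", "sample_id", "structure",
                                    "record_id", "z", "n_DBA", "n_SO3_lost",
                                    "decoy")]
  features
}

#' Simulate a cohort of samples with technical replicates
#'
#' @param models List of [phenotype_model()] objects (or names accepted by
#'   [phenotype_model()]).
#' @param config A [sim_config()]; `config$seed` makes the whole cohort
#'   reproducible.
#' @return A list with `features` (one tibble per sample x replicate, named
#'   by sample id), `truth` (combined truth tibble) and `manifest` (tibble
#'   `sample_id`, `subject`, `phenotype`, `replicate`, `expected_call`).
#' @export
simulate_cohort <- function(models = lapply(phenotype_names(), phenotype_model),
                            config = sim_config()) {
  if (length(models) == 0)
    return(list(features = list(), truth = NULL,
                manifest = tibble::tibble(sample_id = character(),
                                          subject = character(),
                                          phenotype = character(),
                                          replicate = integer(),
                                          expected_call = character())))
  models <- lapply(models, function(m)
    if (inherits(m, "phenotype_model")) m else phenotype_model(m))
  set.seed(config$seed)
  features <- list()
  manifest <- list()
  for (m in models) {
    for (r in seq_len(config$n_replicates)) {
      sid <- sprintf("%s_r%d", m$name, r)
      features[[sid]] <- simulate_sample(m, config, sample_id = sid)
      manifest[[sid]] <- tibble::tibble(sample_id = sid, subject = m$name,
                                        phenotype = m$name, replicate = r,
                                        expected_call = m$expected_call)
    }
  }
  truth <- do.call(rbind, lapply(features, attr, "truth"))
  rownames(truth) <- NULL
  list(features = features, truth = truth,
       manifest = do.call(rbind, manifest))
}

#' Simulate an MS2 spectrum for a named structure
#'
#' Builds a centroided fragment spectrum from the structure's diagnostic-ion
#' template: GlcA-terminated templates emphasize the intact-UA C ion (193.04)
#' over the dehydrated B ion (175.02) and IdoA templates the reverse;
#' 2-O-sulfated uronic templates contain the sulfated-UA ion (254.98);
#' templates with sulfated HexNAc contain the 420.11 Y ion, strong for 4S and
#' weak for 6S; free-amine (GlcNH2) termini contribute hexosamine C ions.
#' Template intensities get lognormal noise and low-level random noise peaks
#' are added.
#'
#' @param structure Structure name from [gag_structures()].
#' @param config A [sim_config()] (drives the noise level; the caller seeds
#'   the random state).
#' @param structures Structure reference table.
#' @param n_noise_peaks Number of random low-intensity noise peaks.
#' @return An [ms2_spectrum()].
#' @export
simulate_ms2 <- function(structure, config = sim_config(),
                         structures = gag_structures(), n_noise_peaks = 6) {
  row <- structures[structures$structure == structure, , drop = FALSE]
  if (nrow(row) != 1)
    stop("no fragment template for structure: ", structure, call. = FALSE)
  comp <- .record_composition(row$record_id, structures)
  tmpl <- c()
  if (comp$terminus == "NRE" && comp$n_UA >= 1 && comp$dp == 2) {
    tmpl <- switch(row$epimer,
      GlcA = c(C1_UA = 0.85, B1_UA = 0.25),
      IdoA = c(C1_UA = 0.22, B1_UA = 0.80),
      c(C1_UA = 0.50, B1_UA = 0.50))
  }
  if (row$ua_2s) tmpl <- c(tmpl, B1_UA2S = 0.60)
  # 420.11 strong for 4S, weak for 6S; the in-source-labile 6-O-sulfate makes
  # the de-sulfated Y ion (340.15) the anchor peak of 6S spectra
  if (row$hexnac_pos == "4S")
    tmpl <- c(tmpl, Y1_HexNAcS_2AB = 0.55,
              if (comp$labeled) c(Y1_HexNAc_2AB = 0.45))
  if (row$hexnac_pos == "6S")
    tmpl <- c(tmpl, Y1_HexNAcS_2AB = 0.10,
              if (comp$labeled) c(Y1_HexNAc_2AB = 1.00))
  if (comp$n_acetyl >= 1 && row$hexnac_pos == "none" && comp$labeled &&
      comp$terminus == "NRE")
    tmpl <- c(tmpl, Y1_HexNAc_2AB = 0.50)
  if (row$glcnh2) {
    kind <- if (grepl("^GlcNH2\\(6S\\)", structure)) "C1_HexNS" else "C1_HexN"
    tmpl <- c(tmpl, stats::setNames(0.45, kind))
  }
  z <- if (comp$n_SO3 >= 2) 2L else 1L
  z <- min(z, .max_charge(comp$n_SO3, comp$n_UA, comp$n_dUA))
  prec <- ion_mz(comp, z)
  mzs <- vapply(names(tmpl), fragment_mz, numeric(1))
  ints <- 100 * unname(tmpl) * .lognoise(length(tmpl), 0.25)
  mzs <- unname(mzs) * (1 + stats::rnorm(length(mzs), 0, config$ppm_sigma * 2) * 1e-6)
  if (n_noise_peaks > 0) {
    noise_mz <- stats::runif(n_noise_peaks, 100, max(prec * z, 450))
    noise_int <- stats::runif(n_noise_peaks, 0, 0.8)
    mzs <- c(mzs, noise_mz)
    ints <- c(ints, noise_int)
  }
  ms2_spectrum(prec, z, mzs, ints, rt = row$rt_ref, sample_id = structure)
}

#' Simulate labeled/unlabeled dp2S2 intensity pairs
#'
#' Draws `n` independent (labeled, unlabeled) intensity pairs of the internal
#' dp2S2 QC disaccharide at a given derivatization efficiency with lognormal
#' intensity noise — the elementary experiment behind the labeling-yield QC.
#'
#' @param n Number of pairs.
#' @param efficiency True labeling efficiency in (0, 1].
#' @param config A [sim_config()] (noise level and total intensity scale).
#' @return A tibble with columns `labeled` and `unlabeled`.
#' @export
simulate_dp2s2_pairs <- function(n, efficiency = 0.91, config = sim_config()) {
  stopifnot(n >= 1, efficiency > 0, efficiency <= 1)
  total <- config$total_intensity * 0.05 * .lognoise(n, config$intensity_cv)
  tibble::tibble(
    labeled = total * efficiency * .lognoise(n, config$intensity_cv),
    unlabeled = total * (1 - efficiency) * .lognoise(n, config$intensity_cv))
}
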