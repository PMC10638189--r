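spec_from <- function(mz, int, prec = 596.1403, z = 1) {
  ms2_spectrum(prec, z, mz, int)
}

test_that("diagnostic fragments annotate within tolerance, others do not", {
  s <- spec_from(c(420.108, 254.982, 400.000, 193.0354),
                 c(50, 30, 10, 100))
  ann <- annotate_fragments(s)
  expect_setequal(ann$fragment_kind, c("Y1_HexNAcS_2AB", "B1_UA2S", "C1_UA"))
  expect_equal(ann$rel_intensity[ann$fragment_kind == "Y1_HexNAcS_2AB"], 0.5)
  expect_true(all(abs(ann$ppm_error) <= 20))
  expect_warning(empty <- annotate_fragments(ms2_spectrum(500, 1, numeric(0),
                                                          numeric(0))),
                 "empty")
  expect_equal(nrow(empty), 0L)
})

test_that("uronic epimer call follows the 193.04/175.02 intensity ratio", {
  glca <- annotate_fragments(spec_from(c(193.0354, 175.0248), c(100, 20)))
  idoa <- annotate_fragments(spec_from(c(193.0354, 175.0248), c(20, 100)))
  expect_equal(call_uronic_epimer(glca), "GlcA")
  expect_equal(call_uronic_epimer(idoa), "IdoA")
  none <- annotate_fragments(spec_from(420.108, 100))
  expect_equal(call_uronic_epimer(none), "unknown")
  # dead band
  near <- annotate_fragments(spec_from(c(193.0354, 175.0248), c(100, 95)))
  expect_equal(call_uronic_epimer(near), "unknown")
})

test_that("epimer call is antisymmetric and invariant under intensity scaling", {
  set.seed(9)
  for (k in 1:20) {
    i1 <- runif(1, 1, 100); i2 <- runif(1, 1, 100)
    a <- call_uronic_epimer(annotate_fragments(
      spec_from(c(193.0354, 175.0248), c(i1, i2))))
    b <- call_uronic_epimer(annotate_fragments(
      spec_from(c(193.0354, 175.0248), c(i2, i1))))
    swapped <- c(GlcA = "IdoA", IdoA = "GlcA", unknown = "unknown")
    expect_equal(b, unname(swapped[a]))
    scaled <- call_uronic_epimer(annotate_fragments(
      spec_from(c(193.0354, 175.0248), 37.5 * c(i1, i2))))
    expect_equal(scaled, a)
  }
})

test_that("2-O-sulfated uronic call requires 254.98 present and 420.11 absent", {
  yes <- annotate_fragments(spec_from(c(254.9816, 193.0354), c(60, 100)))
  expect_true(call_2S_uronic(yes))
  no <- annotate_fragments(spec_from(c(193.0354), c(100)))
  expect_false(call_2S_uronic(no))
  both <- annotate_fragments(spec_from(c(254.9816, 420.1082), c(60, 60)))
  expect_warning(res <- call_2S_uronic(both), "mixed")
  expect_false(res)
})

test_that("sulfation-position call is thresholded with a dead band and polarity", {
  cfg <- ms2_rule_config()  # high 420.11 -> 4S, cutoff 0.30 +/- 0.05
  high <- annotate_fragments(spec_from(c(420.1082, 193.0354), c(60, 100)))
  low <- annotate_fragments(spec_from(c(420.1082, 193.0354), c(10, 100)))
  mid <- annotate_fragments(spec_from(c(420.1082, 193.0354), c(30, 100)))
  absent <- annotate_fragments(spec_from(193.0354, 100))
  expect_equal(call_sulfation_position(high, cfg), "4S")
  expect_equal(call_sulfation_position(low, cfg), "6S")
  expect_equal(call_sulfation_position(mid, cfg), "unknown")
  expect_equal(call_sulfation_position(absent, cfg), "unknown")
  flipped <- ms2_rule_config(pos_polarity = "high_is_6S")
  expect_equal(call_sulfation_position(high, flipped), "6S")
})

test_that("polarity and cutoff calibrate from spectra of known standards", {
  set.seed(11)
  spectra <- c(lapply(1:5, function(i) simulate_ms2("GlcAGalNAc4S")),
               lapply(1:5, function(i) simulate_ms2("GlcAGalNAc6S")))
  cfg <- calibrate_sulfation(spectra, rep(c("4S", "6S"), each = 5))
  expect_equal(cfg$pos_polarity, "high_is_4S")
  expect_gt(cfg$pos_cutoff, 0.1)
  expect_lt(cfg$pos_cutoff, 0.9)
  expect_error(calibrate_sulfation(spectra[1:5], rep("4S", 5)), "both")
})

test_that("GlcNH2 terminus call combines precursor mass and retaining fragments", {
  comp <- glycan_composition(n_UA = 1, n_hexN = 2, n_acetyl = 1, n_SO3 = 1,
                             labeled = TRUE)
  expect_equal(round(ion_mz(comp, 1), 4), 757.2091)
  with_frag <- ms2_spectrum(757.2091, 1, c(178.0721, 300), c(40, 100))
  res <- call_glcnh2_terminus(with_frag, comp)
  expect_true(res$call)
  expect_equal(res$confidence, "diagnostic")
  # mass-only evidence downgrades to tentative
  no_frag <- ms2_spectrum(757.2091, 1, c(300, 350), c(100, 20))
  res2 <- call_glcnh2_terminus(no_frag, comp)
  expect_true(res2$call)
  expect_equal(res2$confidence, "tentative")
  # fully acetylated backbone cannot carry a free amine
  full <- glycan_composition(n_UA = 1, n_hexN = 2, n_acetyl = 2, n_SO3 = 1,
                             labeled = TRUE)
  res3 <- call_glcnh2_terminus(ms2_spectrum(ion_mz(full, 1), 1, 300, 100), full)
  expect_false(res3$call)
  # wrong precursor mass fails the mass gate
  off <- ms2_spectrum(760.0, 1, 178.0721, 100)
  expect_false(call_glcnh2_terminus(off, comp)$call)
})

test_that("simulated spectra encode the published qualitative fragment rules", {
  set.seed(21)
  s2s <- simulate_ms2("IdoA2SGalNAc")
  ann <- annotate_fragments(s2s)
  expect_true("B1_UA2S" %in% ann$fragment_kind)
  expect_true(suppressWarnings(call_2S_uronic(ann)))
  glca <- annotate_fragments(simulate_ms2("GlcAGalNAc4S"))
  expect_gt(.subset2(glca, "rel_intensity")[glca$fragment_kind == "C1_UA"],
            glca$rel_intensity[glca$fragment_kind == "B1_UA"])
  # noise-only spectrum triggers no diagnostic calls
  noise <- ms2_spectrum(596.14, 1, c(111.1, 222.2, 333.3), c(5, 10, 2))
  ann0 <- annotate_fragments(noise)
  expect_equal(call_uronic_epimer(ann0), "unknown")
  expect_false(call_2S_uronic(ann0))
})

test_that("the rule set recovers declared structures on noisy synthetic spectra", {
  set.seed(31)
  targets <- c("IdoAGalNAc4S", "GlcAGalNAc4S", "IdoAGalNAc6S", "GlcAGalNAc6S",
               "IdoA2SGalNAc", "GalNAc4S", "GalNAc6S",
               "GlcNH2UAGlcNAc(6S)", "GlcNH2UAGlcNS(6S)")
  n_per <- 30
  correct <- 0
  for (st in targets) {
    row <- gag_structures()[gag_structures()$structure == st, ]
    for (k in seq_len(n_per)) {
      call <- suppressWarnings(
        call_isomer(simulate_ms2(st), row$record_id))
      if (call$structure == st) correct <- correct + 1
    }
  }
  expect_gte(correct / (length(targets) * n_per), 0.95)
})

test_that("MGF peak lists round-trip through the reader", {
  path <- withr::local_tempfile(fileext = ".mgf")
  writeLines(c("BEGIN IONS", "TITLE=spec1", "PEPMASS=596.1403", "CHARGE=1-",
               "RTINSECONDS=1959.6", "193.0354 100.0", "175.0248 25.0",
               "END IONS",
               "BEGIN IONS", "TITLE=spec2", "PEPMASS=337.5449", "CHARGE=2-",
               "420.1082 55.0", "END IONS"), path)
  specs <- read_mgf(path)
  expect_length(specs, 2L)
  expect_equal(specs[[1]]$precursor_mz, 596.1403)
  expect_equal(specs[[1]]$precursor_z, 1L)
  expect_equal(specs[[1]]$rt, 32.66, tolerance = 1e-6)
  expect_equal(nrow(specs[[1]]$peaks), 2L)
  expect_equal(specs[[2]]$peaks$intensity, 55)
  writeLines(c("BEGIN IONS", "PEPMASS=1"), path)
  expect_error(read_mgf(path), "unbalanced")
})
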