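test_that("neutral masses match the elemental-formula oracle on key species", {
  # 2-AB-labeled saturated (NRE) mono-sulfated disaccharide
  nre_dp2s1 <- glycan_composition(n_UA = 1, n_hexN = 1, n_acetyl = 1,
                                  n_SO3 = 1, labeled = TRUE)
  expect_equal(neutral_mass(nre_dp2s1),
               oracle_neutral_mass(n_UA = 1, n_hexNAc = 1, n_SO3 = 1,
                                   labeled = TRUE),
               tolerance = 1e-6)
  expect_equal(round(neutral_mass(nre_dp2s1), 4), 597.1476)

  # internal counterpart: dUA instead of UA, one water lighter
  int_dp2s1 <- glycan_composition(n_dUA = 1, n_hexN = 1, n_acetyl = 1,
                                  n_SO3 = 1, labeled = TRUE)
  expect_equal(round(neutral_mass(int_dp2s1), 4), 579.1370)

  # free unlabeled uronic acid
  ua <- glycan_composition(n_UA = 1, labeled = FALSE)
  expect_equal(round(neutral_mass(ua), 4), 194.0427)

  # GlcNH2-UA-GlcNAc(6S)-2AB trisaccharide (free-amine terminus)
  dp3 <- glycan_composition(n_UA = 1, n_hexN = 2, n_acetyl = 1, n_SO3 = 1,
                            labeled = TRUE)
  expect_equal(neutral_mass(dp3),
               oracle_neutral_mass(n_UA = 1, n_hexNAc = 1, n_hexN_free = 1,
                                   n_SO3 = 1, labeled = TRUE),
               tolerance = 1e-6)
  expect_equal(round(neutral_mass(dp3), 4), 758.2164)
})

test_that("ion m/z agrees with the formula oracle across the composition lattice", {
  grid <- expand.grid(n_dUA = 0:1, n_UA = 0:1, n_hexN = 0:2, n_acetyl = 0:2,
                      n_SO3 = 0:3, labeled = c(TRUE, FALSE),
                      n_DBA = 0:1, lost = 0:1)
  checked <- 0
  for (k in seq_len(nrow(grid))) {
    g <- grid[k, ]
    comp <- tryCatch(
      glycan_composition(g$n_dUA, g$n_UA, g$n_hexN, g$n_acetyl, g$n_SO3,
                         g$labeled),
      error = function(e) NULL)
    if (is.null(comp) || g$lost > comp$n_SO3) next
    neutral <- formula_mass(composition_formula(
      n_dUA = g$n_dUA, n_UA = g$n_UA, n_hexNAc = g$n_acetyl,
      n_hexN_free = g$n_hexN - g$n_acetyl, n_SO3 = g$n_SO3 - g$lost,
      labeled = g$labeled, n_DBA = g$n_DBA))
    for (z in 1:2) {
      expect_equal(ion_mz(comp, z, n_DBA = g$n_DBA, n_SO3_lost = g$lost),
                   oracle_mz(neutral, z), tolerance = 1e-4)
      checked <- checked + 1
    }
  }
  expect_gt(checked, 100)
})

test_that("the printed diagnostic ion m/z values are reproduced to two decimals", {
  dp2s1 <- glycan_composition(n_UA = 1, n_hexN = 1, n_acetyl = 1, n_SO3 = 1)
  dp2s2 <- glycan_composition(n_UA = 1, n_hexN = 1, n_acetyl = 1, n_SO3 = 2)
  expect_equal(round(ion_mz(dp2s1, 1), 2), 596.14)
  expect_equal(round(ion_mz(dp2s2, 2), 2), 337.54)
  # sulfate loss from the disulfated species is isobaric with the
  # mono-sulfated parent ion
  expect_equal(ion_mz(dp2s2, 1, n_SO3_lost = 1), ion_mz(dp2s1, 1))
  expect_equal(round(fragment_mz("Y1_HexNAcS_2AB"), 2), 420.11)
  expect_equal(round(fragment_mz("B1_UA2S"), 2), 254.98)
  expect_equal(round(fragment_mz("C1_UA"), 2), 193.04)
  expect_equal(round(fragment_mz("B1_UA"), 2), 175.02)
  # the mono-sulfated dp1 NRE precursor is the same ion as the Y1 fragment
  dp1s1 <- glycan_composition(n_hexN = 1, n_acetyl = 1, n_SO3 = 1)
  expect_equal(ion_mz(dp1s1, 1), fragment_mz("Y1_HexNAcS_2AB"), tolerance = 1e-9)
})

test_that("m/z strictly decreases with charge for fixed neutral mass", {
  comp <- glycan_composition(n_UA = 1, n_hexN = 2, n_acetyl = 1, n_SO3 = 3,
                             labeled = TRUE)
  mzs <- vapply(1:4, function(z) ion_mz(comp, z), numeric(1))
  expect_true(all(diff(mzs) < 0))
})

test_that("the NRE/internal mass delta is one water for any substitution state", {
  for (ac in 0:1) for (s in 0:2) for (lab in c(TRUE, FALSE)) {
    nre <- glycan_composition(n_UA = 1, n_hexN = 1, n_acetyl = ac, n_SO3 = s,
                              labeled = lab)
    int <- glycan_composition(n_dUA = 1, n_hexN = 1, n_acetyl = ac, n_SO3 = s,
                              labeled = lab)
    expect_equal(round(nre_internal_mass_delta(nre, int), 4), 18.0106)
  }
  # non-counterpart pair
  nre <- glycan_composition(n_UA = 1, n_hexN = 1, n_acetyl = 1, n_SO3 = 1)
  other <- glycan_composition(n_dUA = 1, n_hexN = 1, n_acetyl = 1, n_SO3 = 2)
  expect_error(nre_internal_mass_delta(nre, other), "counterpart")
  # residue-constant invariant behind the delta
  r <- gag_constants()$residues
  expect_equal(r[["UA"]] - r[["dUA"]], gag_constants()$H2O, tolerance = 1e-6)
})

test_that("invalid compositions and ions are rejected", {
  expect_error(glycan_composition(n_UA = -1, n_hexN = 1), "non-negative")
  expect_error(glycan_composition(n_hexN = 1, n_acetyl = 2), "acetyl")
  expect_error(glycan_composition(n_UA = 1, n_hexN = 1, n_SO3 = 9), "exceeds maximum")
  expect_error(glycan_composition(), "dp")
  comp <- glycan_composition(n_UA = 1, n_hexN = 1, n_acetyl = 1, n_SO3 = 1)
  expect_error(ion_mz(comp, 5), "1..4")
  expect_error(ion_mz(comp, 1, n_SO3_lost = 2), "exceeds composition sulfate")
  expect_error(fragment_mz("Z9_bogus"), "unsupported fragment")
})

test_that("constants export as JSON for audit", {
  path <- withr::local_tempfile(fileext = ".json")
  export_constants_json(path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$SO3, gag_constants()$SO3)
  expect_equal(back$residues[["HexNAc"]], 203.079373)
})
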