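cat38 <- build_ion_catalog(enumerate_compositions())

test_that("feature tables read with validation and row-level error reporting", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,rt_min,mz,charge,intensity,sn",
               "s1,10.0,596.1403,1,1000,50",
               "s1,11.0,337.5449,2,500,30",
               "s1,12.0,420.1082,1,250,20"), path)
  f <- read_feature_table(path)
  expect_equal(nrow(f), 3L)
  expect_equal(f$feature_id, 1:3)

  writeLines(c("sample_id,rt_min,mz,charge,intensity,sn",
               "s1,10.0,596.1403,1,1000,50",
               "s1,11.0,NA,2,500,30"), path)
  expect_error(read_feature_table(path), "row(.*)2")

  writeLines(c("sample_id,rt_min,mz,intensity,sn", "s1,1,2,3,4"), path)
  expect_error(read_feature_table(path), "charge")

  writeLines("sample_id,rt_min,mz,charge,intensity,sn", path)
  expect_warning(f0 <- read_feature_table(path), "empty")
  expect_equal(nrow(f0), 0L)
})

test_that("features match catalog ions within 15 ppm with charge agreement", {
  feats <- tibble::tibble(
    feature_id = 1:4, sample_id = "s1",
    rt_min = c(32.66, 32.66, 37.46, 25.0),
    mz = c(596.1403, 596.1403 * (1 + 20e-6), 337.5449, 800.0),
    charge = c(1L, 1L, 2L, 1L),
    intensity = c(100, 50, 80, 10), sn = 10)
  m <- match_features(feats, cat38, tol_ppm = 15)
  m1 <- m[m$feature_id == 1 & m$preferred, ]
  expect_equal(m1$record_id, "nre-dp2-ac1-s1-2ab")
  expect_equal(m1$role, "parent")
  expect_lt(abs(m1$ppm_error), 0.1)
  expect_false(2 %in% m$feature_id)  # +20 ppm is outside the gate
  m3 <- m[m$feature_id == 3 & m$preferred, ]
  expect_equal(m3$record_id, "nre-dp2-ac1-s2-2ab")
  un <- unassigned_features(m)
  expect_setequal(un$feature_id, c(2L, 4L))
})

test_that("undetermined charge may match any catalog charge state, flagged", {
  feats <- tibble::tibble(feature_id = 1L, sample_id = "s1", rt_min = 37.46,
                          mz = 337.5449, charge = 0L, intensity = 10, sn = 5)
  m <- match_features(feats, cat38)
  expect_true(all(m$charge_undetermined))
  expect_true("nre-dp2-ac1-s2-2ab" %in% m$record_id[m$z == 2])
})

test_that("matching equals the brute-force all-pairs oracle on random instances", {
  set.seed(101)
  sub <- cat38[sample(nrow(cat38), 40), ]
  sub <- sub[order(sub$mz_theoretical), ]
  for (trial in 1:25) {
    feats <- random_match_instance(30, sub)
    got <- match_features(feats, sub, tol_ppm = 15)
    want <- brute_force_match(feats, sub, tol_ppm = 15)
    got_keys <- sort(paste(got$feature_id, got$record_id, got$z,
                           got$n_DBA, got$n_SO3_lost))
    want_keys <- sort(paste(want[, 1], sub$record_id[want[, 2]],
                            sub$z[want[, 2]], sub$n_DBA[want[, 2]],
                            sub$n_SO3_lost[want[, 2]]))
    expect_identical(got_keys, want_keys)
  }
})

test_that("match sets are tolerance-monotone, order-independent, and conserve intensity", {
  set.seed(202)
  for (trial in 1:50) {
    feats <- random_match_instance(20, cat38)
    m15 <- match_features(feats, cat38, tol_ppm = 15)
    m10 <- match_features(feats, cat38, tol_ppm = 10)
    k15 <- paste(m15$feature_id, m15$record_id, m15$z, m15$n_DBA, m15$n_SO3_lost)
    k10 <- paste(m10$feature_id, m10$record_id, m10$z, m10$n_DBA, m10$n_SO3_lost)
    expect_true(all(k10 %in% k15))
    # order independence
    shuf <- feats[sample(nrow(feats)), ]
    ms <- match_features(shuf, cat38, tol_ppm = 15)
    expect_identical(sort(paste(ms$feature_id, ms$record_id, ms$z,
                                ms$n_DBA, ms$n_SO3_lost)), sort(k15))
    # conservation: aggregated + unassigned = total input
    agg <- aggregate_by_composition(consolidate_coeluting(m15))
    expect_equal(sum(agg$intensity) + sum(unassigned_features(m15)$intensity),
                 sum(feats$intensity))
  }
})

test_that("co-eluting sulfate-loss features are attached to their disulfated parent", {
  # one disulfated NRE eluting at 37.46 min observed as its 2- parent and a
  # co-eluting 1- sulfate-loss feature isobaric with the dp2S1 parent ion
  feats <- tibble::tibble(
    feature_id = 1:3, sample_id = "s1",
    rt_min = c(37.46, 37.47, 32.66),
    mz = c(337.5449, 596.1403, 596.1403),
    charge = c(2L, 1L, 1L),
    intensity = c(900, 100, 400), sn = 10)
  m <- consolidate_coeluting(match_features(feats, cat38), rt_tol = 0.2)
  f2 <- m[m$feature_id == 2 & m$preferred, ]
  expect_equal(f2$record_id, "nre-dp2-ac1-s2-2ab")
  expect_equal(f2$flag, "sulfate_loss_attached")
  # the same ion with no co-eluting parent is the mono-sulfated parent itself
  f3 <- m[m$feature_id == 3 & m$preferred, ]
  expect_equal(f3$record_id, "nre-dp2-ac1-s1-2ab")
  expect_equal(f3$role, "parent")
  agg <- aggregate_by_composition(m)
  s2 <- agg[agg$record_id == "nre-dp2-ac1-s2-2ab", ]
  expect_equal(s2$intensity, 1000)  # parent 900 + attached loss 100
})

test_that("orphan loss candidates without an isobaric parent are flagged loss_only", {
  rec <- enumerate_compositions(list(series = list(
    list(terminus = "NRE", dp = 2, acetyl = c(1, 1), so3 = c(2, 2),
         labeled = TRUE, gag_class = "ambiguous"))))
  cat_s2 <- build_ion_catalog(rec)
  feats <- tibble::tibble(feature_id = 1L, sample_id = "s1", rt_min = 30,
                          mz = 596.1403, charge = 1L, intensity = 50, sn = 5)
  m <- consolidate_coeluting(match_features(feats, cat_s2), rt_tol = 0.2)
  expect_equal(m$flag[m$preferred], "loss_only")
  agg <- aggregate_by_composition(m)
  expect_match(agg$flags, "loss_only")
})

test_that("aggregation sums charge states and counts ambiguous features once", {
  feats <- tibble::tibble(
    feature_id = 1:2, sample_id = "s1", rt_min = c(28.2, 28.21),
    mz = c(ion_mz(glycan_composition(n_dUA = 1, n_hexN = 1, n_acetyl = 1,
                                     n_SO3 = 1), 1),
           ion_mz(glycan_composition(n_dUA = 1, n_hexN = 1, n_acetyl = 1,
                                     n_SO3 = 1), 2)),
    charge = c(1L, 2L), intensity = c(80, 20), sn = 10)
  agg <- aggregate_by_composition(consolidate_coeluting(match_features(feats, cat38)))
  row <- agg[agg$record_id == "int-dp2-ac1-s1-2ab", ]
  expect_equal(row$intensity, 100)
  expect_equal(row$n_features, 2L)
  expect_equal(sum(agg$intensity), 100)  # nothing double-counted
})

test_that("elution clusters are assigned to isomer structures by retention time", {
  mk <- function(rt, fid) tibble::tibble(
    feature_id = fid, sample_id = "s1", rt_min = rt,
    mz = 596.1403, charge = 1L, intensity = 100, sn = 10)
  feats <- rbind(mk(32.15, 1L), mk(32.66, 2L), mk(33.83, 3L), mk(40.0, 4L))
  agg <- aggregate_by_composition(consolidate_coeluting(match_features(feats, cat38)))
  q <- assign_structures(agg)
  q1 <- q[q$record_id == "nre-dp2-ac1-s1-2ab", ]
  expect_setequal(q1$structure[!q1$isomer_unresolved],
                  c("IdoAGalNAc4S", "GlcAGalNAc4S", "GlcAGalNAc6S"))
  expect_true(any(q1$isomer_unresolved))
  expect_match(q1$structure[q1$isomer_unresolved], "unresolved")
})
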