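# Independent elemental-formula mass oracle: sums monoisotopic atomic masses
# (CODATA/IUPAC values entered here independently of the package's residue
# constants) over explicit atom counts.

.atoms <- c(C = 12.0, H = 1.0078250319, N = 14.0030740052,
            O = 15.9949146221, S = 31.97207069)
.electron <- 0.00054857990907

formula_mass <- function(...) {
  counts <- c(...)
  sum(.atoms[names(counts)] * counts)
}

# atom counts of a composition (free saccharide incl. reducing-end water)
composition_formula <- function(n_dUA = 0, n_UA = 0, n_hexNAc = 0,
                                n_hexN_free = 0, n_SO3 = 0, labeled = FALSE,
                                n_DBA = 0) {
  f <- c(C = 0, H = 0, N = 0, O = 0, S = 0)
  addf <- function(f, v, k = 1) { f[names(v)] <- f[names(v)] + k * v; f }
  f <- addf(f, c(C = 6, H = 6, O = 5), n_dUA)       # dUA residue
  f <- addf(f, c(C = 6, H = 8, O = 6), n_UA)        # UA residue
  f <- addf(f, c(C = 8, H = 13, N = 1, O = 5), n_hexNAc)
  f <- addf(f, c(C = 6, H = 11, N = 1, O = 4), n_hexN_free)
  f <- addf(f, c(H = 2, O = 1))                     # reducing-end water
  f <- addf(f, c(S = 1, O = 3), n_SO3)
  if (labeled) f <- addf(f, c(C = 7, H = 8, N = 2)) # 2-AB - H2O + H2
  f <- addf(f, c(C = 8, H = 19, N = 1), n_DBA)
  f
}

oracle_neutral_mass <- function(...) formula_mass(composition_formula(...))

# m/z of an n-fold deprotonated ion from its neutral formula
oracle_mz <- function(neutral, z) {
  (neutral - z * (.atoms[["H"]] - .electron)) / z
}

# brute-force all-pairs ppm matcher used as the matching oracle
brute_force_match <- function(features, catalog, tol_ppm) {
  hits <- list()
  for (i in seq_len(nrow(features))) {
    for (j in seq_len(nrow(catalog))) {
      ppm <- 1e6 * (features$mz[i] - catalog$mz_theoretical[j]) /
        catalog$mz_theoretical[j]
      if (abs(ppm) <= tol_ppm &&
          (features$charge[i] == 0 || features$charge[i] == catalog$z[j])) {
        hits[[length(hits) + 1]] <- c(features$feature_id[i], j)
      }
    }
  }
  if (!length(hits)) return(matrix(integer(0), ncol = 2))
  do.call(rbind, hits)
}

# quant-table builder for quantify/profiler tests
make_quants <- function(..., sample_id = "s1") {
  rows <- list(...)
  structures <- gag_structures()
  out <- lapply(rows, function(r) {
    st <- structures[structures$structure == r[[1]], , drop = FALSE]
    if (nrow(st) == 1) {
      tibble::tibble(sample_id = sample_id, structure = r[[1]],
                     record_id = st$record_id, terminus = st$terminus,
                     labeled = grepl("2ab$", st$record_id),
                     intensity = r[[2]], isomer_unresolved = FALSE)
    } else {
      tibble::tibble(sample_id = sample_id, structure = r[[1]],
                     record_id = r[[3]],
                     terminus = if (grepl("^int-", r[[3]])) "internal" else "NRE",
                     labeled = grepl("2ab", r[[3]]),
                     intensity = r[[2]], isomer_unresolved = TRUE)
    }
  })
  do.call(rbind, out)
}

# random feature/catalog instance generator for matcher property tests
random_match_instance <- function(n_feat, catalog, frac_near = 0.5) {
  n_near <- round(n_feat * frac_near)
  near_idx <- sample(nrow(catalog), n_near, replace = TRUE)
  mz <- c(catalog$mz_theoretical[near_idx] *
            (1 + runif(n_near, -25, 25) * 1e-6),
          runif(n_feat - n_near, 150, 1200))
  z <- sample(0:4, n_feat, replace = TRUE)
  tibble::tibble(feature_id = seq_len(n_feat), sample_id = "t",
                 rt_min = runif(n_feat, 0, 60), mz = mz, charge = z,
                 intensity = rlnorm(n_feat, 10, 1),
                 sn = rlnorm(n_feat, 3, 0.5))
}
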