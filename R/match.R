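#' Read an MS1 feature table
#'
#' Consumes the deconvoluted output of an upstream feature-detection step as
#' CSV or TSV. Required columns: `sample_id`, `rt_min`, `mz`, `charge`
#' (0 = undetermined), `intensity`, `sn`. Rows failing validation are reported
#' by index, never silently dropped.
#'
#' @param path File path.
#' @param dialect `"auto"` (by extension), `"csv"`, or `"tsv"`.
#' @return A tibble of features with a `feature_id` column added.
#' @export
read_feature_table <- function(path, dialect = c("auto", "csv", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("feature table not found: ", path, call. = FALSE)
  if (dialect == "auto")
    dialect <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "tsv" else "csv"
  df <- if (dialect == "tsv") utils::read.delim(path, stringsAsFactors = FALSE)
        else utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("sample_id", "rt_min", "mz", "charge", "intensity", "sn")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("feature table schema error: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (nrow(df) == 0) {
    warning("feature table is empty: ", path)
    return(tibble::tibble(feature_id = integer(), sample_id = character(),
                          rt_min = numeric(), mz = numeric(), charge = integer(),
                          intensity = numeric(), sn = numeric()))
  }
  num_cols <- c("rt_min", "mz", "charge", "intensity", "sn")
  for (cl in num_cols) df[[cl]] <- suppressWarnings(as.numeric(df[[cl]]))
  bad <- which(!stats::complete.cases(df[num_cols]) | df$mz <= 0 | df$intensity < 0)
  if (length(bad))
    stop("feature table row error: invalid value(s) in row(s) ",
         paste(utils::head(bad, 20), collapse = ", "), call. = FALSE)
  tibble::tibble(feature_id = seq_len(nrow(df)),
                 sample_id = as.character(df$sample_id),
                 rt_min = df$rt_min, mz = df$mz, charge = as.integer(df$charge),
                 intensity = df$intensity, sn = df$sn)
}

#' Match MS1 features against the theoretical ion catalog
#'
#' A feature matches an ion species iff its relative mass deviation is within
#' `tol_ppm` and the charge states agree (features with undetermined charge,
#' `charge = 0`, may match any catalog charge and are flagged). When a feature
#' matches several catalog entries all candidates are retained under a shared
#' `ambiguity_group`; the preferred candidate is chosen deterministically by
#' smallest |ppm error|, then fewer DBA adducts, then fewer sulfate losses.
#'
#' @param features Feature tibble from [read_feature_table()] or
#'   [simulate_sample()] (needs `feature_id`, `sample_id`, `rt_min`, `mz`,
#'   `charge`, `intensity`).
#' @param catalog Ion catalog from [build_ion_catalog()].
#' @param tol_ppm Precursor mass-accuracy gate in ppm (default 15).
#' @return A tibble of candidate matches (one row per feature x candidate)
#'   with `ppm_error`, `role` (`parent`, `sulfate_loss` or `adduct`),
#'   `preferred`, `ambiguity_group` and `charge_undetermined`. Unmatched
#'   features are attached as the `"unassigned"` attribute.
#' @export
match_features <- function(features, catalog, tol_ppm = 15) {
  stopifnot(tol_ppm > 0)
  if (!"feature_id" %in% names(features))
    features$feature_id <- seq_len(nrow(features))
  cat_mz <- catalog$mz_theoretical  # catalog is sorted by m/z
  if (is.unsorted(cat_mz)) {
    catalog <- catalog[order(cat_mz), ]
    cat_mz <- catalog$mz_theoretical
  }
  lo <- findInterval(features$mz / (1 + tol_ppm * 1e-6), cat_mz) + 1L
  hi <- findInterval(features$mz / (1 - tol_ppm * 1e-6), cat_mz)
  n_cand <- pmax(hi - lo + 1L, 0L)
  fi <- rep.int(seq_len(nrow(features)), n_cand)      # feature row index
  ci <- unlist(lapply(which(n_cand > 0), function(i) lo[i]:hi[i]),
               use.names = FALSE)                      # catalog row index
  if (length(fi)) {
    ppm <- 1e6 * (features$mz[fi] - cat_mz[ci]) / cat_mz[ci]
    keep <- abs(ppm) <= tol_ppm &                      # guard interval edges
      (features$charge[fi] == 0 | catalog$z[ci] == features$charge[fi])
    fi <- fi[keep]; ci <- ci[keep]; ppm <- ppm[keep]
  } else ppm <- numeric(0)
  if (length(fi)) {
    ord <- order(features$feature_id[fi], abs(ppm),
                 catalog$n_DBA[ci], catalog$n_SO3_lost[ci])
    fi <- fi[ord]; ci <- ci[ord]; ppm <- ppm[ord]
    fid <- features$feature_id[fi]
    multi <- fid %in% fid[duplicated(fid)]
    matches <- tibble::tibble(
      feature_id = fid,
      sample_id = features$sample_id[fi],
      rt_min = features$rt_min[fi], mz = features$mz[fi],
      charge = features$charge[fi], intensity = features$intensity[fi],
      record_id = catalog$record_id[ci], terminus = catalog$terminus[ci],
      dp = catalog$dp[ci], n_SO3 = catalog$n_SO3[ci],
      labeled = catalog$labeled[ci],
      z = catalog$z[ci], n_DBA = catalog$n_DBA[ci],
      n_SO3_lost = catalog$n_SO3_lost[ci],
      mz_theoretical = cat_mz[ci], ppm_error = ppm,
      role = ifelse(catalog$n_SO3_lost[ci] > 0, "sulfate_loss",
                    ifelse(catalog$n_DBA[ci] > 0, "adduct", "parent")),
      preferred = !duplicated(fid),
      ambiguity_group = ifelse(multi, paste0("amb-", fid), NA_character_),
      charge_undetermined = features$charge[fi] == 0
    )
  } else
    matches <- tibble::tibble(feature_id = integer(), sample_id = character(),
                              rt_min = numeric(), mz = numeric(),
                              charge = integer(), intensity = numeric(),
                              record_id = character(), terminus = character(),
                              dp = integer(), n_SO3 = integer(),
                              labeled = logical(), z = integer(),
                              n_DBA = integer(), n_SO3_lost = integer(),
                              mz_theoretical = numeric(), ppm_error = numeric(),
                              role = character(), preferred = logical(),
                              ambiguity_group = character(),
                              charge_undetermined = logical())
  attr(matches, "unassigned") <-
    features[!features$feature_id %in% matches$feature_id, , drop = FALSE]
  matches
}

#' Unmatched features of a match table
#'
#' @param matches Output of [match_features()].
#' @return The tibble of features that matched no catalog ion.
#' @export
unassigned_features <- function(matches) attr(matches, "unassigned")

#' Consolidate co-eluting satellite species with their parents
#'
#' In-source sulfate-loss products and DBA-adduct ions co-elute with the
#' parent species of their composition. A satellite candidate is kept
#' (attached) only when a parent-species match of the same composition exists
#' within `rt_tol` minutes in the same sample. An orphan sulfate-loss
#' candidate that is isobaric with a lower-sulfation parent (e.g. dp2S2 minus
#' one sulfate vs the dp2S1 parent at the same m/z) is resolved in favor of
#' that parent; with no alternative it is flagged `loss_only`/`adduct_only`.
#' This replaces manual inspection of such cases with a deterministic,
#' auditable rule.
#'
#' @param matches Match table from [match_features()].
#' @param rt_tol Co-elution tolerance in minutes (default 0.2).
#' @return The match table with updated `preferred` flags and a `flag` column.
#' @export
consolidate_coeluting <- function(matches, rt_tol = 0.2) {
  if (nrow(matches) == 0) {
    matches$flag <- character(0)
    return(matches)
  }
  m <- matches
  m$flag <- ifelse(m$role == "parent", "parent", NA_character_)
  # parent-species evidence per (sample, composition): preferred parent rows
  is_par <- m$role == "parent"
  par_key <- paste(m$sample_id[is_par], m$record_id[is_par])
  par_rt <- split(m$rt_min[is_par], par_key)
  par_fid <- split(m$feature_id[is_par], par_key)
  supported <- logical(nrow(m))
  for (i in which(!is_par)) {
    k <- paste(m$sample_id[i], m$record_id[i])
    rts <- par_rt[[k]]
    if (is.null(rts)) next
    supported[i] <- any(abs(rts - m$rt_min[i]) <= rt_tol &
                          par_fid[[k]] != m$feature_id[i])
  }
  m$flag[m$role != "parent"] <-
    ifelse(supported[m$role != "parent"],
           ifelse(m$role[m$role != "parent"] == "sulfate_loss",
                  "sulfate_loss_attached", "adduct_attached"),
           ifelse(m$role[m$role != "parent"] == "sulfate_loss",
                  "loss_only", "adduct_only"))
  # re-pick the preferred candidate inside each ambiguity group:
  # a supported satellite interpretation beats an unsupported parent of a
  # different (isobaric) composition; otherwise the parent interpretation wins.
  for (g in unique(m$ambiguity_group[!is.na(m$ambiguity_group)])) {
    idx <- which(m$ambiguity_group %in% g)
    sat <- idx[m$role[idx] != "parent" & supported[idx]]
    par <- idx[m$role[idx] == "parent"]
    pick <- if (length(sat)) sat[1] else if (length(par)) par[1] else idx[1]
    m$preferred[idx] <- FALSE
    m$preferred[pick] <- TRUE
  }
  attr(m, "unassigned") <- attr(matches, "unassigned")
  m
}

#' Aggregate matched intensities per composition and elution cluster
#'
#' Sums the intensities of the preferred matches of each composition over
#' charge states, attached adducts and attached sulfate-loss satellites.
#' Because distinct positional/epimeric isomers of one composition elute at
#' different retention times, features are first grouped into elution clusters
#' (single-linkage, gap > `cluster_gap` starts a new cluster); downstream
#' isomer assignment operates per cluster.
#'
#' @param matches Consolidated match table from [consolidate_coeluting()].
#' @param cluster_gap Retention-time gap starting a new cluster (minutes).
#' @return A tibble with one row per (sample, composition, cluster):
#'   aggregated `intensity`, `rt_apex`, `n_features`, `flags`.
#' @export
aggregate_by_composition <- function(matches, cluster_gap = 0.2) {
  pref <- matches[matches$preferred, , drop = FALSE]
  if (nrow(pref) == 0)
    return(tibble::tibble(sample_id = character(), record_id = character(),
                          terminus = character(), labeled = logical(),
                          cluster = integer(), rt_apex = numeric(),
                          intensity = numeric(), n_features = integer(),
                          flags = character()))
  if (any(pref$intensity < 0)) stop("negative feature intensity", call. = FALSE)
  pref <- pref[order(pref$sample_id, pref$record_id, pref$rt_min), ]
  grp <- paste(pref$sample_id, pref$record_id)
  new_cluster <- c(TRUE, grp[-1] != grp[-length(grp)] |
                     diff(pref$rt_min) > cluster_gap)
  pref$cluster <- stats::ave(as.integer(new_cluster), grp, FUN = cumsum)
  key <- factor(paste(grp, pref$cluster), levels = unique(paste(grp, pref$cluster)))
  first <- !duplicated(key)
  apex <- vapply(split(seq_len(nrow(pref)), key),
                 function(ii) pref$rt_min[ii][which.max(pref$intensity[ii])],
                 numeric(1))
  amb <- tapply(!is.na(pref$ambiguity_group), key, any)
  all_loss <- tapply(pref$flag == "loss_only", key, all)
  all_add <- tapply(pref$flag == "adduct_only", key, all)
  flags <- mapply(function(a, l, d) paste(
    c(if (a) "ambiguous", if (l) "loss_only", if (d) "adduct_only"),
    collapse = ","), amb, all_loss, all_add)
  out <- tibble::tibble(
    sample_id = pref$sample_id[first], record_id = pref$record_id[first],
    terminus = pref$terminus[first], labeled = pref$labeled[first],
    cluster = pref$cluster[first],
    rt_apex = unname(apex),
    intensity = as.numeric(tapply(pref$intensity, key, sum)),
    n_features = as.integer(tabulate(key)),
    flags = unname(flags))
  out <- out[order(out$sample_id, out$record_id, out$cluster), ]
  out
}

#' Assign elution clusters to named isomer structures by retention time
#'
#' Each (composition, cluster) row is assigned to the nearest reference
#' structure of that composition within `rt_window` minutes. Clusters with no
#' reference inside the window keep the composition-level quantity and are
#' flagged `isomer_unresolved` rather than split heuristically.
#'
#' @param quants Output of [aggregate_by_composition()].
#' @param structures Structure reference table, see [gag_structures()].
#' @param rt_window Maximum |rt - rt_ref| for an assignment (minutes).
#' @return `quants` with `structure` and `isomer_unresolved` columns.
#' @export
assign_structures <- function(quants, structures = gag_structures(),
                              rt_window = 0.25) {
  n <- nrow(quants)
  quants$structure <- NA_character_
  quants$isomer_unresolved <- rep(TRUE, n)
  for (i in seq_len(n)) {
    cand <- structures[structures$record_id == quants$record_id[i], , drop = FALSE]
    if (!nrow(cand)) next
    d <- abs(cand$rt_ref - quants$rt_apex[i])
    j <- which.min(d)
    if (d[j] <= rt_window) {
      quants$structure[i] <- cand$structure[j]
      quants$isomer_unresolved[i] <- FALSE
    }
  }
  unres <- is.na(quants$structure)
  quants$structure[unres] <- paste0(quants$record_id[unres], ":unresolved")
  quants
}
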