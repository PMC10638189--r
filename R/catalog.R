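# Residue counts per (terminus, dp): lyase products alternate uronic acid and
# hexosamine. Internal fragments start with the unsaturated dUA left by
# beta-elimination; NRE products are saturated. dp1 NREs are hexosamines,
# dp3 NREs are hexosamine-UA-hexosamine (MPS III type).
.residue_layout <- function(terminus, dp) {
  if (terminus == "internal") {
    if (dp < 2) stop("internal products have dp >= 2", call. = FALSE)
    n_hexN <- floor(dp / 2)
    list(n_dUA = 1L, n_UA = dp - 1L - n_hexN, n_hexN = n_hexN)
  } else {
    switch(as.character(dp),
      "1" = list(n_dUA = 0L, n_UA = 0L, n_hexN = 1L),
      "2" = list(n_dUA = 0L, n_UA = 1L, n_hexN = 1L),
      "3" = list(n_dUA = 0L, n_UA = 1L, n_hexN = 2L),
      stop("NRE products are dp1-dp3", call. = FALSE))
  }
}

#' Default composition enumeration bounds
#'
#' The default search space covers the depolymerization products the assay
#' observes: 2-AB-labeled internal disaccharides (0-3 sulfates, with and
#' without N-acetyl), the unlabeled internal disulfated disaccharide (dp2S2)
#' kept as labeling-efficiency QC, and 2-AB-labeled NRE mono-, di- and
#' trisaccharides. Each series is a block of bounds; [enumerate_compositions()]
#' expands them into records.
#'
#' @return An enumeration config: a list with `name` and `series`, where each
#'   series has `terminus`, `dp`, `acetyl` (min,max), `so3` (min,max),
#'   `labeled`, and `gag_class`.
#' @export
default_enum_config <- function() {
  list(
    name = "default",
    series = list(
      list(terminus = "internal", dp = 2, acetyl = c(0, 1), so3 = c(0, 3),
           labeled = TRUE,  gag_class = "ambiguous"),
      list(terminus = "internal", dp = 2, acetyl = c(1, 1), so3 = c(2, 2),
           labeled = FALSE, gag_class = "ambiguous"),  # dp2S2 QC species
      list(terminus = "NRE", dp = 1, acetyl = c(0, 1), so3 = c(0, 2),
           labeled = TRUE,  gag_class = "ambiguous"),
      list(terminus = "NRE", dp = 2, acetyl = c(0, 1), so3 = c(0, 3),
           labeled = TRUE,  gag_class = "ambiguous"),
      list(terminus = "NRE", dp = 3, acetyl = c(0, 2), so3 = c(0, 4),
           labeled = TRUE,  gag_class = "ambiguous")
    )
  )
}

#' Read an enumeration config from JSON
#'
#' @param path Path to a JSON config with the same shape as
#'   [default_enum_config()].
#' @return An enumeration config list.
#' @export
read_enum_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (is.null(cfg$series) || !length(cfg$series))
    stop("enumeration config has no series", call. = FALSE)
  cfg$series <- lapply(cfg$series, function(s) {
    s$acetyl <- as.numeric(s$acetyl); s$so3 <- as.numeric(s$so3)
    s$labeled <- isTRUE(s$labeled); s
  })
  cfg
}

#' Path to a config file shipped with the package
#'
#' @param file File name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return A file path (or a character vector of file names).
#' @export
gagnre_extdata <- function(file = NULL) {
  if (is.null(file))
    return(dir(system.file("extdata", package = "gagnre")))
  path <- system.file("extdata", file, package = "gagnre")
  if (!nzchar(path)) stop("no such extdata file: ", file, call. = FALSE)
  path
}

#' Enumerate the considered saccharide compositions
#'
#' Expands an enumeration config into a deterministic, sorted table of
#' composition records. Record ids are stable text keys derived from the
#' composition (and the GAG-class hint when a series is class-specific, since
#' CS/DS- and HS-derived products of identical composition are isobaric).
#'
#' @param config An enumeration config, see [default_enum_config()].
#' @return A tibble with one row per record: `record_id`, `terminus`, `dp`,
#'   residue and substituent counts, `labeled`, `gag_class`.
#' @examples
#' nrow(enumerate_compositions(default_enum_config()))
#' @export
enumerate_compositions <- function(config = default_enum_config()) {
  rows <- lapply(config$series, function(s) {
    layout <- .residue_layout(s$terminus, s$dp)
    if (s$acetyl[1] > s$acetyl[2] || s$so3[1] > s$so3[2])
      stop("config error: empty bound range in series", call. = FALSE)
    if (s$acetyl[2] > layout$n_hexN)
      stop(sprintf("config error: acetyl bound %d exceeds hexosamine count %d (dp %d %s)",
                   s$acetyl[2], layout$n_hexN, s$dp, s$terminus), call. = FALSE)
    grid <- expand.grid(n_acetyl = s$acetyl[1]:s$acetyl[2],
                        n_SO3 = s$so3[1]:s$so3[2])
    cls <- if (is.null(s$gag_class)) "ambiguous" else s$gag_class
    tibble::tibble(
      terminus = s$terminus, dp = as.integer(s$dp),
      n_dUA = layout$n_dUA, n_UA = layout$n_UA, n_hexN = layout$n_hexN,
      n_acetyl = as.integer(grid$n_acetyl), n_SO3 = as.integer(grid$n_SO3),
      labeled = s$labeled, gag_class = cls
    )
  })
  rec <- do.call(rbind, rows)
  # validate each composition through the constructor
  for (i in seq_len(nrow(rec))) {
    glycan_composition(rec$n_dUA[i], rec$n_UA[i], rec$n_hexN[i],
                       rec$n_acetyl[i], rec$n_SO3[i], rec$labeled[i],
                       dp_max = max(rec$dp))
  }
  cls_tag <- function(cls) {
    ifelse(cls == "ambiguous", "", paste0("-", tolower(gsub("[^A-Za-z]", "", cls))))
  }
  rec$record_id <- sprintf("%s-dp%d-ac%d-s%d-%s%s",
                           ifelse(rec$terminus == "internal", "int", "nre"),
                           rec$dp, rec$n_acetyl, rec$n_SO3,
                           ifelse(rec$labeled, "2ab", "free"),
                           cls_tag(rec$gag_class))
  if (anyDuplicated(rec$record_id))
    stop("config error: duplicate composition records: ",
         paste(unique(rec$record_id[duplicated(rec$record_id)]), collapse = ", "),
         call. = FALSE)
  ord <- order(rec$terminus == "NRE", rec$dp, rec$n_acetyl, rec$n_SO3,
               !rec$labeled, rec$gag_class)
  rec <- rec[ord, c("record_id", "terminus", "dp", "n_dUA", "n_UA", "n_hexN",
                    "n_acetyl", "n_SO3", "labeled", "gag_class")]
  rownames(rec) <- NULL
  tibble::as_tibble(rec)
}

# Physically feasible charge: one carboxylate per uronic acid plus one site
# per (remaining) sulfate, plus the reducing-end/label site.
.max_charge <- function(n_SO3_remaining, n_UA, n_dUA) {
  pmin(4, n_SO3_remaining + n_UA + n_dUA + 1)
}

#' Expand composition records into the searchable ion catalog
#'
#' Every record is expanded over negative charge states, di-n-butylamine (DBA)
#' adduct counts and in-source sulfate-loss counts. Charge states are capped
#' at the number of ionizable acidic sites remaining after sulfate loss.
#' Entries with `n_DBA = 0` and `n_SO3_lost = 0` are the catalog parents;
#' satellite entries reference their parent record.
#'
#' @param records Composition records from [enumerate_compositions()].
#' @param z_max Maximum charge state considered (1-4).
#' @param max_DBA Maximum number of DBA adducts per ion.
#' @param allow_sulfate_loss Generate sulfate-loss satellite entries.
#' @return A tibble of ion species with `mz_theoretical` and `is_parent`.
#' @export
build_ion_catalog <- function(records, z_max = 4, max_DBA = 1,
                              allow_sulfate_loss = TRUE) {
  if (is.null(records) || nrow(records) == 0)
    stop("records must be a nonempty composition table", call. = FALSE)
  stopifnot(z_max >= 1, z_max <= 4, max_DBA >= 0)
  per_record <- lapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    losses <- if (allow_sulfate_loss) 0:r$n_SO3 else 0L
    grid <- expand.grid(z = 1:z_max, n_DBA = 0:max_DBA, n_SO3_lost = losses)
    grid <- grid[grid$z <= .max_charge(r$n_SO3 - grid$n_SO3_lost, r$n_UA, r$n_dUA), ,
                 drop = FALSE]
    if (!nrow(grid)) return(NULL)
    neutral <- .neutral_mass_vec(r$n_dUA, r$n_UA, r$n_hexN, r$n_acetyl,
                                 r$n_SO3, r$labeled)
    m <- neutral - grid$n_SO3_lost * .gag_const$SO3 + grid$n_DBA * .gag_const$DBA
    cbind(r[rep(1, nrow(grid)), ], grid,
          mz_theoretical = (m - grid$z * .gag_const$proton) / grid$z)
  })
  cat <- do.call(rbind, per_record)
  cat$is_parent <- cat$n_DBA == 0 & cat$n_SO3_lost == 0
  key <- paste(cat$record_id, cat$z, cat$n_DBA, cat$n_SO3_lost)
  if (anyDuplicated(key)) stop("internal error: duplicate catalog entries", call. = FALSE)
  cat <- cat[order(cat$mz_theoretical), ]
  rownames(cat) <- NULL
  tibble::as_tibble(cat)
}

.catalog_cols <- c("record_id", "terminus", "dp", "n_dUA", "n_UA", "n_hexN",
                   "n_acetyl", "n_SO3", "labeled", "gag_class",
                   "z", "n_DBA", "n_SO3_lost", "mz_theoretical", "is_parent")

#' Write / read an ion catalog as TSV
#'
#' The on-disk format is a plain TSV with one row per ion species; the round
#' trip is lossless. Import validates the schema, rejects duplicate
#' (record, charge, adduct, loss) keys, and recomputes every theoretical m/z
#' from the composition fields as a consistency check.
#'
#' @param catalog An ion catalog from [build_ion_catalog()].
#' @param path TSV file path.
#' @return `export_catalog()` returns `path` invisibly; `import_catalog()`
#'   returns the catalog tibble.
#' @export
export_catalog <- function(catalog, path) {
  df <- as.data.frame(catalog)[, .catalog_cols, drop = FALSE]
  df$mz_theoretical <- sprintf("%.6f", df$mz_theoretical)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname export_catalog
#' @export
import_catalog <- function(path) {
  if (!file.exists(path)) stop("catalog file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(.catalog_cols, names(df))
  if (length(missing))
    stop("catalog parse error: missing columns ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (nrow(df)) {
    key <- paste(df$record_id, df$z, df$n_DBA, df$n_SO3_lost)
    dup <- which(duplicated(key))
    if (length(dup))
      stop(sprintf("catalog parse error: duplicate key at line %d (%s)",
                   dup[1] + 1L, key[dup[1]]), call. = FALSE)
    recomputed <- (.neutral_mass_vec(df$n_dUA, df$n_UA, df$n_hexN, df$n_acetyl,
                                     df$n_SO3, df$labeled) -
                     df$n_SO3_lost * .gag_const$SO3 + df$n_DBA * .gag_const$DBA -
                     df$z * .gag_const$proton) / df$z
    bad <- which(abs(recomputed - df$mz_theoretical) > 1e-4)
    if (length(bad))
      stop(sprintf("catalog parse error: m/z inconsistent with composition at line %d",
                   bad[1] + 1L), call. = FALSE)
  }
  tibble::as_tibble(df[, .catalog_cols, drop = FALSE])
}
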