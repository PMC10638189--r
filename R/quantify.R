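.check_quants <- function(quants) {
  req <- c("sample_id", "structure", "record_id", "terminus", "labeled", "intensity")
  missing <- setdiff(req, names(quants))
  if (length(missing))
    stop("quant table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (any(quants$intensity < 0))
    stop("negative intensity in quant table", call. = FALSE)
  invisible(quants)
}

# sum intensity per structure for a subset
.per_structure <- function(quants) {
  if (!nrow(quants)) return(stats::setNames(numeric(0), character(0)))
  x <- tapply(quants$intensity, quants$structure, sum)[unique(quants$structure)]
  stats::setNames(as.numeric(x), names(x))
}

#' Relative abundance within the internal or NRE class
#'
#' Each structure's intensity divided by the summed intensity of all
#' identified (2-AB-labeled) species of the same class in the same sample,
#' as a percentage. Unlabeled QC species are excluded from the denominators.
#'
#' @param quants Structure-level quant tibble for one sample, see
#'   [assign_structures()].
#' @param class `"internal"` or `"NRE"`.
#' @return A named numeric vector of percentages summing to 100 (empty when
#'   the class is absent).
#' @export
relative_abundance <- function(quants, class = c("internal", "NRE")) {
  class <- match.arg(class)
  .check_quants(quants)
  q <- quants[quants$terminus == class & quants$labeled, , drop = FALSE]
  x <- .per_structure(q)
  if (!length(x) || sum(x) == 0) return(stats::setNames(numeric(0), character(0)))
  100 * x / sum(x)
}

#' NRE to internal-disaccharide (dp2S1) ratios
#'
#' Each NRE structure's intensity divided by the combined intensity of the
#' two major internal disaccharides (dUAGalNAc4S + dUAGalNAc6S), as a
#' percentage. This normalization uses the internal disaccharides as
#' internal references, which vary far less between samples than the NREs
#' themselves. Undefined (zero reference) propagates as `NA` with a reason
#' attribute, never as 0 or infinity.
#'
#' @param quants Structure-level quant tibble for one sample.
#' @param reference_structures Internal reference structures to combine.
#' @return A named vector of percentages over NRE structures (all `NA` with
#'   `attr(, "reason")` when the reference intensity is zero).
#' @export
nre_to_dp2s1_ratio <- function(quants,
                               reference_structures = .dp2s1_reference_structures) {
  .check_quants(quants)
  ref <- sum(quants$intensity[quants$structure %in% reference_structures])
  nre <- .per_structure(quants[quants$terminus == "NRE" & quants$labeled, ,
                               drop = FALSE])
  if (ref <= 0) {
    out <- stats::setNames(rep(NA_real_, length(nre)), names(nre))
    attr(out, "reason") <- "reference internal disaccharides not detected"
    return(out)
  }
  100 * nre / ref
}

#' GalNAc6S / GalNAc4S intensity ratio
#'
#' Ratio of the two mono-sulfated dp1 NRE positional isomers, elevated in
#' MPS IVa relative to controls. Undefined when GalNAc4S is not detected
#' (`NA` with a reason), as for naive MPS VI samples where GalNAc6S itself
#' is absent.
#'
#' @param quants Structure-level quant tibble for one sample.
#' @return A single ratio, or `NA` with `attr(, "reason")`.
#' @export
galnac6s_4s_ratio <- function(quants) {
  .check_quants(quants)
  i6 <- sum(quants$intensity[quants$structure == "GalNAc6S"])
  i4 <- sum(quants$intensity[quants$structure == "GalNAc4S"])
  if (i4 <= 0) {
    out <- NA_real_
    attr(out, "reason") <- "GalNAc4S not detected"
    return(out)
  }
  i6 / i4
}

#' 2-AB labeling yield from the dp2S2 QC species
#'
#' The internal disulfated disaccharide is searched both 2-AB-labeled and
#' unlabeled; the labeled fraction of their combined intensity estimates the
#' derivatization efficiency.
#'
#' @param quants Structure-level quant tibble for one sample.
#' @param labeled_record,unlabeled_record Record ids of the QC pair.
#' @return Percentage (0-100), or `NA` when neither species was detected.
#'   A `qc_fail` attribute is set when the labeled species is absent while
#'   the unlabeled one is present.
#' @export
labeling_yield <- function(quants,
                           labeled_record = "int-dp2-ac1-s2-2ab",
                           unlabeled_record = "int-dp2-ac1-s2-free") {
  .check_quants(quants)
  l <- sum(quants$intensity[quants$record_id == labeled_record])
  u <- sum(quants$intensity[quants$record_id == unlabeled_record])
  if (l + u <= 0) {
    out <- NA_real_
    attr(out, "reason") <- "dp2S2 QC species not detected"
    return(out)
  }
  out <- 100 * l / (l + u)
  if (l == 0) attr(out, "qc_fail") <- TRUE
  out
}

#' Build a per-sample NRE profile
#'
#' Collects the relative-quantification statistics of one sample: relative
#' abundances within the NRE and internal classes, NRE/dp2S1 ratios, the NRE
#' fraction of all identified saccharide intensity, the GalNAc6S/GalNAc4S
#' ratio, and the 2-AB labeling yield.
#'
#' @param quants Structure-level quant tibble for one sample.
#' @param sample_id Sample identifier (defaults to the one in `quants`).
#' @return An object of class `nre_profile`.
#' @export
nre_profile <- function(quants, sample_id = NULL) {
  .check_quants(quants)
  if (is.null(sample_id)) {
    sample_id <- unique(quants$sample_id)
    if (length(sample_id) != 1)
      stop("quants must come from a single sample; got ",
           length(sample_id), call. = FALSE)
  }
  lab <- quants[quants$labeled, , drop = FALSE]
  nre_total <- sum(lab$intensity[lab$terminus == "NRE"])
  int_total <- sum(lab$intensity[lab$terminus == "internal"])
  structure(list(
    sample_id = sample_id,
    nre_rel = relative_abundance(quants, "NRE"),
    internal_rel = relative_abundance(quants, "internal"),
    nre_over_dp2s1 = nre_to_dp2s1_ratio(quants),
    nre_fraction_total = if (nre_total + int_total > 0)
      100 * nre_total / (nre_total + int_total) else NA_real_,
    galnac_ratio = galnac6s_4s_ratio(quants),
    labeling_yield = labeling_yield(quants),
    n_replicates = 1L, sd = NULL
  ), class = "nre_profile")
}

#' @export
print.nre_profile <- function(x, ...) {
  cat(sprintf("<nre_profile> %s (%d replicate%s)\n", x$sample_id,
              x$n_replicates, if (x$n_replicates > 1) "s" else ""))
  cat(sprintf("  NRE fraction of identified saccharides: %.1f%%\n",
              x$nre_fraction_total))
  cat(sprintf("  GalNAc6S/GalNAc4S ratio: %s\n",
              if (is.na(x$galnac_ratio)) paste0("undefined (",
        attr(x$galnac_ratio, "reason"), ")") else sprintf("%.2f", x$galnac_ratio)))
  cat(sprintf("  2-AB labeling yield: %s\n",
              if (is.na(x$labeling_yield)) "undefined"
              else sprintf("%.1f%%", x$labeling_yield)))
  top <- sort(x$nre_rel, decreasing = TRUE)
  top <- utils::head(top, 5)
  cat("  top NREs (% of total NRE):\n")
  for (n in names(top)) cat(sprintf("    %-24s %6.1f\n", n, top[[n]]))
  invisible(x)
}

# mean/SD over replicate vectors after aligning names (missing -> 0)
.summarize_vectors <- function(vecs, warn_label) {
  all_names <- unique(unlist(lapply(vecs, names)))
  if (!length(all_names)) {
    return(list(mean = stats::setNames(numeric(0), character(0)),
                sd = stats::setNames(numeric(0), character(0))))
  }
  mat <- vapply(vecs, function(v) {
    out <- stats::setNames(rep(0, length(all_names)), all_names)
    out[names(v)] <- ifelse(is.na(v), 0, v)
    out
  }, numeric(length(all_names)))
  mat <- matrix(mat, nrow = length(all_names),
                dimnames = list(all_names, NULL))
  if (length(vecs) > 1 &&
      any(vapply(vecs, function(v) length(setdiff(all_names, names(v))) > 0,
                 logical(1))))
    warning(warn_label, ": composition sets differ between replicates; ",
            "missing values treated as 0")
  list(mean = apply(mat, 1, mean),
       sd = if (ncol(mat) > 1) apply(mat, 1, stats::sd)
            else stats::setNames(rep(NA_real_, length(all_names)), all_names))
}

#' Summarize technical replicates into one profile
#'
#' Arithmetic mean and sample SD per quantity across technical replicates
#' (the assay runs triplicates). A composition missing from a replicate is
#' treated as 0 with a warning; with a single replicate the SDs are `NA`.
#' Ratios undefined in all replicates stay undefined; otherwise the mean is
#' taken over the replicates in which they are defined.
#'
#' @param profiles A list of [nre_profile()] objects from one subject.
#' @return An `nre_profile` whose elements are means, with an `sd` list.
#' @export
replicate_summary <- function(profiles) {
  stopifnot(length(profiles) >= 1,
            all(vapply(profiles, inherits, logical(1), "nre_profile")))
  if (length(profiles) == 1) return(profiles[[1]])
  nre <- .summarize_vectors(lapply(profiles, `[[`, "nre_rel"), "nre_rel")
  int <- .summarize_vectors(lapply(profiles, `[[`, "internal_rel"), "internal_rel")
  ratio <- .summarize_vectors(lapply(profiles, `[[`, "nre_over_dp2s1"),
                              "nre_over_dp2s1")
  scalar <- function(field) {
    v <- vapply(profiles, function(p) as.numeric(p[[field]]), numeric(1))
    if (all(is.na(v))) {
      out <- NA_real_
      attr(out, "reason") <- attr(profiles[[1]][[field]], "reason")
      list(mean = out, sd = NA_real_)
    } else list(mean = mean(v, na.rm = TRUE), sd = stats::sd(v[!is.na(v)]))
  }
  frac <- scalar("nre_fraction_total")
  gr <- scalar("galnac_ratio")
  ly <- scalar("labeling_yield")
  structure(list(
    sample_id = paste(unique(vapply(profiles, `[[`, character(1), "sample_id")),
                      collapse = "+"),
    nre_rel = nre$mean, internal_rel = int$mean, nre_over_dp2s1 = ratio$mean,
    nre_fraction_total = frac$mean, galnac_ratio = gr$mean,
    labeling_yield = ly$mean,
    n_replicates = length(profiles),
    sd = list(nre_rel = nre$sd, internal_rel = int$sd,
              nre_over_dp2s1 = ratio$sd, nre_fraction_total = frac$sd,
              galnac_ratio = gr$sd, labeling_yield = ly$sd)
  ), class = "nre_profile")
}
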