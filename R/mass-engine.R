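#' Construct a saccharide composition
#'
#' A composition counts the residues and substituents of one depolymerization
#' product: uronic acids (saturated `UA` or unsaturated `dUA`), hexosamine
#' backbone units, N-acetyl groups, sulfates (N- and O-sulfo combined, since
#' they are isobaric at MS1), and the 2-AB label flag. Internal lyase products
#' carry exactly one dUA at the new non-reducing terminus; saturated
#' non-reducing-end (NRE) products carry none.
#'
#' @param n_dUA,n_UA,n_hexN Residue counts (dUA = unsaturated uronic acid,
#'   UA = saturated uronic acid, hexN = hexosamine backbone units).
#' @param n_acetyl Number of N-acetylated hexosamines (`<= n_hexN`).
#' @param n_SO3 Total sulfate count.
#' @param labeled Logical; `TRUE` if reductively aminated with 2-AB.
#' @param dp_max Maximum degree of polymerization allowed (validation bound).
#' @param max_SO3 Maximum sulfate count allowed (validation bound; default
#'   allows roughly one sulfate per residue plus one N-sulfo per free amine).
#' @return An object of class `gag_composition`: a list with the counts, the
#'   derived `dp`, and `terminus` (`"internal"` or `"NRE"`).
#' @examples
#' glycan_composition(n_UA = 1, n_hexN = 1, n_acetyl = 1, n_SO3 = 1, labeled = TRUE)
#' @export
glycan_composition <- function(n_dUA = 0, n_UA = 0, n_hexN = 0, n_acetyl = 0,
                               n_SO3 = 0, labeled = TRUE, dp_max = 6,
                               max_SO3 = NULL) {
  counts <- c(n_dUA = n_dUA, n_UA = n_UA, n_hexN = n_hexN,
              n_acetyl = n_acetyl, n_SO3 = n_SO3)
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("invalid composition: counts must be non-negative integers", call. = FALSE)
  if (n_dUA > 1)
    stop("invalid composition: at most one unsaturated uronic acid (internal terminus)",
         call. = FALSE)
  if (n_acetyl > n_hexN)
    stop("invalid composition: n_acetyl exceeds hexosamine backbone count", call. = FALSE)
  dp <- n_dUA + n_UA + n_hexN
  if (dp < 1 || dp > dp_max)
    stop(sprintf("invalid composition: dp = %d outside 1..%d", dp, dp_max), call. = FALSE)
  # capacity: up to two O-sulfates per hexosamine plus an N-sulfate on free
  # amines, one O-sulfate per uronic acid
  if (is.null(max_SO3)) max_SO3 <- 3 * n_hexN - n_acetyl + n_UA + n_dUA
  if (n_SO3 > max_SO3)
    stop(sprintf("invalid composition: n_SO3 = %d exceeds maximum %d for dp %d",
                 n_SO3, max_SO3, dp), call. = FALSE)
  structure(
    list(n_dUA = as.integer(n_dUA), n_UA = as.integer(n_UA),
         n_hexN = as.integer(n_hexN), n_acetyl = as.integer(n_acetyl),
         n_SO3 = as.integer(n_SO3), labeled = isTRUE(labeled),
         dp = as.integer(dp),
         terminus = if (n_dUA == 1) "internal" else "NRE"),
    class = "gag_composition"
  )
}

#' @export
print.gag_composition <- function(x, ...) {
  cat(sprintf("<gag_composition> %s dp%d: dUA=%d UA=%d HexN=%d (Ac %d) SO3=%d %s\n",
              x$terminus, x$dp, x$n_dUA, x$n_UA, x$n_hexN, x$n_acetyl, x$n_SO3,
              if (x$labeled) "2-AB" else "unlabeled"))
  invisible(x)
}

#' Stable text id for a composition
#'
#' @param comp A `gag_composition`.
#' @return A character scalar such as `"nre-dp2-ac1-s1-2ab"`.
#' @export
composition_id <- function(comp) {
  stopifnot(inherits(comp, "gag_composition"))
  sprintf("%s-dp%d-ac%d-s%d-%s",
          if (comp$terminus == "internal") "int" else "nre",
          comp$dp, comp$n_acetyl, comp$n_SO3,
          if (comp$labeled) "2ab" else "free")
}

# Vectorized neutral mass over composition columns; used by the catalog
# builder. `labeled` logical.
.neutral_mass_vec <- function(n_dUA, n_UA, n_hexN, n_acetyl, n_SO3, labeled) {
  r <- .gag_const$residues
  hexnac <- n_acetyl
  hexn_free <- n_hexN - n_acetyl
  n_dUA * r[["dUA"]] + n_UA * r[["UA"]] +
    hexnac * r[["HexNAc"]] + hexn_free * r[["HexN"]] +
    .gag_const$H2O + n_SO3 * .gag_const$SO3 +
    ifelse(labeled, .gag_const$AB2, 0)
}

#' Neutral monoisotopic mass of a composition
#'
#' Sum of residue masses plus the reducing-end water, the sulfate increments,
#' and (when labeled) the net 2-AB reductive-amination addition. N-acetylated
#' hexosamines use the HexNAc residue mass, the remainder the free-amine HexN
#' residue mass (GlcNH2 and N-sulfo cores carry no extra mass term beyond the
#' shared SO3 count).
#'
#' @param comp A `gag_composition`.
#' @return Neutral mass in Da.
#' @examples
#' m <- neutral_mass(glycan_composition(n_UA = 1, n_hexN = 1, n_acetyl = 1,
#'                                      n_SO3 = 1, labeled = TRUE))
#' round(m, 4)  # 597.1476
#' @export
neutral_mass <- function(comp) {
  stopifnot(inherits(comp, "gag_composition"))
  unname(.neutral_mass_vec(comp$n_dUA, comp$n_UA, comp$n_hexN,
                           comp$n_acetyl, comp$n_SO3, comp$labeled))
}

#' Theoretical m/z of a negative-mode ion species
#'
#' An ion species is a composition observed at charge `z` (magnitude of the
#' negative charge), optionally carrying di-n-butylamine (DBA) adducts and
#' having lost in-source sulfate groups. The DBA adduct is modeled as the
#' neutral amine retained on the deprotonated ion (\[M + n·DBA − z·H\]^z−).
#'
#' @param comp A `gag_composition`.
#' @param z Charge state magnitude, 1..4.
#' @param n_DBA Number of DBA adducts (>= 0).
#' @param n_SO3_lost Number of sulfates lost in source (`<= n_SO3`).
#' @return Theoretical m/z (Th).
#' @examples
#' dp2s1 <- glycan_composition(n_UA = 1, n_hexN = 1, n_acetyl = 1, n_SO3 = 1)
#' round(ion_mz(dp2s1, z = 1), 4)  # 596.1403
#' @export
ion_mz <- function(comp, z, n_DBA = 0, n_SO3_lost = 0) {
  stopifnot(inherits(comp, "gag_composition"))
  if (!is.numeric(z) || length(z) != 1 || z < 1 || z > 4 || z != round(z))
    stop("charge z must be an integer in 1..4", call. = FALSE)
  if (n_DBA < 0 || n_DBA != round(n_DBA))
    stop("n_DBA must be a non-negative integer", call. = FALSE)
  if (n_SO3_lost < 0 || n_SO3_lost > comp$n_SO3)
    stop(sprintf("invalid ion: n_SO3_lost = %d exceeds composition sulfate count %d",
                 n_SO3_lost, comp$n_SO3), call. = FALSE)
  m <- neutral_mass(comp) - n_SO3_lost * .gag_const$SO3 + n_DBA * .gag_const$DBA
  (m - z * .gag_const$proton) / z
}

#' Diagnostic fragment m/z
#'
#' Singly deprotonated m/z of the negative-mode diagnostic fragments used for
#' isomer assignment: the saturated uronic acid C ion (`C1_UA`, 193.04), its
#' dehydrated B ion (`B1_UA`, 175.02), the sulfated uronic B ion (`B1_UA2S`,
#' 254.98), the 2-AB-retaining reducing-end Y ions of sulfated/unsulfated
#' HexNAc (`Y1_HexNAcS_2AB` 420.11, `Y1_HexNAc_2AB` 340.15), and the free-amine
#' hexosamine C ions (`C1_HexN`, `C1_HexNS`) diagnostic for GlcNH2 termini.
#'
#' @param kind Fragment kind, one of `names(fragment_kinds())`.
#' @return m/z (Th) of the singly charged fragment.
#' @examples
#' round(fragment_mz("C1_UA"), 4)  # 193.0354
#' @export
fragment_mz <- function(kind) {
  if (length(kind) != 1 || !kind %in% names(.gag_fragments))
    stop(sprintf("unsupported fragment kind '%s'", paste(kind, collapse = ",")),
         call. = FALSE)
  unname(.gag_fragments[[kind]])
}

#' @rdname fragment_mz
#' @export
fragment_kinds <- function() .gag_fragments

#' Mass delta between a saturated NRE and its internal counterpart
#'
#' The saturated (UA-terminated) NRE disaccharide is one water heavier than
#' the internal unsaturated (dUA-terminated) disaccharide of identical
#' substitution, which is what distinguishes the two classes at MS1.
#'
#' @param comp_nre NRE composition (`n_dUA = 0`).
#' @param comp_internal Internal counterpart: identical except one UA swapped
#'   for the dUA.
#' @return The neutral-mass difference, 18.0106 Da.
#' @export
nre_internal_mass_delta <- function(comp_nre, comp_internal) {
  stopifnot(inherits(comp_nre, "gag_composition"),
            inherits(comp_internal, "gag_composition"))
  counterparts <- comp_nre$terminus == "NRE" &&
    comp_internal$terminus == "internal" &&
    comp_nre$n_UA == comp_internal$n_UA + 1L &&
    comp_nre$n_hexN == comp_internal$n_hexN &&
    comp_nre$n_acetyl == comp_internal$n_acetyl &&
    comp_nre$n_SO3 == comp_internal$n_SO3 &&
    comp_nre$labeled == comp_internal$labeled
  if (!counterparts)
    stop("compositions are not NRE/internal counterparts (dUA <-> UA swap)",
         call. = FALSE)
  neutral_mass(comp_nre) - neutral_mass(comp_internal)
}
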