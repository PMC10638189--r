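# Monoisotopic mass constants (Da). Residue masses are glycosidically linked
# residues, i.e. the free monosaccharide minus one water.
.gag_const <- list(
  proton = 1.007276,     # mass of H+ removed per negative charge
  H2O    = 18.010565,
  H2     = 2.015650,
  SO3    = 79.956815,    # net sulfation increment (N- and O-sulfo are isobaric)
  DBA    = 129.151750,   # di-n-butylamine C8H19N, retained as neutral adduct
  AB2    = 120.068748,   # 2-aminobenzamide net addition by reductive amination:
                         # C7H8N2O - H2O + H2
  residues = c(
    dUA    = 158.021523, # 4,5-unsaturated uronic acid (internal lyase product)
    UA     = 176.032088, # saturated uronic acid (GlcA/IdoA, isobaric)
    HexNAc = 203.079373,
    HexN   = 161.068808  # hexosamine backbone without N-acetyl (GlcNH2/GlcNS core)
  )
)

# Diagnostic fragment m/z table (singly deprotonated, negative mode).
# B ions are dehydrated residues, C ions retain the glycosidic water,
# Y ions retain the reducing end incl. the 2-AB label.
.gag_fragments <- local({
  r <- .gag_const$residues
  p <- .gag_const$proton
  h2o <- .gag_const$H2O
  so3 <- .gag_const$SO3
  ab <- .gag_const$AB2
  c(
    C1_UA          = r[["UA"]] + h2o - p,
    B1_UA          = r[["UA"]] - p,
    B1_UA2S        = r[["UA"]] + so3 - p,
    Y1_HexNAcS_2AB = r[["HexNAc"]] + h2o + so3 + ab - p,
    Y1_HexNAc_2AB  = r[["HexNAc"]] + h2o + ab - p,
    C1_HexN        = r[["HexN"]] + h2o - p,
    C1_HexNS       = r[["HexN"]] + h2o + so3 - p
  )
})

#' Monoisotopic mass constants used by the mass engine
#'
#' Returns the fixed table of monoisotopic constants: proton, water, sulfate
#' increment (SO3), the di-n-butylamine (DBA) adduct mass, the net mass added
#' by 2-aminobenzamide (2-AB) reductive amination, and the four glycosidically
#' linked residue masses (dUA, UA, HexNAc, HexN).
#'
#' @return A named list of constants in Da; `residues` is a named numeric
#'   vector.
#' @examples
#' gag_constants()$residues[["UA"]] - gag_constants()$residues[["dUA"]] # one water
#' @export
gag_constants <- function() .gag_const

#' Export the mass-constant table as JSON for audit
#'
#' @param path File path to write; created or overwritten.
#' @return `path`, invisibly.
#' @export
export_constants_json <- function(path) {
  x <- .gag_const
  x$residues <- as.list(x$residues)
  x$fragments <- as.list(.gag_fragments)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
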