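#' Reference table of named saccharide structures
#'
#' Isomer-level annotations for the compositions the assay resolves: structure
#' name (field nomenclature; the `dUA` prefix denotes the 4,5-unsaturated
#' uronic acid of internal lyase products), the composition record it belongs
#' to, the uronic epimer (GlcA/IdoA/unknown, isobaric at MS1), the HexNAc
#' O-sulfation position, whether the uronic acid is 2-O-sulfated, whether the
#' non-reducing terminus is a free-amine glucosamine (GlcNH2, the MPS IIIc
#' hallmark), and a reference retention time.
#'
#' Retention times printed for the dp2S1/dp2S2 NRE glycoforms
#' (32.15, 32.66, 33.06, 33.83, 34.86, 37.46 min) anchor the table and fix the
#' elution order IdoAGalNAc4S < GlcAGalNAc4S < GlcAGalNAc6S; the remaining
#' slots are plausible synthetic choices, spaced so that isomers of one
#' composition are chromatographically resolvable. They are configuration, not
#' measurements, and must be re-anchored against standards before use on real
#' chromatograms.
#'
#' @return A tibble with columns `structure`, `record_id`, `terminus`,
#'   `epimer`, `hexnac_pos`, `ua_2s`, `glcnh2`, `rt_ref`.
#' @export
gag_structures <- function() {
  tb <- tibble::tribble(
    ~structure,                ~record_id,            ~epimer,   ~hexnac_pos, ~ua_2s, ~glcnh2, ~rt_ref,
    # internal (dUA-terminated) disaccharides
    "dUAGalNAc",               "int-dp2-ac1-s0-2ab",  "none",    "none",      FALSE,  FALSE,   20.5,
    "dUAGlcNAc",               "int-dp2-ac1-s0-2ab",  "none",    "none",      FALSE,  FALSE,   21.3,
    "dUAGlcNS",                "int-dp2-ac0-s1-2ab",  "none",    "none",      FALSE,  FALSE,   24.0,
    "dUAGalNAc4S",             "int-dp2-ac1-s1-2ab",  "none",    "4S",        FALSE,  FALSE,   28.2,
    "dUAGalNAc6S",             "int-dp2-ac1-s1-2ab",  "none",    "6S",        FALSE,  FALSE,   29.4,
    "dUAGlcNS(6S)",            "int-dp2-ac0-s2-2ab",  "none",    "6S",        FALSE,  FALSE,   30.6,
    "dUA2SGalNAc4S",           "int-dp2-ac1-s2-2ab",  "none",    "4S",        TRUE,   FALSE,   35.0,
    "dUA2SGalNAc4S(unlabeled)","int-dp2-ac1-s2-free", "none",    "4S",        TRUE,   FALSE,   30.9,
    # NRE monosaccharides (dp1)
    "GlcNH2",                  "nre-dp1-ac0-s0-2ab",  "none",    "none",      FALSE,  TRUE,    15.0,
    "GalNAc",                  "nre-dp1-ac1-s0-2ab",  "none",    "none",      FALSE,  FALSE,   18.0,
    "GlcNS",                   "nre-dp1-ac0-s1-2ab",  "none",    "none",      FALSE,  FALSE,   23.0,
    "GalNAc4S",                "nre-dp1-ac1-s1-2ab",  "none",    "4S",        FALSE,  FALSE,   24.6,
    "GalNAc6S",                "nre-dp1-ac1-s1-2ab",  "none",    "6S",        FALSE,  FALSE,   25.8,
    "GlcNS(6S)",               "nre-dp1-ac0-s2-2ab",  "none",    "6S",        FALSE,  FALSE,   27.2,
    # NRE disaccharides (dp2, saturated UA terminus)
    "UAGalNAc",                "nre-dp2-ac1-s0-2ab",  "unknown", "none",      FALSE,  FALSE,   22.2,
    "UAGlcNAc",                "nre-dp2-ac1-s0-2ab",  "unknown", "none",      FALSE,  FALSE,   23.4,
    "IdoAGlcNS",               "nre-dp2-ac0-s1-2ab",  "IdoA",    "none",      FALSE,  FALSE,   29.6,
    "UAGlcNS",                 "nre-dp2-ac0-s1-2ab",  "unknown", "none",      FALSE,  FALSE,   30.4,
    "IdoAGalNAc4S",            "nre-dp2-ac1-s1-2ab",  "IdoA",    "4S",        FALSE,  FALSE,   32.15,
    "GlcAGalNAc4S",            "nre-dp2-ac1-s1-2ab",  "GlcA",    "4S",        FALSE,  FALSE,   32.66,
    "IdoAGalNAc6S",            "nre-dp2-ac1-s1-2ab",  "IdoA",    "6S",        FALSE,  FALSE,   33.06,
    "GlcAGalNAc6S",            "nre-dp2-ac1-s1-2ab",  "GlcA",    "6S",        FALSE,  FALSE,   33.83,
    "IdoA2SGalNAc",            "nre-dp2-ac1-s1-2ab",  "IdoA",    "none",      TRUE,   FALSE,   34.86,
    "IdoAGlcNS(6S)",           "nre-dp2-ac0-s2-2ab",  "IdoA",    "6S",        FALSE,  FALSE,   31.0,
    "UAGlcNS(6S)",             "nre-dp2-ac0-s2-2ab",  "unknown", "6S",        FALSE,  FALSE,   31.8,
    "UA2SGlcNS",               "nre-dp2-ac0-s2-2ab",  "unknown", "none",      TRUE,   FALSE,   32.9,
    "IdoA2SGlcNS",             "nre-dp2-ac0-s2-2ab",  "IdoA",    "none",      TRUE,   FALSE,   33.5,
    "IdoA2SGalNAc4S",          "nre-dp2-ac1-s2-2ab",  "IdoA",    "4S",        TRUE,   FALSE,   37.46,
    "IdoA2SGlcNS(6S)",         "nre-dp2-ac0-s3-2ab",  "IdoA",    "6S",        TRUE,   FALSE,   36.2,
    # NRE trisaccharides (dp3, glucosamine terminus; MPS III type)
    "GlcNH2UAGlcNAc(6S)",      "nre-dp3-ac1-s1-2ab",  "unknown", "none",      FALSE,  TRUE,    26.5,
    "GlcNH2UAGlcNS(6S)",       "nre-dp3-ac0-s2-2ab",  "unknown", "none",      FALSE,  TRUE,    28.8,
    "GlcNH2(6S)UAGlcNS(6S)",   "nre-dp3-ac0-s3-2ab",  "unknown", "none",      FALSE,  TRUE,    30.8
  )
  tb$terminus <- ifelse(grepl("^int-", tb$record_id), "internal", "NRE")
  tb
}

# internal reference structures used for NRE/disaccharide normalization:
# the two major internal disaccharides.
.dp2s1_reference_structures <- c("dUAGalNAc4S", "dUAGalNAc6S")
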