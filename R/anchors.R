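# Reference anchor segments for domain-architecture annotation.
#
# These are fixed synthetic stand-ins for the S8 (catalytic) and I9
# (prodomain) reference segments that a real screen would take from a known
# subtilase such as tobacco phytaspase.  The S8 anchor carries four
# designated "catalytic" positions occupied by the Asp/His/Asn/Ser catalytic
# machinery of subtilases, plus a designated S1-pocket position playing the
# role of the diagnostic residue 331 (His in the reference).  Real reference
# segments can be supplied to the screening functions in their place.

.S8_ANCHOR <- paste0(
  "GYTWPLSGYNMQFTDHCGNQFNGRSDIQECEKAMNTFPNEARKHYSIHYVNAPRDLAEQH",
  "GFQMHTRGEGSARICRMFDVKFEFQEEWGYCWSWNIMATPKFPPEVHDGHLLRLRYYLAR",
  "RPERADPFWCVNIPHLCHMSGKFTAVTIWG")

.I9_ANCHOR <- "YKPCGVRLKESDFHHYSWPCAADKEWAAYLFIDGYIIANKCKRSDFCANMYQHAFFNWCW"

# 1-based positions of the four catalytic residues (D, H, N, S) within the
# S8 anchor, strictly increasing.
.S8_CATALYTIC <- c(15L, 48L, 95L, 140L)

# 1-based position within the S8 anchor that is homologous to the
# diagnostic S1-pocket residue (residue 331 in tobacco phytaspase
# numbering); His in the reference anchor.
.S8_RES331 <- 60L

# Offset of the S8 anchor start downstream of the junction in planted
# proteins: the anchor starts 30 residues after the first mature residue,
# so the S1-pocket analog sits at junction_index + 30 + .S8_RES331 - 1.
.S8_JUNCTION_OFFSET <- 30L

# Conserved N-terminal segment of the mature protease, planted between the
# prime side of the junction window (after P6') and the S8 anchor.  Plant
# subtilases are strongly conserved immediately downstream of the
# prodomain junction; keeping this segment fixed across planted family
# members is what lets reference-anchored junction mapping stay exact.
.MATURE_SPACER <- "AWCQKEGMSNPGLFDITKPHPLHQ"

#' Reference anchor segments
#'
#' `s8_anchor()` and `i9_anchor()` return the synthetic reference segments
#' used by default for S8 catalytic-domain and I9 prodomain detection.
#' `s8_catalytic_positions()` gives the 1-based positions of the four
#' catalytic residues (Asp/His/Asn/Ser) within the S8 anchor and
#' `s8_residue331_position()` the position homologous to the diagnostic
#' S1-pocket residue (residue 331 in tobacco phytaspase numbering).
#'
#' @return A character scalar (anchors) or integer vector (positions).
#' @export
s8_anchor <- function() .S8_ANCHOR

#' @rdname s8_anchor
#' @export
i9_anchor <- function() .I9_ANCHOR

#' @rdname s8_anchor
#' @export
s8_catalytic_positions <- function() .S8_CATALYTIC

#' @rdname s8_anchor
#' @export
s8_residue331_position <- function() .S8_RES331
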