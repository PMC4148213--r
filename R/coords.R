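#' ATG-anchored promoter coordinates
#'
#' Positions around a translation start are conventionally numbered with the
#' A of the initiator ATG as +1 and no position 0: the base immediately
#' upstream is -1.  These helpers convert between genomic base-pair positions
#' and that signed offset for a gene read in increasing genomic coordinate
#' (plus strand).
#'
#' `atg_from_offset()` recovers the genomic position of the ATG A from any
#' anchored position: a promoter variant at 70,486,623 bp known to sit at
#' offset -103 implies the ATG A is at 70,486,726 bp.
#'
#' @param anchor_pos Genomic position (bp) of a base with known offset.
#' @param anchor_offset Its signed ATG-relative offset (never 0).
#' @return Genomic position of the ATG A (+1 base).
#' @examples
#' atg <- atg_from_offset(70486623, -103)
#' offset_from_atg(70486636, atg)  # -90, a transcription start site
#' @export
atg_from_offset <- function(anchor_pos, anchor_offset) {
  if (anchor_offset == 0) stop("offset 0 does not exist in ATG numbering")
  if (anchor_offset < 0) anchor_pos - anchor_offset
  else anchor_pos - anchor_offset + 1
}

#' @rdname atg_from_offset
#' @param pos Genomic position (bp) to convert.
#' @param atg_pos Genomic position of the ATG A.
#' @return Signed offset of `pos` relative to the ATG (+1 = the A itself).
#' @export
offset_from_atg <- function(pos, atg_pos) {
  ifelse(pos >= atg_pos, pos - atg_pos + 1, pos - atg_pos)
}
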