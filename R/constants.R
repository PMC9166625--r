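#' Default dsODN tag sequence
#'
#' GUIDE-seq marks double-strand breaks by capture of a blunt 34-nt
#' double-stranded oligodeoxynucleotide at the break. Only the tag's length
#' and detectability matter to the pipeline, so the package ships a fixed
#' 34-nt constant; any other 34-nt tag may be supplied wherever a tag is
#' accepted.
#'
#' @return character, 34-nt DNA.
#' @export
dsodnTag <- function() {
  "GTTTAATTGAGTTGTCATATGTTAATAACGGTAT"
}

#' Default AAV ITR sequence
#'
#' A 130-nt stand-in for the AAV2 inverted terminal repeat used to detect
#' AAV vector integration junctions. As for the dsODN, only its length and
#' detectability matter; any ITR sequence may be configured.
#'
#' @return character, 130-nt DNA.
#' @export
itrSequence <- function() {
  paste0(
    "TTGGCCACTCCCTCTCTGCGCGCTCGCTCGCTCACTGAGGCCGGGCGACCAAAGGTCGCCC",
    "GACGCCCGGGCTTTGCCCGGGCGGCCTCAGTGAGCGAGCGAGCGCGCAGAGAGGGAGTGGCCAACTCC")
}
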