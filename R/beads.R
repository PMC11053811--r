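#' Bead type codes
#'
#' Six bead species are supported: hydrophilic `A`, hydrophobic `B`,
#' end-cap `EC` (the terminal labile unit of a hydrophobic block, treated as
#' `B` for all nonbonded interactions), cargo `C`, trigger `T`, and `X`
#' (inert, e.g. a consumed trigger). All beads have unit mass and diameter
#' sigma = 1 in reduced units.
#'
#' @format Named integer vector mapping type tag to the internal integer code.
#' @export
BEAD_TYPES <- c(A = 1L, B = 2L, EC = 3L, C = 4L, T = 5L, X = 6L)

TYPE_TAGS <- names(BEAD_TYPES)
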