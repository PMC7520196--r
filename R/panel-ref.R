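#' Published summary of the seven-locus mountain hare monitoring panel
#'
#' Per-locus population-genetic reference values for the seven biallelic
#' microsatellites used in the alpine mountain hare monitoring this package
#' models (Lsa1, Lsa3, Sat5, Sat8, Sol30, Sol33, Sol8): allele count `A`,
#' individuals typed `N`, observed/expected heterozygosity, probability of
#' identity for unrelated individuals (`P_ID`) and for siblings
#' (`P_IDsib`). These reference values parameterize worked examples and
#' the multilocus identity-probability calculations for the panel; the
#' across-loci identity probabilities follow from [multilocus_pid()].
#'
#' @return data frame with one row per locus.
#' @export
#' @examples
#' multilocus_pid(hare_panel_summary()$P_ID)     # ~8e-4
#' multilocus_pid(hare_panel_summary()$P_IDsib)  # ~0.036
hare_panel_summary <- function() {
  data.frame(
    locus = c("Lsa1", "Lsa3", "Sat5", "Sat8", "Sol30", "Sol33", "Sol8"),
    A = c(3L, 5L, 7L, 2L, 6L, 3L, 5L),
    N = c(96L, 93L, 92L, 96L, 96L, 91L, 95L),
    H_O = c(0.677, 0.140, 0.391, 0.146, 0.396, 0.582, 0.389),
    H_E = c(0.611, 0.371, 0.509, 0.136, 0.426, 0.585, 0.392),
    P_ID = c(0.231, 0.416, 0.274, 0.757, 0.365, 0.264, 0.430),
    P_IDsib = c(0.504, 0.669, 0.565, 0.872, 0.629, 0.525, 0.662),
    stringsAsFactors = FALSE
  )
}
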