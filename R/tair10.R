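#' TAIR10 nuclear chromosome lengths
#'
#' Lengths in bp of the five Arabidopsis thaliana nuclear chromosomes in
#' the TAIR10 assembly (119.15 Mb total), used to turn per-chromosome
#' insertion counts into densities per Mbp.
#'
#' @return Named integer vector (Chr1..Chr5).
#' @export
tair10_chrom_lengths <- function() {
  c(Chr1 = 30427671L, Chr2 = 19698289L, Chr3 = 23459830L,
    Chr4 = 18585056L, Chr5 = 26975502L)
}
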