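#' Study-group overview the simulator defaults emulate
#'
#' The published 17-family multiplex tic-disorder cohort that this package's
#' defaults are modeled on: per-family genome counts (124 total), affected
#' counts (40 full-syndrome + 40 other tic disorder), healthy genotyped
#' relatives (44), and the per-family null co-segregation probabilities
#' reported alongside them (families H and T were analyzed under two
#' segregation patterns; both values are kept).
#'
#' @return data.frame with columns `family_code`, `genomes`, `gts`, `td`,
#'   `healthy`, `p_seg`, `p_seg_alt` (NA when a single pattern was used).
#' @export
study_overview <- function() {
  data.frame(
    family_code = c("A", "B", "C", "D", "E", "F", "G", "H", "I", "J", "R",
                    "S", "T", "U", "W", "X", "Y"),
    genomes = c(7L, 8L, 9L, 7L, 7L, 11L, 4L, 6L, 6L, 5L, 6L, 6L, 9L, 6L,
                14L, 5L, 8L),
    gts = c(3L, 3L, 2L, 2L, 2L, 4L, 1L, 2L, 2L, 1L, 1L, 4L, 2L, 2L, 4L,
            2L, 3L),
    td = c(1L, 2L, 4L, 2L, 2L, 4L, 2L, 3L, 2L, 2L, 3L, 0L, 3L, 2L, 4L,
           1L, 3L),
    healthy = c(3L, 3L, 3L, 3L, 3L, 3L, 1L, 1L, 2L, 2L, 2L, 2L, 4L, 2L,
                6L, 2L, 2L),
    p_seg = c(0.0625, 0.0156, 0.0078, 0.0156, 0.0625, 0.0078, 0.250, 0.125,
              0.0625, 0.250, 0.125, 0.125, 0.125, 0.0625, 0.000976, 0.125,
              0.03125),
    p_seg_alt = c(NA, NA, NA, NA, NA, NA, NA, 0.125, NA, NA, NA, NA, 0.250,
                  NA, NA, NA, NA),
    stringsAsFactors = FALSE)
}
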