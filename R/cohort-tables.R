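#' Published genotype counts for the TG-PCA3 STR
#'
#' Genotype counts of the TG dinucleotide STR in the PCA3 lncRNA, from a
#' Queensland prostate-cancer case-control study (1,156 genotyped cases
#' and 1,213 genotyped controls; the recruited cohort was 1,153 / 1,210).
#' Five alleles of 9-13 TG repeats were observed. These printed counts
#' are the input to the tabulation and association stage.
#'
#' @return Genotype count table: `data.frame` with `group`
#'   (`"case"`/`"control"`), `genotype`, `count`.
#' @seealso [pca3_gleason_counts()] for the case-only aggressiveness
#'   split.
#' @export
pca3_case_control_counts <- function() {
  rbind(
    data.frame(group = "case",
               genotype = c("10/10", "10/11", "10/12", "9/11", "11/11",
                            "11/12", "11/13", "12/12", "12/13"),
               count = c(2L, 2L, 3L, 1L, 680L, 392L, 2L, 73L, 1L)),
    data.frame(group = "control",
               genotype = c("10/10", "10/11", "11/11", "11/12", "12/12",
                            "12/13"),
               count = c(3L, 1L, 634L, 461L, 113L, 1L))
  )
}

#' Published TG-PCA3 genotype counts by Gleason-score group
#'
#' Case-only genotype counts split at Gleason score 8 (`"GS<8"` = less
#' aggressive, `"GS>=8"` = aggressive).
#'
#' @return Genotype count table (`group`, `genotype`, `count`).
#' @export
pca3_gleason_counts <- function() {
  rbind(
    data.frame(group = "GS<8",
               genotype = c("10/10", "10/11", "10/12", "11/11", "11/12",
                            "11/13", "12/12", "12/13"),
               count = c(2L, 2L, 2L, 534L, 309L, 2L, 64L, 1L)),
    data.frame(group = "GS>=8",
               genotype = c("10/12", "9/11", "11/11", "11/12", "12/12"),
               count = c(1L, 1L, 86L, 52L, 5L))
  )
}
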