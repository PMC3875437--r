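#' Default LacI/GalR homolog panel
#'
#' The fourteen mutagenized parent repressors of the LacI/GalR chimera panel
#' (LacI DNA-binding domain fused to each homolog's linker and regulatory
#' domain), with their published repression activities in Miller units and
#' the effector condition in which repression is read out. Inducible
#' repressors are scored in the absence of effector; the co-repressible
#' PurR-based chimeras in its presence. For the two weak repressors TreR and
#' AscG the panel uses the tightened point-mutant parents (LLhT/V52A,
#' LLhA/Q55A), as in the original scans, so that repression changes remain
#' measurable.
#'
#' The `del_control` column is the beta-galactosidase activity with no
#' repressor present ("DEL"), the floor of detectable repression. The
#' published scans print DEL per assay plate rather than one number; here a
#' representative 750 Miller units is used. `growth_threshold` is the
#' repression level (13 Miller units) below which any further change alters
#' growth on lactose minimal medium.
#'
#' @return A tibble with columns `homolog`, `parent_mean`, `parent_sd`,
#'   `del_mean`, `del_sd`, `active_condition`, `growth_threshold`.
#' @export
#' @examples
#' default_homologs()
default_homologs <- function() {
  tibble(
    homolog = c(
      "LacI-11", "LLhR", "LLhF", "LLhG", "LLhG/E62K", "LGhG", "LLhP",
      "LPhP57cs", "LLhS", "LLhS/R51S", "LLhS/D62N", "LLhS/R51S/D62N",
      "LLhT/V52A", "LLhA/Q55A"
    ),
    parent_mean = c(0.12, 0.06, 1.9, 15, 0.7, 13, 3.9,
                    37, 6, 58, 3, 0.06, 0.5, 0.2),
    parent_sd = c(0.06, 0.06, 0.3, 4, 0.2, 11, 2.2,
                  5, 4, 20, 1, 0.03, 0.1, 0.04),
    del_mean = 750,
    del_sd = 60,
    active_condition = c(
      "minus_effector", "minus_effector", "minus_effector", "minus_effector",
      "minus_effector", "minus_effector", "plus_effector", "plus_effector",
      "minus_effector", "minus_effector", "minus_effector", "minus_effector",
      "minus_effector", "minus_effector"
    ),
    growth_threshold = 13
  )
}

#' Published sequence entropies of the LacI/GalR linker
#'
#' Gap-inclusive Shannon entropies (nats, 21-symbol alphabet) of linker
#' positions 45-62, computed from three nested sequence sets: the whole
#' LacI/GalR family alignment, the subset of sequences carrying the YPAL
#' linker motif, and the LacI ortholog subfamily. The `mutated` column marks
#' the twelve nonconserved positions targeted by the mutagenesis scans; the
#' four YPAL motif positions (47, 49, 53, 56) were not mutated.
#'
#' These are the published reference values used to calibrate the two-tier
#' toggle/rheostat separation; [entropy_table()] recomputes such entropies
#' from any alignment.
#'
#' @return A tibble with columns `position` (character label), `all_seqs`,
#'   `ypal_seqs`, `laci_subfamily` (entropies in nats), and `mutated`
#'   (logical).
#' @export
#' @examples
#' linker_entropies()
linker_entropies <- function() {
  mutated <- c("46", "48", "50", "51", "52", "54",
               "55", "58", "59", "60", "61", "62")
  tibble(
    position = as.character(45:62),
    all_seqs = c(1.20, 1.56, 0.24, 2.25, 0.70, 1.20, 2.15, 2.24, 0.91,
                 1.37, 2.21, 0.96, 1.98, 2.37, 2.14, 2.28, 1.68, 2.30),
    ypal_seqs = c(1.01, 1.62, 0.07, 1.99, 0.00, 0.60, 1.92, 1.80, 0.00,
                  0.82, 1.67, 0.00, 1.70, 2.26, 1.66, 2.16, 1.03, 2.18),
    laci_subfamily = c(0.00, 0.86, 0.00, 0.93, 0.00, 0.00, 0.07, 0.93,
                       0.00, 0.00, 0.37, 0.00, 0.36, 0.20, 0.20, 1.28,
                       1.07, 1.47),
    mutated = .data$position %in% mutated
  )
}

#' Published enhancement counts for the linker scan
#'
#' Per-position counts of substitutions that enhanced repression more than
#' 10-fold in the LacI/GalR linker scans, together with the total variant
#' counts (each parent protein counted once per position), the number of
#' parent proteins mutated, and the printed percentage of enhancing
#' substitutions. Used as a reference input for [enhancement_percent()].
#'
#' @return A tibble with columns `position`, `total_variants`,
#'   `enhanced_gt10`, `pct_enhanced`, `parents_mutated`, `parents_enhanced`.
#' @export
#' @examples
#' enhancement_reference_counts()
enhancement_reference_counts <- function() {
  tibble(
    position = c("46", "48", "50", "51", "52", "54",
                 "55", "58", "59", "60", "61", "62"),
    total_variants = c(114L, 102L, 96L, 100L, 113L, 117L,
                       113L, 95L, 101L, 107L, 92L, 126L),
    enhanced_gt10 = c(4L, 1L, 0L, 10L, 7L, 1L, 9L, 5L, 1L, 3L, 2L, 21L),
    pct_enhanced = c(4L, 1L, 0L, 11L, 7L, 1L, 9L, 6L, 1L, 3L, 3L, 19L),
    parents_mutated = c(13L, 14L, 14L, 13L, 14L, 13L,
                        14L, 13L, 14L, 14L, 14L, 13L),
    parents_enhanced = c(2L, 1L, 0L, 5L, 7L, 1L, 5L, 3L, 1L, 3L, 1L, 6L)
  )
}

#' The YPAL linker motif
#'
#' The conserved Tyr47/Pro49/Ala53/Leu56 motif that defines the
#' YPAL subfamily of LacI/GalR linker sequences, as a named character vector
#' mapping reference position labels to required amino acids. Suitable as
#' the `motif` argument of [subset_by_motif()].
#'
#' @return A named character vector (names are position labels).
#' @export
#' @examples
#' ypal_motif()
ypal_motif <- function() {
  c("47" = "Y", "49" = "P", "53" = "A", "56" = "L")
}

#' Physico-chemical amino-acid scales
#'
#' Standard literature scales of the kinds used to screen substitution
#' outcomes: Kyte-Doolittle hydropathy, accessible surface area of the free
#' residue (Miller et al. 1987, in square Angstroms), alpha-helix propensity
#' (Pace & Scholtz 1998, kcal/mol, lower = more helix-favouring), and
#' residue volume (Zamyatnin, cubic Angstroms). Returned in long format as
#' expected by [scale_screen()].
#'
#' @return A tibble with columns `scale_name`, `aa`, `value`.
#' @export
#' @examples
#' dplyr::count(amino_acid_scales(), scale_name)
amino_acid_scales <- function() {
  aa <- amino_acids()
  # values indexed in amino_acids() order: A C D E F G H I K L M N P Q R S T V W Y
  hydropathy <- c(1.8, 2.5, -3.5, -3.5, 2.8, -0.4, -3.2, 4.5, -3.9, 3.8,
                  1.9, -3.5, -1.6, -3.5, -4.5, -0.8, -0.7, 4.2, -0.9, -1.3)
  asa <- c(113, 140, 151, 183, 218, 85, 194, 182, 211, 180,
           204, 158, 143, 189, 241, 122, 146, 160, 259, 229)
  helix <- c(0.00, 0.68, 0.69, 0.40, 0.54, 1.00, 0.61, 0.41, 0.26, 0.21,
             0.24, 0.65, 3.16, 0.39, 0.21, 0.50, 0.66, 0.61, 0.49, 0.53)
  volume <- c(88.6, 108.5, 111.1, 138.4, 189.9, 60.1, 153.2, 166.7, 168.6,
              166.7, 162.9, 114.1, 112.7, 143.8, 173.4, 89.0, 116.1, 140.0,
              227.8, 193.6)
  dplyr::bind_rows(
    tibble(scale_name = "hydropathy_kd", aa = aa, value = hydropathy),
    tibble(scale_name = "asa_free_residue", aa = aa, value = asa),
    tibble(scale_name = "helix_propensity", aa = aa, value = helix),
    tibble(scale_name = "residue_volume", aa = aa, value = volume)
  )
}
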