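#' Starter ferroptosis regulator gene sets
#'
#' The 16 ferroptosis regulator genes (FRGs) printed in the source
#' literature's panel description: 12 positive regulators and the 4 named
#' negative regulators. The full published panel has 24 genes; the negative
#' list is described only as these four "among others", so this collection
#' is a documented starter fixture, not a claimed-complete panel. Analyses
#' of real cohorts should supply their own curated GMT.
#'
#' @return a [gene_set_collection()] with sets `FRG_positive` and
#'   `FRG_negative`.
#' @export
frg_sets <- function() {
  gene_set_collection(
    list(
      FRG_positive = c("LPCAT3", "NCOA4", "ACSL4", "GPX4", "SLC3A2",
                       "ALOX15", "SLC7A11", "NOX5", "NFE2L2", "NOX3",
                       "NOX1", "NOX4"),
      FRG_negative = c("FDFT1", "COQ10A", "HMGCR", "COQ10B")
    ),
    descriptions = c("positive ferroptosis regulators (printed panel)",
                     "negative ferroptosis regulators (partial printed list)")
  )
}

# Bindea-style 24 immune cell types used for marker-based ssGSEA
# infiltration scoring.
immune_cell_types <- function() {
  c("B_cells", "CD8_T_cells", "T_helper_cells", "Th17_cells",
    "NK_CD56bright_cells", "NK_CD56dim_cells", "T_cells", "Th1_cells",
    "Th2_cells", "Tcm", "Tem", "TFH", "Tgd", "Treg", "NK_cells",
    "Cytotoxic_cells", "DC", "aDC", "iDC", "pDC", "Macrophages",
    "Mast_cells", "Neutrophils", "Eosinophils")
}

#' Synthetic immune marker gene sets
#'
#' Marker sets for 24 immune cell types with generated gene identifiers
#' (`<celltype>_M1`, ...). These are synthetic placeholders matching the
#' cell-type panel used for marker-based infiltration scoring; they pair
#' with [generate_cohort()], which plants expression for exactly these
#' genes. They are not curated human marker genes.
#'
#' @param markers_per_type number of marker genes per cell type.
#' @return a [gene_set_collection()] with one set per cell type.
#' @export
synthetic_immune_marker_sets <- function(markers_per_type = 8) {
  types <- immune_cell_types()
  sets <- lapply(types, function(ct)
    paste0(ct, "_M", seq_len(markers_per_type)))
  names(sets) <- types
  gene_set_collection(sets,
    descriptions = rep("synthetic marker set", length(types)))
}

#' WDFY4 clinicopathologic contingency tables
#'
#' The printed 2x2 contingency tables dichotomizing 98 lung adenocarcinoma
#' tissue-microarray cases by WDFY4 immunohistochemistry (high vs low) and
#' by each clinical feature. Rows are the feature levels, columns are
#' WDFY4 high / low counts. The `age` table is included for completeness but
#' its printed p-value is not reproducible by a Pearson chi-square on these
#' counts, and the printed gender percentages are internally inconsistent;
#' neither is used in validation.
#'
#' @return named list of 2x2 integer matrices.
#' @export
wdfy4_table1 <- function() {
  t22 <- function(a, b, c, d, rn) {
    m <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE,
                dimnames = list(rn, c("WDFY4_high", "WDFY4_low")))
    storage.mode(m) <- "integer"
    m
  }
  list(
    tumor_location = t22(9, 47, 1, 41, c("left_pulmonary", "right_pulmonary")),
    tumor_size     = t22(7, 65, 3, 23, c("lt_5cm", "ge_5cm")),
    lymph_node     = t22(5, 47, 5, 41, c("negative", "positive")),
    tnm_stage      = t22(5, 61, 5, 27, c("I_II", "III_IV")),
    path_grade     = t22(3, 66, 2, 27, c("I_II", "III")),
    age            = t22(5, 40, 5, 48, c("lt_60", "ge_60"))
  )
}
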