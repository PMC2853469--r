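#' The 20 standard amino acids (three-letter codes)
#'
#' Fixed alphabet and ordering used to index all count and energy tables.
#' @export
AA_THREE <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"
)

#' One-letter codes for the 20 standard amino acids
#'
#' Named by the corresponding three-letter code, same order as [AA_THREE].
#' @export
AA_ONE <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)

#' Orientation class labels
#'
#' The three discrete relative arrangements of two residues' Ca->Cb vectors:
#' parallel, antiparallel with i facing j, antiparallel with i pointing away
#' from j. Order is fixed; integer codes 1:3 used internally follow it.
#' @export
ORIENT_LABELS <- c("PARALLEL", "ANTIPARALLEL_FACING", "ANTIPARALLEL_AWAY")

N_TYPES <- 20L

aa_index <- function(type_code) {
  idx <- match(type_code, AA_THREE)
  if (anyNA(idx)) {
    stop("unknown residue type: ", paste(unique(type_code[is.na(idx)]), collapse = ", "))
  }
  idx
}
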