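# Scoring tables used by the sequence metrics.
#
# BLOSUM45 is the standard NCBI table restricted to the 20 canonical amino
# acids; it is embedded here (rather than loaded from an external dependency
# at run time) so that distances are reproducible bit-exactly and the table
# can be checksum-pinned by the test suite. Substitution-matrix dialects
# differ in rare entries, so the exact table in use is part of the contract.

BLOSUM45_VALUES <- c(
  #  A   C   D   E   F   G   H   I   K   L   M   N   P   Q   R   S   T   V   W   Y
     5, -1, -2, -1, -2,  0, -2, -1, -1, -1, -1, -1, -1, -1, -2,  1,  0,  0, -2, -2, # A
    -1, 12, -3, -3, -2, -3, -3, -3, -3, -2, -2, -2, -4, -3, -3, -1, -1, -1, -5, -3, # C
    -2, -3,  7,  2, -4, -1,  0, -4,  0, -3, -3,  2, -1,  0, -1,  0, -1, -3, -4, -2, # D
    -1, -3,  2,  6, -3, -2,  0, -3,  1, -2, -2,  0,  0,  2,  0,  0, -1, -3, -3, -2, # E
    -2, -2, -4, -3,  8, -3, -2,  0, -3,  1,  0, -2, -3, -4, -2, -2, -1,  0,  1,  3, # F
     0, -3, -1, -2, -3,  7, -2, -4, -2, -3, -2,  0, -2, -2, -2,  0, -2, -3, -2, -3, # G
    -2, -3,  0,  0, -2, -2, 10, -3, -1, -2,  0,  1, -2,  1,  0, -1, -2, -3, -3,  2, # H
    -1, -3, -4, -3,  0, -4, -3,  5, -3,  2,  2, -2, -2, -2, -3, -2, -1,  3, -2,  0, # I
    -1, -3,  0,  1, -3, -2, -1, -3,  5, -3, -1,  0, -1,  1,  3, -1, -1, -2, -2, -1, # K
    -1, -2, -3, -2,  1, -3, -2,  2, -3,  5,  2, -3, -3, -2, -2, -3, -1,  1, -2,  0, # L
    -1, -2, -3, -2,  0, -2,  0,  2, -1,  2,  6, -2, -2,  0, -1, -2, -1,  1, -2,  0, # M
    -1, -2,  2,  0, -2,  0,  1, -2,  0, -3, -2,  6, -2,  0,  0,  1,  0, -3, -4, -2, # N
    -1, -4, -1,  0, -3, -2, -2, -2, -1, -3, -2, -2,  9, -1, -2, -1, -1, -3, -3, -3, # P
    -1, -3,  0,  2, -4, -2,  1, -2,  1, -2,  0,  0, -1,  6,  1,  0, -1, -3, -2, -1, # Q
    -2, -3, -1,  0, -2, -2,  0, -3,  3, -2, -1,  0, -2,  1,  7, -1, -1, -2, -2, -1, # R
     1, -1,  0,  0, -2,  0, -1, -2, -1, -3, -2,  1, -1,  0, -1,  4,  2, -1, -4, -2, # S
     0, -1, -1, -1, -1, -2, -2, -1, -1, -1, -1,  0, -1, -1, -1,  2,  5,  0, -3, -1, # T
     0, -1, -3, -3,  0, -3, -3,  3, -2,  1,  1, -3, -3, -3, -2, -1,  0,  5, -3, -1, # V
    -2, -5, -4, -3,  1, -2, -3, -2, -2, -2, -2, -4, -3, -2, -2, -4, -3, -3, 15,  3, # W
    -2, -3, -2, -2,  3, -3,  2,  0, -1,  0,  0, -2, -3, -1, -1, -2, -1, -1,  3,  8  # Y
)

#' BLOSUM45 substitution matrix
#'
#' The standard NCBI BLOSUM45 substitution-score table restricted to the 20
#' canonical amino acids, as used by the global-alignment sequence metric.
#'
#' @return A symmetric 20 x 20 integer matrix with amino-acid one-letter
#'   dimnames (alphabetical order) and positive diagonal.
#' @examples
#' blosum45_matrix()["C", "C"]  # 12
#' @export
blosum45_matrix <- function() {
  m <- matrix(as.integer(BLOSUM45_VALUES), nrow = 20, byrow = TRUE,
              dimnames = list(AA_ALPHABET, AA_ALPHABET))
  m
}

# Atchley et al. (2005) solution scores: five orthogonal factors summarising
# ~500 physicochemical amino-acid properties. Factor 1 ~ polarity/hydrophobicity,
# 2 ~ secondary-structure propensity, 3 ~ molecular size, 4 ~ codon composition,
# 5 ~ electrostatic charge. Published values used as-is (no re-standardisation).
ATCHLEY_VALUES <- c(
  # f1      f2      f3      f4      f5
  -0.591, -1.302, -0.733,  1.570, -0.146, # A
  -1.343,  0.465, -0.862, -1.020, -0.255, # C
   1.050,  0.302, -3.656, -0.259, -3.242, # D
   1.357, -1.453,  1.477,  0.113, -0.837, # E
  -1.006, -0.590,  1.891, -0.397,  0.412, # F
  -0.384,  1.652,  1.330,  1.045,  2.064, # G
   0.336, -0.417, -1.673, -1.474, -0.078, # H
  -1.239, -0.547,  2.131,  0.393,  0.816, # I
   1.831, -0.561,  0.533, -0.277,  1.648, # K
  -1.019, -0.987, -1.505,  1.266, -0.912, # L
  -0.663, -1.524,  2.219, -1.005,  1.212, # M
   0.945,  0.828,  1.299, -0.169,  0.933, # N
   0.189,  2.081, -1.628,  0.421, -1.392, # P
   0.931, -0.179, -3.005, -0.503, -1.853, # Q
   1.538, -0.055,  1.502,  0.440,  2.897, # R
  -0.228,  1.399, -4.760,  0.670, -2.647, # S
  -0.032,  0.326,  2.213,  0.908,  1.313, # T
  -1.337, -0.279, -0.544,  1.242, -1.262, # V
  -0.595,  0.009,  0.672, -2.128, -0.184, # W
   0.260,  0.830,  3.097, -0.838,  1.512  # Y
)

#' Atchley-factor table
#'
#' Per-residue five-factor physicochemical summaries for the 20 canonical
#' amino acids, used by the embedding sequence metric.
#'
#' @return A 20 x 5 numeric matrix; rows named by amino acid, columns
#'   `f1`..`f5`.
#' @examples
#' atchley_factors()["A", ]
#' @export
atchley_factors <- function() {
  matrix(ATCHLEY_VALUES, nrow = 20, byrow = TRUE,
         dimnames = list(AA_ALPHABET, paste0("f", 1:5)))
}
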