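# Amino-acid constants shared by the encoders.

AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

NONSTANDARD_LETTERS <- c("B", "J", "O", "U", "X", "Z")

# Seven physicochemical properties per residue, the set conventionally used with
# the auto-covariance descriptor. Column sources:
#   H1   hydrophobicity (Fauchere-Pliska scale, FAUJ830101-style)
#   H2   hydrophilicity (Hopp-Woods, HOPT810101)
#   VSC  volume of side chains (A^3)
#   P1   polarity (Grantham, GRAR740102)
#   P2   polarizability (Charton-Charton, CHAM820101)
#   SASA solvent-accessible surface area (Rose-style, nm^2 x 10)
#   NCI  net charge index of side chains (Klein)
.aa_property_raw <- local({
  m <- rbind(
    #        H1     H2     VSC    P1    P2     SASA   NCI
    A = c( 0.62,  -0.5,   27.5,  8.1, 0.046, 1.181,  0.007187),
    C = c( 0.29,  -1.0,   44.6,  5.5, 0.128, 1.461, -0.036610),
    D = c(-0.90,   3.0,   40.0, 13.0, 0.105, 1.587, -0.023820),
    E = c(-0.74,   3.0,   62.0, 12.3, 0.151, 1.862,  0.006802),
    F = c( 1.19,  -2.5,  115.5,  5.2, 0.290, 2.228,  0.037552),
    G = c( 0.48,   0.0,    0.0,  9.0, 0.000, 0.881,  0.179052),
    H = c(-0.40,  -0.5,   79.0, 10.4, 0.230, 2.025, -0.010690),
    I = c( 1.38,  -1.8,   93.5,  5.2, 0.186, 1.810,  0.021631),
    K = c(-1.50,   3.0,  100.0, 11.3, 0.219, 2.258,  0.017708),
    L = c( 1.06,  -1.8,   93.5,  4.9, 0.186, 1.931,  0.051672),
    M = c( 0.64,  -1.3,   94.1,  5.7, 0.221, 2.034,  0.002683),
    N = c(-0.78,   0.2,   58.7, 11.6, 0.134, 1.655,  0.005392),
    P = c( 0.12,   0.0,   41.9,  8.0, 0.131, 1.468,  0.239531),
    Q = c(-0.85,   0.2,   80.7, 10.5, 0.180, 1.932,  0.049211),
    R = c(-2.53,   3.0,  105.0, 10.5, 0.291, 2.560,  0.043587),
    S = c(-0.18,   0.3,   29.3,  9.2, 0.062, 1.298,  0.004627),
    T = c(-0.05,  -0.4,   51.3,  8.6, 0.108, 1.525,  0.003352),
    V = c( 1.08,  -1.5,   71.5,  5.9, 0.140, 1.645,  0.057004),
    W = c( 0.81,  -3.4,  145.5,  5.4, 0.409, 2.663,  0.037977),
    Y = c( 0.26,  -2.3,  117.3,  6.2, 0.298, 2.368,  0.023599)
  )
  colnames(m) <- c("H1", "H2", "VSC", "P1", "P2", "SASA", "NCI")
  m
})

# Side-chain masses (Da) for the third pseudo-amino-acid-composition property.
.aa_side_chain_mass <- c(
  A = 15, C = 47, D = 59, E = 73, F = 91, G = 1, H = 82, I = 57, K = 73,
  L = 57, M = 75, N = 58, P = 42, Q = 72, R = 101, S = 31, T = 45, V = 43,
  W = 130, Y = 107
)

#' Physicochemical property table for the auto-covariance encoder
#'
#' Seven properties per standard amino acid: hydrophobicity (H1),
#' hydrophilicity (H2), side-chain volume (VSC), polarity (P1), polarizability
#' (P2), solvent-accessible surface area (SASA) and the net charge index of
#' side chains (NCI). When `standardized = TRUE` (the default, and what the
#' encoders use) each property column is centred to mean 0 and scaled to unit
#' variance over the 20 amino acids, which makes the auto-covariance descriptor
#' invariant to the units the raw scales happen to be published in.
#'
#' @param standardized Standardize each property column over the 20 residues?
#' @return A tibble with columns `aa` and the seven property columns.
#' @export
#' @examples
#' aa_property_table()
aa_property_table <- function(standardized = TRUE) {
  m <- .aa_property_raw
  if (standardized) m <- scale_property_columns(m)
  tibble::as_tibble(m, rownames = "aa")
}

#' PseAAC property table (hydrophobicity, hydrophilicity, side-chain mass)
#'
#' The three properties used by the sequence-order correlation terms of the
#' pseudo amino acid composition. Standardized over the 20 residues before use,
#' following the usual PseAAC convention.
#'
#' @inheritParams aa_property_table
#' @return A tibble with columns `aa`, `H1`, `H2`, `mass`.
#' @export
pseaac_property_table <- function(standardized = TRUE) {
  m <- cbind(.aa_property_raw[, c("H1", "H2")],
             mass = .aa_side_chain_mass[rownames(.aa_property_raw)])
  if (standardized) m <- scale_property_columns(m)
  tibble::as_tibble(m, rownames = "aa")
}

# population-style standardization (divide by the variance over exactly the 20
# residues, not the n-1 sample variance), so each column has mean 0, var 1
scale_property_columns <- function(m) {
  mu <- colMeans(m)
  sd20 <- sqrt(colMeans(sweep(m, 2, mu)^2))
  sweep(sweep(m, 2, mu), 2, sd20, "/")
}

# Seven-group partition of the amino-acid alphabet by dipole and side-chain
# volume, shared by the conjoint-triad and local-descriptor encoders.
.aa_group <- c(
  A = 1L, G = 1L, V = 1L,
  C = 2L,
  F = 3L, I = 3L, L = 3L, P = 3L,
  M = 4L, S = 4L, T = 4L, Y = 4L,
  H = 5L, N = 5L, Q = 5L, W = 5L,
  K = 6L, R = 6L,
  D = 7L, E = 7L
)

#' Seven-group amino-acid classification
#'
#' The standard dipole / side-chain-volume partition used by the conjoint-triad
#' and local (composition/transition/distribution) descriptors: group 1 =
#' A,G,V; 2 = C; 3 = F,I,L,P; 4 = M,S,T,Y; 5 = H,N,Q,W; 6 = K,R; 7 = D,E.
#'
#' @return A tibble with columns `aa` and `group`.
#' @export
aa_group_map <- function() {
  g <- .aa_group[AA_LETTERS]
  tibble::tibble(aa = AA_LETTERS, group = unname(g))
}

# Ambiguity-code resolution used under the "impute" policy: map to the group of
# the most common resolution; letters with no sensible group are dropped.
.nonstandard_group <- c(B = 7L, Z = 7L, U = 2L, J = 3L)

# Background residue frequencies (approximately SwissProt composition),
# used by the synthetic proteome generator.
.aa_background_freq <- c(
  A = 0.0826, C = 0.0137, D = 0.0546, E = 0.0674, F = 0.0386,
  G = 0.0708, H = 0.0227, I = 0.0593, K = 0.0582, L = 0.0965,
  M = 0.0241, N = 0.0406, P = 0.0473, Q = 0.0393, R = 0.0553,
  S = 0.0661, T = 0.0535, V = 0.0687, W = 0.0110, Y = 0.0292
)
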