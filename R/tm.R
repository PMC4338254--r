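# Unified nearest-neighbor duplex thermodynamics.
#
# dH in kcal/mol, dS in cal/(mol K), for each 5'->3' dinucleotide stack of
# the primer strand paired with its perfect complement. Initiation terms
# depend on the terminal base pairs. Tm(K) = 1000 dH / (dS + R ln(Ct/4))
# for a non-self-complementary oligo at total strand concentration Ct,
# followed by the monovalent-salt correction +16.6 log10([Na+]).

NN_DH <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4, CT = -7.8,
           GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0,
           TT = -7.9, TG = -8.5, AC = -8.4, AG = -7.8, TC = -8.2, CC = -8.0)
NN_DS <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
           CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
           TT = -22.2, TG = -22.7, AC = -22.4, AG = -21.0, TC = -22.2,
           CC = -19.9)
INIT_DH <- c(G = 0.1, C = 0.1, A = 2.3, T = 2.3)
INIT_DS <- c(G = -2.8, C = -2.8, A = 4.1, T = 4.1)
GAS_CONSTANT <- 1.987  # cal/(mol K)

# dH/dS sums for one primer, optionally against a mismatched template
# context. Stacks containing a mismatched position contribute no stacking
# enthalpy but the duplex still pays their conformational entropy: dropping
# only dH guarantees every additional mismatch strictly lowers Tm (a
# destabilization floor suited to ranking, not to quantitative mismatch
# thermodynamics). Returns c(dH kcal, dS cal/K).
duplex_thermo <- function(sequence, complement_context = NULL) {
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(ch)
  mismatch <- rep(FALSE, n)
  if (!is.null(complement_context)) {
    ctx <- strsplit(complement_context, "", fixed = TRUE)[[1]]
    if (length(ctx) != n) {
      abort("complement_context must have the same length as the primer")
    }
    mismatch <- ch != ctx
  }
  stacks <- paste0(ch[-n], ch[-1])
  keep <- !(mismatch[-n] | mismatch[-1])
  dh <- INIT_DH[[ch[1]]] + INIT_DH[[ch[n]]] + sum(NN_DH[stacks][keep])
  ds <- INIT_DS[[ch[1]]] + INIT_DS[[ch[n]]] + sum(NN_DS[stacks])
  c(dh = dh, ds = ds)
}

#' Nearest-neighbor primer melting temperature
#'
#' Computes the duplex melting temperature of a primer against its perfect
#' complement (or a mismatched template window) from unified nearest-neighbor
#' stacking enthalpies and entropies with duplex-initiation terms:
#' `Tm(K) = 1000 dH / (dS + R ln(Ct/4))`, the `Ct/4` factor being the
#' symmetry term for a non-self-complementary oligo, followed by a
#' monovalent-salt correction of `+16.6 log10([Na+])` degrees.
#'
#' With a `complement_context`, every stack touching a mismatched position
#' loses its stacking enthalpy while the duplex keeps paying the full
#' entropy term — a conservative destabilization floor (rather than full
#' mismatch tables) under which each extra mismatch strictly lowers Tm:
#' useful for ranking allele-specific designs by on- vs off-target Tm, not
#' for quantitative mismatch thermodynamics.
#'
#' @param sequence primer 5'->3', ACGT, length >= 8.
#' @param complement_context optional same-length template window (sense
#'   strand, i.e. what the primer would need to equal for a perfect match);
#'   differing positions are treated as mismatches.
#' @param na_mM monovalent cation concentration in mM (default 50).
#' @param oligo_nM total oligo concentration in nM (default 500).
#' @return melting temperature in degrees Celsius.
#' @export
#' @examples
#' melting_temperature("AGCGTAAGCTTGCATGCCTG")
melting_temperature <- function(sequence, complement_context = NULL,
                                na_mM = 50, oligo_nM = 500) {
  if (nchar(sequence) < 8) abort("primer must be at least 8 bases")
  assert_dna(sequence, "primer")
  th <- duplex_thermo(sequence, complement_context)
  ct <- oligo_nM * 1e-9
  tm_k <- 1000 * th[["dh"]] / (th[["ds"]] + GAS_CONSTANT * log(ct / 4))
  tm_k - 273.15 + 16.6 * log10(na_mM / 1000)
}
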