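# Built-in single-stem nearest-neighbour MFE folding engine. Pre-miRNA
# evaluation only needs hairpin geometry, so the search space is restricted to
# single-hairpin (non-multibranch) structures: one chain of nested pairs
# separated by stacks, bulges and internal loops, closed by a hairpin loop.

#' Nearest-neighbour energy tables of the built-in folder
#'
#' Stack free energies for the 36 combinations of adjacent pairs over
#' `{AT, TA, GC, CG, GT, TG}` (RNA values, T standing for U), hairpin-loop,
#' bulge and internal-loop size penalties with Jacobson-Stockmayer
#' extrapolation beyond the tabulated sizes, and an internal-loop asymmetry
#' penalty. All values in kcal/mol at 37 degrees C.
#'
#' @return a named list consumed by [fold_mfe()] and usable by independent
#'   re-scorers.
#' @export
folding_params <- function() {
  pairs <- c("AT", "TA", "GC", "CG", "GT", "TG")
  stack <- matrix(c(
    # inner:  AT     TA     GC     CG     GT     TG     (outer pair = row)
             -0.9,  -1.1,  -2.1,  -2.2,  -0.6,  -1.4,  # AT
             -1.3,  -0.9,  -2.4,  -2.1,  -1.0,  -1.3,  # TA
             -2.1,  -2.2,  -3.3,  -3.4,  -1.4,  -2.5,  # GC
             -2.1,  -2.4,  -3.3,  -3.3,  -2.1,  -2.1,  # CG
             -1.3,  -1.4,  -2.5,  -2.1,  -0.5,  -0.4,  # GT
             -1.0,  -0.6,  -1.5,  -1.4,  -0.2,  -0.4   # TG
  ), nrow = 6, byrow = TRUE, dimnames = list(pairs, pairs))
  list(
    stack = stack,
    # hairpin loop penalties for sizes 3..30
    hairpin = c(5.4, 5.6, 5.7, 5.4, 6.0, 5.5, 6.4, 6.5, 6.6, 6.7, 6.8, 6.9,
                7.0, 7.1, 7.1, 7.2, 7.3, 7.3, 7.4, 7.4, 7.5, 7.5, 7.6, 7.6,
                7.7, 7.7, 7.8, 7.8),
    # bulge penalties for sizes 1..30
    bulge = c(3.8, 2.8, 3.2, 3.6, 4.0, 4.4, 4.6, 4.7, 4.8, 4.9, 5.0, 5.1,
              5.2, 5.3, 5.4, 5.4, 5.5, 5.5, 5.6, 5.7, 5.7, 5.8, 5.8, 5.8,
              5.9, 5.9, 6.0, 6.0, 6.0, 6.1),
    # internal loop penalties for total sizes 2..30
    internal = c(1.5, 1.8, 2.0, 2.2, 2.5, 2.6, 2.8, 2.9, 3.0, 3.1, 3.2, 3.3,
                 3.4, 3.5, 3.5, 3.6, 3.7, 3.7, 3.8, 3.8, 3.9, 3.9, 4.0, 4.0,
                 4.1, 4.1, 4.2, 4.2, 4.3),
    asym_coef = 0.5,
    asym_max = 3.0,
    js_coef = 1.75 * 0.6163, # 1.75 * RT at 37C
    maxloop = 30L
  )
}

#' Fold a sequence into its minimum-free-energy single-stem structure
#'
#' Dynamic program over all single-hairpin structures under the embedded
#' nearest-neighbour tables ([folding_params()]): stacks, hairpin-loop, bulge
#' and internal-loop penalties (interior loops capped at a total size of 30).
#' Deterministic, with ties broken toward the 5'-most closing pair. If no
#' structure has negative free energy the open chain (all dots, 0 kcal/mol)
#' is returned.
#'
#' @param sequence DNA string, 20-400 nt, no N.
#' @param params energy tables, by default [folding_params()].
#' @return list with `sequence`, `structure` (dot-bracket) and `energy`
#'   (kcal/mol).
#' @export
fold_mfe <- function(sequence, params = folding_params()) {
  n <- nchar(sequence)
  if (n < 20 || n > 400) {
    stop("fold_mfe: sequence length ", n, " outside the supported 20-400 nt")
  }
  if (grepl("[^ACGT]", sequence)) {
    stop("fold_mfe: sequence contains characters outside {A,C,G,T}")
  }
  res <- fold_mfe_cpp(sequence, params)
  list(sequence = sequence, structure = res$structure, energy = res$energy)
}
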