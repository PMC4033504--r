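res_counts <- function(seq) {
  seq <- as_protein_sequence(seq)
  chars <- strsplit(seq$residues, "")[[1]]
  counts <- table(factor(chars, levels = c(AA_ALPHABET, "X")))
  as.integer(counts)[seq_along(c(AA_ALPHABET, "X"))] |>
    stats::setNames(c(AA_ALPHABET, "X"))
}

check_no_x <- function(seq, what) {
  pos <- regexpr("X", seq$residues, fixed = TRUE)
  if (pos > 0L) {
    stop(sprintf("%s is undefined for unknown residue X (position %d)",
                 what, pos), call. = FALSE)
  }
}

check_nonempty <- function(seq) {
  if (seq$length == 0L) stop("empty sequence", call. = FALSE)
}

#' Average molecular weight
#'
#' Sum of average residue masses plus one water, the convention of the
#' ExPASy ProtParam tool.
#'
#' @param seq A [protein_sequence()] or character scalar.
#' @return Molecular weight in Daltons (unrounded; the report layer
#'   prints it to 1 decimal).
#' @export
molecular_weight <- function(seq) {
  seq <- as_protein_sequence(seq)
  check_nonempty(seq)
  check_no_x(seq, "molecular weight")
  cnt <- res_counts(seq)[AA_ALPHABET]
  sum(cnt * AA_RESIDUE_MASS[AA_ALPHABET]) + WATER_MASS
}

#' Net charge at a given pH
#'
#' Henderson-Hasselbalch sum over the ionizable groups, with the
#' Bjellqvist pKa set used by ProtParam: positive contributions from the
#' N-terminal amine (pKa depending on the first residue), His, Lys and
#' Arg as `1/(1 + 10^(pH - pKa))`; negative contributions from the
#' C-terminal carboxyl (pKa adjusted when the last residue is Asp/Glu),
#' Asp, Glu, Cys and Tyr as `1/(1 + 10^(pKa - pH))`.
#'
#' @inheritParams molecular_weight
#' @param pH pH value (may be a vector).
#' @return Net charge in elementary charges; strictly decreasing in pH.
#' @export
net_charge_at_pH <- function(seq, pH) {
  seq <- as_protein_sequence(seq)
  check_nonempty(seq)
  cnt <- res_counts(seq)
  first <- substr(seq$residues, 1, 1)
  last <- substr(seq$residues, seq$length, seq$length)
  nterm_pka <- if (first %in% names(PKA_NTERM)) PKA_NTERM[[first]] else PKA_NTERM_DEFAULT
  cterm_pka <- if (last %in% names(PKA_CTERM)) PKA_CTERM[[last]] else PKA_CTERM_DEFAULT
  pos_pkas <- c(nterm_pka, PKA_POSITIVE)
  pos_n <- c(1, cnt[names(PKA_POSITIVE)])
  neg_pkas <- c(cterm_pka, PKA_NEGATIVE)
  neg_n <- c(1, cnt[names(PKA_NEGATIVE)])
  vapply(pH, function(p) {
    sum(pos_n / (1 + 10^(p - pos_pkas))) - sum(neg_n / (1 + 10^(neg_pkas - p)))
  }, numeric(1))
}

#' Theoretical isoelectric point
#'
#' The pH at which [net_charge_at_pH()] crosses zero, located by
#' bisection on (0, 14). The charge model is strictly decreasing in pH,
#' so the root is unique. Bisection runs to a bracketing interval below
#' `tol` pH units; the charge magnitude at the returned pH is then far
#' below 1e-4 even where the charge curve is nearly flat.
#'
#' @inheritParams molecular_weight
#' @param tol Width of the final bisection bracket, in pH units.
#' @return pI in pH units (unrounded; reported to 2 decimals).
#' @export
isoelectric_point <- function(seq, tol = 1e-8) {
  seq <- as_protein_sequence(seq)
  check_nonempty(seq)
  lo <- 0; hi <- 14
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (net_charge_at_pH(seq, mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Grand average of hydropathicity (GRAVY)
#'
#' Arithmetic mean of the Kyte-Doolittle hydropathy values over all
#' residues; negative values indicate a hydrophilic protein.
#'
#' @inheritParams molecular_weight
#' @return Dimensionless mean hydropathy (reported to 3 decimals).
#' @export
gravy <- function(seq) {
  seq <- as_protein_sequence(seq)
  check_nonempty(seq)
  check_no_x(seq, "GRAVY")
  cnt <- res_counts(seq)[AA_ALPHABET]
  sum(cnt * KYTE_DOOLITTLE[AA_ALPHABET]) / seq$length
}

#' Aliphatic index
#'
#' `X(Ala) + 2.9 X(Val) + 3.9 (X(Ile) + X(Leu))` where `X(r)` is the mole
#' percent of residue `r` — the relative volume occupied by aliphatic
#' side chains, a classical thermostability proxy.
#'
#' @inheritParams molecular_weight
#' @return Dimensionless index (reported to 2 decimals).
#' @export
aliphatic_index <- function(seq) {
  seq <- as_protein_sequence(seq)
  check_nonempty(seq)
  cnt <- res_counts(seq)
  100 * (cnt[["A"]] + ALIPHATIC_A * cnt[["V"]] +
           ALIPHATIC_B * (cnt[["I"]] + cnt[["L"]])) / seq$length
}

#' Guruprasad instability index
#'
#' `(10 / L) * sum(DIWV(x_i, x_{i+1}))` over the `L - 1` overlapping
#' dipeptides; proteins scoring below 40 are conventionally classed
#' "stable". Unlike the other global parameters this statistic depends on
#' residue order.
#'
#' @inheritParams molecular_weight
#' @return Dimensionless index (reported to 2 decimals).
#' @export
instability_index <- function(seq) {
  seq <- as_protein_sequence(seq)
  if (seq$length < 2L) stop("instability index needs length >= 2", call. = FALSE)
  check_no_x(seq, "instability index")
  chars <- strsplit(seq$residues, "")[[1]]
  L <- seq$length
  (10 / L) * sum(DIWV[cbind(chars[-L], chars[-1])])
}

#' Amino-acid composition
#'
#' @inheritParams molecular_weight
#' @return A `data.frame` with one row per residue code present in the
#'   alphabet: `residue`, `count`, `fraction`. Counts sum to the sequence
#'   length.
#' @export
aa_composition <- function(seq) {
  seq <- as_protein_sequence(seq)
  check_nonempty(seq)
  cnt <- res_counts(seq)
  data.frame(residue = names(cnt), count = unname(cnt),
             fraction = unname(cnt) / seq$length)
}

#' Full physicochemical profile
#'
#' Runs every global parameter and formats values at the precision the
#' source tools conventionally print: molecular weight to 1 decimal, pI
#' to 2, GRAVY to 3, aliphatic and instability indices to 2.
#'
#' @inheritParams molecular_weight
#' @return A list with elements `length`, `molecular_weight`,
#'   `theoretical_pI`, `gravy`, `aliphatic_index`, `instability_index`,
#'   `stability_class` ("stable" if the instability index is below 40,
#'   else "unstable") and `composition`.
#' @examples
#' physchem_profile(protein_sequence("AYEPVWAIGTG"))
#' @export
physchem_profile <- function(seq) {
  seq <- as_protein_sequence(seq)
  ii <- round(instability_index(seq), 2)
  list(
    length = seq$length,
    molecular_weight = round(molecular_weight(seq), 1),
    theoretical_pI = round(isoelectric_point(seq), 2),
    gravy = round(gravy(seq), 3),
    aliphatic_index = round(aliphatic_index(seq), 2),
    instability_index = ii,
    stability_class = if (ii < 40) "stable" else "unstable",
    composition = aa_composition(seq)
  )
}
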