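# Tissue partitioning from composition and physicochemistry.
#
# The steady-state tissue:plasma partition coefficient is built from the
# classical composition arguments (Rodgers-Rowland type): only the neutral,
# unbound species crosses membranes, so at equilibrium its aqueous
# concentration is equal everywhere. Each phase then holds, per unit neutral
# aqueous concentration,
#     T(comp, pH) = f_water * (1 + I(pH))
#                 + P * f_neutral_lipid
#                 + (0.3 * P + 0.7) * f_phospholipid
#                 + K_protein * f_protein
#                 + [bases only] KA_ap * f_phospholipid * I(pH)
# where P = 10^logP, I(pH) is the ionised:neutral ratio from the
# Henderson-Hasselbalch relation, and the last term is the electrostatic
# association of the ionised base with acidic membrane phospholipids.
# K_protein (affinity per unit binding-protein fraction) is not a free
# parameter: it is solved from the plasma row so that the measured plasma
# unbound fraction is reproduced exactly,
#     fu_plasma = (1 + I_plasma) / T(plasma comp, pH_plasma).
# The cell:plasma coefficient is then
#     Kp = fu_plasma * T(tissue comp, pH_tissue) / (1 + I_plasma).

ionised_ratio <- function(pKa, type, pH) {
  if (is.null(pKa)) return(0)
  switch(type,
         base = 10^(pKa - pH),
         acid = 10^(pH - pKa),
         neutral = 0,
         stop(sprintf("unknown pKa type '%s'", type)))
}

phase_capacity <- function(comp, P, I_pH, K_protein, ap_term) {
  comp$f_water * (1 + I_pH) +
    P * comp$f_neutral_lipid +
    (0.3 * P + 0.7) * comp$f_phospholipid +
    K_protein * comp$f_protein +
    ap_term * comp$f_phospholipid * I_pH
}

# derive the protein affinity that reproduces fu_plasma for this compound
derive_protein_affinity <- function(compound, plasma_comp, config) {
  pc <- compound$physchem
  fu <- pc$fraction_unbound
  if (!is.numeric(fu) || fu <= 0) abort_field("fraction_unbound", "must be > 0")
  P <- 10^pc$logP
  Ip <- ionised_ratio(pc$pKa$value, pc$pKa$type %||% "neutral",
                      config$pH_plasma)
  nonprotein <- phase_capacity(
    list(f_water = plasma_comp$f_water,
         f_neutral_lipid = plasma_comp$f_neutral_lipid,
         f_phospholipid = plasma_comp$f_phospholipid,
         f_protein = 0),
    P, Ip, 0, 0)
  max(0, ((1 + Ip) / fu - nonprotein) / plasma_comp$f_protein)
}

#' Unbound fraction in the interstitial space
#'
#' The interstitial space holds the same binding proteins as plasma
#' (equal affinity) at a reduced concentration; the unbound fraction
#' follows as `fu / (fu + ratio * (1 - fu))`, which equals `fu` when the
#' protein contents are identical and 1 when the compound is unbound.
#'
#' @param fu_plasma plasma unbound fraction in (0, 1].
#' @param protein_ratio interstitial:plasma binding-protein concentration
#'   ratio (>= 0); 0.37 in the shipped composition table.
#' @return Unbound interstitial fraction.
#' @export
interstitial_unbound_fraction <- function(fu_plasma, protein_ratio) {
  if (any(fu_plasma <= 0) || any(fu_plasma > 1)) {
    abort_field("fu_plasma", "must be in (0, 1]")
  }
  if (any(protein_ratio < 0)) abort_field("protein_ratio", "must be >= 0")
  fu_plasma / (fu_plasma + protein_ratio * (1 - fu_plasma))
}

#' Intracellular-to-plasma partition coefficient
#'
#' Composition-based Kp between the cellular space of a tissue and total
#' plasma (see the block comment in the source and the methods vignette for
#' the equations). Strictly positive; monotonically non-decreasing in logP
#' for a fixed composition; reduces to the tissue water fraction for a
#' neutral, fully unbound compound in a protein- and lipid-free tissue.
#'
#' @param compound a `compound_model` (needs logP, optional pKa, fu).
#' @param tissue one-row data.frame/list with `f_water`, `f_neutral_lipid`,
#'   `f_phospholipid`, `f_protein`.
#' @param plasma one-row plasma composition (default: shipped table).
#' @param pH_tissue tissue-water pH (default: intracellular pH from config).
#' @param config a [pbpk_config()].
#' @return Dimensionless Kp (scalar).
#' @export
cell_to_plasma_kp <- function(compound, tissue,
                              plasma = plasma_composition(),
                              pH_tissue = NULL,
                              config = pbpk_config()) {
  pc <- compound$physchem
  if (is.null(pH_tissue)) pH_tissue <- config$pH_intracellular
  type <- pc$pKa$type %||% "neutral"
  if (!is.null(pc$pKa) && is.null(pc$pKa$value)) {
    abort_field("pKa", "charged-type compound needs a pKa value")
  }
  P <- 10^pc$logP
  Ip <- ionised_ratio(pc$pKa$value, type, config$pH_plasma)
  It <- ionised_ratio(pc$pKa$value, type, pH_tissue)
  Kprot <- derive_protein_affinity(compound, plasma, config)
  ap <- if (identical(type, "base")) config$base_phospholipid_affinity else 0
  Tt <- phase_capacity(tissue, P, It, Kprot, ap)
  kp <- pc$fraction_unbound * Tt / (1 + Ip)
  if (!is.finite(kp) || kp <= 0) stop("computed Kp is not positive")
  kp
}

#' Blood-cell to plasma concentration ratio
#'
#' The same composition machinery applied to the red-cell composition at
#' red-cell pH. The ratio is a property of the compound and the cell
#' composition only; hematocrit enters later, in blood-level aggregation.
#'
#' @inheritParams cell_to_plasma_kp
#' @param rbc one-row red-cell composition (default: shipped table).
#' @return Dimensionless blood-cell:plasma ratio.
#' @export
rbc_to_plasma_ratio <- function(compound, rbc = red_cell_composition(),
                                plasma = plasma_composition(),
                                config = pbpk_config()) {
  cell_to_plasma_kp(compound, rbc, plasma = plasma,
                    pH_tissue = config$pH_rbc, config = config)
}

#' Partition set of a compound across the organs of an individual
#'
#' Computes, for every solid organ of `individual`, the intracellular Kp and
#' the interstitial unbound fraction, plus the blood-cell:plasma ratio.
#'
#' @param compound a `compound_model`.
#' @param individual an `individual_physiology` whose organ table carries
#'   composition columns.
#' @param config a [pbpk_config()].
#' @return List with `kp` (named per organ), `fu_interstitial` (named per
#'   organ), `k_rbc` (scalar) and `fu_plasma`.
#' @export
partition_set <- function(compound, individual, config = pbpk_config()) {
  org <- individual$organs
  solid <- !(org$organ %in% c("venous_blood", "arterial_blood"))
  rows <- which(solid)
  kp <- vapply(rows, function(i) {
    cell_to_plasma_kp(compound, org[i, ], config = config)
  }, numeric(1))
  fu <- compound$physchem$fraction_unbound
  fui <- interstitial_unbound_fraction(fu,
                                       org$interstitial_protein_ratio[rows])
  names(kp) <- names(fui) <- org$organ[rows]
  list(kp = kp, fu_interstitial = fui,
       k_rbc = rbc_to_plasma_ratio(compound, config = config),
       fu_plasma = fu)
}

#' Export a partition set as a tidy table
#' @param pset result of [partition_set()].
#' @param compound_id id column value.
#' @return data.frame (organ, compound, kp, fu_interstitial, k_rbc).
#' @export
partition_table <- function(pset, compound_id) {
  data.frame(organ = names(pset$kp), compound = compound_id,
             kp = unname(pset$kp),
             fu_interstitial = unname(pset$fu_interstitial),
             k_rbc = pset$k_rbc, row.names = NULL,
             stringsAsFactors = FALSE)
}
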