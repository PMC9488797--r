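#' Gas-exchange constants
#'
#' Caloric equivalents for the abbreviated Weir equation (no urinary
#' nitrogen term, the standard choice for metabolic cages) and the
#' reference-air composition used to reconstruct cage outlet fractions
#' from the recorded differentials.
#'
#' @param weir_o2 kcal released per litre O2 consumed (3.941).
#' @param weir_co2 kcal released per litre CO2 produced (1.106).
#' @param ref_o2 O2 volume fraction of reference (inlet) air.
#' @param ref_co2 CO2 volume fraction of reference (inlet) air.
#' @return an object of class `gas_constants`.
#' @export
gas_constants <- function(weir_o2 = 3.941, weir_co2 = 1.106,
                          ref_o2 = 0.2095, ref_co2 = 0.0004) {
  stopifnot(weir_o2 > 0, weir_co2 > 0,
            ref_o2 > 0, ref_o2 < 1, ref_co2 > 0, ref_co2 < 1,
            ref_o2 + ref_co2 < 1)
  structure(list(weir_o2 = weir_o2, weir_co2 = weir_co2,
                 ref_o2 = ref_o2, ref_co2 = ref_co2),
            class = "gas_constants")
}

#' Haldane-transformed gas-exchange volumes
#'
#' In a pull-mode cage the extraction flow `flow_lpm` is the outlet flow;
#' the inlet flow differs because the animal exchanges unequal O2 and CO2
#' volumes. The inlet flow is recovered from conservation of the inert gas
#' (N2 plus argon): `F_in (1 - ref_o2 - ref_co2) = F_out (1 - Fe_O2 -
#' Fe_CO2)`, where the cage outlet fractions are `Fe_O2 = ref_o2 - d_o2`
#' (O2 differential recorded reference-minus-cage, consumption positive)
#' and `Fe_CO2 = ref_co2 + d_co2` (cage-minus-reference, production
#' positive). Then `VO2 = F_in ref_o2 - F_out Fe_O2` and
#' `VCO2 = F_out Fe_CO2 - F_in ref_co2`.
#'
#' @param d_o2 O2 volume-fraction differential, reference minus cage.
#' @param d_co2 CO2 volume-fraction differential, cage minus reference.
#' @param flow_lpm extraction (outlet) flow, L/min.
#' @param constants a [gas_constants()].
#' @return list with numeric vectors `vo2_lpm` and `vco2_lpm` (L/min).
#' @export
#' @examples
#' haldane_volumes(0.0030, 0.0030, 0.4)  # balanced atmosphere: both 0.0012
haldane_volumes <- function(d_o2, d_co2, flow_lpm,
                            constants = gas_constants()) {
  fe_o2 <- constants$ref_o2 - d_o2
  fe_co2 <- constants$ref_co2 + d_co2
  bad <- fe_o2 <= 0 | fe_o2 >= 1 | fe_co2 <= 0 | fe_co2 >= 1 |
    (1 - fe_o2 - fe_co2) <= 0
  if (any(bad, na.rm = TRUE)) {
    stop("invalid atmosphere: implied cage gas fractions outside (0,1)",
         call. = FALSE)
  }
  f_in <- flow_lpm * (1 - fe_o2 - fe_co2) / (1 - constants$ref_o2 - constants$ref_co2)
  list(vo2_lpm = f_in * constants$ref_o2 - flow_lpm * fe_o2,
       vco2_lpm = flow_lpm * fe_co2 - f_in * constants$ref_co2)
}

#' Invert the Haldane transformation
#'
#' Given target exchange volumes, solve for the gas differentials that the
#' sensors would record at the stated extraction flow. This is the
#' generative counterpart of [haldane_volumes()]: simulated traces are
#' produced in raw differential space so the analysis pipeline's forward
#' computation is exercised nontrivially.
#'
#' @param vo2_lpm,vco2_lpm target volumes (L/min).
#' @inheritParams haldane_volumes
#' @return list with `d_o2` and `d_co2` differentials.
#' @export
haldane_invert <- function(vo2_lpm, vco2_lpm, flow_lpm,
                           constants = gas_constants()) {
  s <- 1 - constants$ref_o2 - constants$ref_co2
  a <- constants$ref_o2 / s
  b <- constants$ref_co2 / s
  # linear system in the outlet fractions (Fe_O2, Fe_CO2):
  #   vo2/flow  = a (1 - Fe_O2 - Fe_CO2) - Fe_O2
  #   vco2/flow = Fe_CO2 - b (1 - Fe_O2 - Fe_CO2)
  m <- matrix(c(-(a + 1), -a, b, 1 + b), nrow = 2, byrow = TRUE)
  m_inv <- solve(m)
  r1 <- vo2_lpm / flow_lpm - a
  r2 <- vco2_lpm / flow_lpm + b
  fe_o2 <- m_inv[1, 1] * r1 + m_inv[1, 2] * r2
  fe_co2 <- m_inv[2, 1] * r1 + m_inv[2, 2] * r2
  list(d_o2 = constants$ref_o2 - fe_o2, d_co2 = fe_co2 - constants$ref_co2)
}

#' Respiratory exchange ratio
#'
#' VCO2 / VO2; approximately 1.0 under pure carbohydrate oxidation and 0.7
#' under pure fat oxidation. Undefined (returned as `NA`) when VO2 is not
#' strictly positive.
#'
#' @param vo2_lpm,vco2_lpm exchange volumes (L/min).
#' @return numeric vector.
#' @export
rer <- function(vo2_lpm, vco2_lpm) {
  ifelse(vo2_lpm > 0, vco2_lpm / vo2_lpm, NA_real_)
}

#' Weir energy expenditure
#'
#' Abbreviated Weir equation: `EE = 3.941 VO2 + 1.106 VCO2` (kcal/min for
#' volumes in L/min), omitting the urinary-nitrogen term for which cage
#' systems provide no data.
#'
#' @inheritParams rer
#' @param constants a [gas_constants()].
#' @return kcal/min.
#' @export
weir_ee <- function(vo2_lpm, vco2_lpm, constants = gas_constants()) {
  constants$weir_o2 * vo2_lpm + constants$weir_co2 * vco2_lpm
}

#' Hydrogen production rate
#'
#' Molecular hydrogen is a by-product of microbial fibre fermentation and a
#' direct readout of microbiota metabolic activity; germ-free animals emit
#' none. The rate is the cage-minus-reference concentration differential
#' times the extraction flow.
#'
#' @param d_h2_ppm hydrogen concentration differential (ppm).
#' @param flow_lpm extraction flow (L/min).
#' @return ppm L/min.
#' @export
hydrogen_rate <- function(d_h2_ppm, flow_lpm) {
  d_h2_ppm * flow_lpm
}

#' Add gas-exchange columns to trace records
#'
#' Computes `vo2_lpm`, `vco2_lpm`, `rer`, `ee_kcal_min` and `h2_rate` for
#' every record; operates pointwise, so record order is irrelevant.
#'
#' @param records QC'd trace records.
#' @param constants a [gas_constants()].
#' @return `records` with the exchange columns appended.
#' @export
add_exchange <- function(records, constants = gas_constants()) {
  v <- haldane_volumes(records$d_o2, records$d_co2, records$flow_lpm, constants)
  records$vo2_lpm <- v$vo2_lpm
  records$vco2_lpm <- v$vco2_lpm
  records$rer <- rer(v$vo2_lpm, v$vco2_lpm)
  records$ee_kcal_min <- weir_ee(v$vo2_lpm, v$vco2_lpm, constants)
  records$h2_rate <- hydrogen_rate(records$d_h2, records$flow_lpm)
  records
}
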