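# Curated core network of methylotrophic yeast metabolism: methanol
# oxidation, XuMP assimilation, dissimilation, glycolysis, TCA cycle,
# glyoxylate shunt, cytosolic rTCA, acetone and MVA/isoprene pathways,
# respiration and a lumped biomass. Metabolite formulas follow the charged
# species conventions of the BiGG database so every internal reaction is
# elementally balanced, with explicit protons.

.MET_FORMULA <- c(
  meoh = "CH4O", fald = "CH2O", "for" = "CHO2", co2 = "CO2", o2 = "O2",
  h2o = "H2O", h = "H", h2o2 = "H2O2", pi = "HO4P", ppi = "HO7P2",
  xu5p = "C5H9O8P", dha = "C3H6O3", dhap = "C3H5O6P", gap = "C3H5O6P",
  pyr = "C3H3O3", acald = "C2H4O", ac = "C2H3O2",
  accoa = "C23H34N7O17P3S", coa = "C21H32N7O16P3S", aacoa = "C25H36N7O18P3S",
  acac = "C4H5O3", acetone = "C3H6O", hmgcoa = "C27H39N7O20P3S",
  mev = "C6H11O4", ipdp = "C5H9O7P2", dmpp = "C5H9O7P2", isoprene = "C5H8",
  cit = "C6H5O7", icit = "C6H5O7", glx = "C2HO3", succ = "C4H4O4",
  fum = "C4H2O4", mal = "C4H4O5", oaa = "C4H2O5", akg = "C5H4O5",
  succoa = "C25H35N7O19P3S",
  nad = "C21H26N7O14P2", nadh = "C21H27N7O14P2",
  nadp = "C21H25N7O17P3", nadph = "C21H26N7O17P3",
  fad = "C27H31N9O15P2", fadh2 = "C27H33N9O15P2",
  amp = "C10H12N5O7P", adp = "C10H12N5O10P2", atp = "C10H12N5O13P3")

.MET_NAME <- c(
  meoh = "methanol", fald = "formaldehyde", "for" = "formate",
  co2 = "carbon dioxide", o2 = "oxygen", h2o = "water", h = "proton",
  h2o2 = "hydrogen peroxide", pi = "phosphate", ppi = "diphosphate",
  xu5p = "D-xylulose 5-phosphate", dha = "dihydroxyacetone",
  dhap = "dihydroxyacetone phosphate", gap = "glyceraldehyde 3-phosphate",
  pyr = "pyruvate", acald = "acetaldehyde", ac = "acetate",
  accoa = "acetyl-CoA", coa = "coenzyme A", aacoa = "acetoacetyl-CoA",
  acac = "acetoacetate", acetone = "acetone",
  hmgcoa = "3-hydroxy-3-methylglutaryl-CoA", mev = "(R)-mevalonate",
  ipdp = "isopentenyl diphosphate", dmpp = "dimethylallyl diphosphate",
  isoprene = "isoprene", cit = "citrate", icit = "isocitrate",
  glx = "glyoxylate", succ = "succinate", fum = "fumarate",
  mal = "L-malate", oaa = "oxaloacetate", akg = "2-oxoglutarate",
  succoa = "succinyl-CoA", nad = "NAD+", nadh = "NADH", nadp = "NADP+",
  nadph = "NADPH", fad = "FAD", fadh2 = "FADH2", amp = "AMP",
  adp = "ADP", atp = "ATP")

#' Product targets for methanol bioconversion
#'
#' Metadata for the three platform chemicals the core network can export:
#' exchange reaction id, carbon count, and degree of reduction (electrons
#' per molecule). Methanol carries 6 electrons per molecule, so the
#' carbon-perfect yield ceiling is `1/carbon_count` mol/mol and the electron
#' ceiling is `6/degree_of_reduction`; for all three products the carbon
#' ceiling is the binding one.
#'
#' @param products subset of `c("malate", "acetone", "isoprene")`
#' @return a `data.frame` with columns `name`, `exchange_reaction`,
#'   `carbon_count`, `degree_of_reduction`
#' @examples
#' productTargets()
#' @export
productTargets <- function(products = c("malate", "acetone", "isoprene")) {
  all <- data.frame(
    name = c("malate", "acetone", "isoprene"),
    exchange_reaction = c("EX_mal_e", "EX_acetone_e", "EX_isoprene_e"),
    carbon_count = c(4L, 3L, 5L),
    degree_of_reduction = c(12L, 16L, 28L),
    stringsAsFactors = FALSE)
  products <- match.arg(products, several.ok = TRUE)
  all[all$name %in% products, , drop = FALSE]
}

#' Build the core methylotroph metabolic model
#'
#' Programmatically constructs the core network used throughout the package:
#' peroxisomal methanol oxidase and catalase, XuMP-cycle formaldehyde
#' assimilation (dihydroxyacetone synthase, DHA kinase, a lumped
#' pentose-phosphate rearrangement regenerating Xu5P), the NADH-producing
#' dissimilatory branch (formaldehyde -> formate -> CO2), lumped lower
#' glycolysis, mitochondrial pyruvate dehydrogenase and a full TCA cycle,
#' citrate transport, the glyoxylate shunt, a cytosolic PDH bypass
#' (pyruvate decarboxylase / NADP-aldehyde dehydrogenase / acetyl-CoA
#' synthetase) and ATP-citrate lyase, the cytosolic reductive TCA route to
#' malate with a Mae1-style exporter, the acetone pathway (thiolase,
#' acetoacetyl-CoA hydrolase or CoA-transferase, acetoacetate
#' decarboxylase), the mevalonate pathway to DMAPP with isoprene synthase,
#' respiration at configurable P/O ratios, ATP maintenance, a lumped NADH
#' shuttle and NADPH source, and a lumped biomass reaction drawing GAP,
#' pyruvate, acetyl-CoA, OAA, ATP and NADPH. Every internal reaction is
#' elementally balanced ([validateMassBalance()] returns zero rows); the
#' biomass pseudo-metabolite carries the exact elemental formula of its
#' precursor draw so even the biomass reaction balances.
#'
#' @param products which product pathways (and exchanges) to include
#' @param uptake methanol uptake rate; the methanol exchange lower bound is
#'   set to `-uptake` (mmol/gDW/h, default 10)
#' @param po_nadh,po_fadh2 P/O ratios (mol ATP per 2 electrons) of NADH and
#'   FADH2 respiration (defaults 1.5 and 1.0)
#' @param atp_maintenance non-growth ATP maintenance flux forced through the
#'   ATP hydrolysis reaction (lower bound, mmol/gDW/h, default 0)
#' @param acetone_route `"hydrolase"` (acetoacetyl-CoA hydrolase, YbgC-style,
#'   cofactor-free; default) or `"coa_transferase"` (CtfAB-style, transfers
#'   the CoA to acetate)
#' @param ... unknown options raise a configuration error
#' @return a validated [MetabolicModel-class]; the default objective is
#'   growth (maximize `BIOMASS`)
#' @examples
#' mod <- buildCoreModel()
#' mod
#' @export
buildCoreModel <- function(products = c("malate", "acetone", "isoprene"),
                           uptake = 10, po_nadh = 1.5, po_fadh2 = 1.0,
                           atp_maintenance = 0,
                           acetone_route = c("hydrolase", "coa_transferase"),
                           ...) {
  extra <- list(...)
  if (length(extra)) {
    stop("unknown model option(s): ", paste(names(extra), collapse = ", "),
      call. = FALSE)
  }
  products <- match.arg(products, several.ok = TRUE)
  if (!length(products)) stop("at least one product must be requested", call. = FALSE)
  acetone_route <- match.arg(acetone_route)
  stopifnot(uptake > 0, po_nadh > 0, po_fadh2 > 0, atp_maintenance >= 0)

  rows <- list()
  rx <- function(id, name, eq, lb, ub, sub, stoich = NULL) {
    rows[[length(rows) + 1L]] <<- list(id = id, name = name,
      stoich = if (is.null(stoich)) .parseEquation(eq, id) else stoich,
      lb = lb, ub = ub, sub = sub)
  }

  ## (1) methanol uptake and peroxisomal oxidation
  rx("EX_meoh_e", "methanol exchange", "meoh_e ->", -uptake, 0, "exchange")
  rx("MEOHt", "methanol transport", "meoh_e -> meoh_x", 0, 1000, "methanol oxidation")
  rx("MOX", "methanol oxidase", "meoh_x + o2_x -> fald_x + h2o2_x", 0, 1000, "methanol oxidation")
  rx("CATx", "catalase", "2 h2o2_x -> 2 h2o_x + o2_x", 0, 1000, "methanol oxidation")
  rx("FALDtx", "formaldehyde export from peroxisome", "fald_x -> fald_c", 0, 1000, "methanol oxidation")
  rx("O2tx", "oxygen transport to peroxisome", "o2_c -> o2_x", -1000, 1000, "transport")
  rx("H2Otx", "water transport from peroxisome", "h2o_x -> h2o_c", -1000, 1000, "transport")

  ## (2) XuMP assimilation
  rx("DAS", "dihydroxyacetone synthase", "fald_c + xu5p_c -> dha_c + gap_c", 0, 1000, "XuMP assimilation")
  rx("DHAK", "dihydroxyacetone kinase", "dha_c + atp_c -> dhap_c + adp_c + h_c", 0, 1000, "XuMP assimilation")
  rx("TPI", "triose-phosphate isomerase", "dhap_c -> gap_c", -1000, 1000, "XuMP assimilation")
  rx("XUMPREG", "Xu5P regeneration (lumped PPP rearrangement)",
    "3 dhap_c + 2 gap_c + 2 h2o_c -> 3 xu5p_c + 2 pi_c", 0, 1000, "XuMP assimilation")

  ## (3) dissimilatory branch
  rx("FALDH", "formaldehyde dehydrogenase (lumped, GSH-dependent)",
    "fald_c + nad_c + h2o_c -> for_c + nadh_c + 2 h_c", 0, 1000, "dissimilation")
  rx("FDH", "formate dehydrogenase", "for_c + nad_c -> co2_c + nadh_c", 0, 1000, "dissimilation")

  ## (4) lower glycolysis, lumped GAP -> pyruvate
  rx("GLYCLOW", "lower glycolysis (lumped)",
    "gap_c + 2 adp_c + pi_c + nad_c -> pyr_c + 2 atp_c + nadh_c + h2o_c",
    0, 1000, "glycolysis")

  ## (5) mitochondrial PDH + TCA cycle + citrate transport
  rx("PYRtm", "pyruvate mitochondrial transport", "pyr_c + h_c -> pyr_m + h_m", -1000, 1000, "transport")
  rx("PDHm", "pyruvate dehydrogenase",
    "pyr_m + coa_m + nad_m -> accoa_m + co2_m + nadh_m", 0, 1000, "TCA cycle")
  rx("CSm", "citrate synthase",
    "accoa_m + oaa_m + h2o_m -> cit_m + coa_m + h_m", 0, 1000, "TCA cycle")
  rx("ACONTm", "aconitase (mitochondrial)", "cit_m -> icit_m", -1000, 1000, "TCA cycle")
  rx("IDHm", "isocitrate dehydrogenase (NAD)",
    "icit_m + nad_m -> akg_m + co2_m + nadh_m", 0, 1000, "TCA cycle")
  rx("AKGDm", "2-oxoglutarate dehydrogenase",
    "akg_m + coa_m + nad_m -> succoa_m + co2_m + nadh_m", 0, 1000, "TCA cycle")
  rx("SUCOASm", "succinyl-CoA synthetase",
    "succoa_m + adp_m + pi_m -> succ_m + coa_m + atp_m", -1000, 1000, "TCA cycle")
  rx("SDHm", "succinate dehydrogenase", "succ_m + fad_m -> fum_m + fadh2_m", 0, 1000, "TCA cycle")
  rx("FUMm", "fumarase", "fum_m + h2o_m -> mal_m", -1000, 1000, "TCA cycle")
  rx("MDHm", "malate dehydrogenase (mitochondrial)",
    "mal_m + nad_m -> oaa_m + nadh_m + h_m", -1000, 1000, "TCA cycle")
  rx("CITtc", "citrate transport (mitochondrial/peroxisomal, merged)",
    "cit_m -> cit_c", -1000, 1000, "transport")

  ## (6) glyoxylate shunt
  rx("ACONTc", "aconitase (cytosolic)", "cit_c -> icit_c", -1000, 1000, "glyoxylate shunt")
  rx("ICL", "isocitrate lyase", "icit_c -> succ_c + glx_c", 0, 1000, "glyoxylate shunt")
  rx("MALS", "malate synthase",
    "accoa_c + glx_c + h2o_c -> mal_c + coa_c + h_c", 0, 1000, "glyoxylate shunt")

  ## cytosolic acetyl-CoA supply: PDH bypass and ATP-citrate lyase
  rx("PDC", "pyruvate decarboxylase", "pyr_c + h_c -> acald_c + co2_c", 0, 1000, "PDH bypass")
  rx("ALDD", "aldehyde dehydrogenase (NAD)",
    "acald_c + nad_c + h2o_c -> ac_c + nadh_c + 2 h_c", 0, 1000, "PDH bypass")
  rx("ACS", "acetyl-CoA synthetase",
    "ac_c + atp_c + coa_c -> accoa_c + amp_c + ppi_c", 0, 1000, "PDH bypass")
  rx("ADK1", "adenylate kinase", "amp_c + atp_c -> 2 adp_c", -1000, 1000, "PDH bypass")
  rx("PPA", "inorganic pyrophosphatase", "ppi_c + h2o_c -> 2 pi_c + h_c", 0, 1000, "PDH bypass")

  ## (7) cytosolic rTCA route and malate export
  rx("PYC", "pyruvate carboxylase",
    "pyr_c + co2_c + atp_c + h2o_c -> oaa_c + adp_c + pi_c + 2 h_c", 0, 1000, "rTCA")
  rx("MDHc", "malate dehydrogenase (cytosolic)",
    "oaa_c + nadh_c + h_c -> mal_c + nad_c", -1000, 1000, "rTCA")
  if ("malate" %in% products) {
    rx("MALt", "malate export (Mae1-style)", "mal_c -> mal_e", 0, 1000, "rTCA")
    rx("EX_mal_e", "malate exchange", "mal_e ->", 0, 1000, "exchange")
  }

  ## (8) acetone pathway, (9) MVA pathway
  if (any(c("acetone", "isoprene") %in% products)) {
    rx("THL", "thiolase (acetyl-CoA acetyltransferase)",
      "2 accoa_c -> aacoa_c + coa_c", 0, 1000, "acetone pathway")
  }
  if ("acetone" %in% products) {
    if (acetone_route == "hydrolase") {
      rx("AACOAH", "acetoacetyl-CoA hydrolase (YbgC-style)",
        "aacoa_c + h2o_c -> acac_c + coa_c + h_c", 0, 1000, "acetone pathway")
    } else {
      rx("AACOACT", "acetoacetyl-CoA transferase (CtfAB-style)",
        "aacoa_c + ac_c -> acac_c + accoa_c", 0, 1000, "acetone pathway")
    }
    rx("ADC", "acetoacetate decarboxylase", "acac_c + h_c -> acetone_c + co2_c", 0, 1000, "acetone pathway")
    rx("ACEt", "acetone diffusion", "acetone_c -> acetone_e", 0, 1000, "acetone pathway")
    rx("EX_acetone_e", "acetone exchange", "acetone_e ->", 0, 1000, "exchange")
  }
  if ("isoprene" %in% products) {
    rx("HMGS", "HMG-CoA synthase",
      "accoa_c + aacoa_c + h2o_c -> hmgcoa_c + coa_c + h_c", 0, 1000, "MVA pathway")
    rx("HMGR", "HMG-CoA reductase",
      "hmgcoa_c + 2 nadph_c + 2 h_c -> mev_c + coa_c + 2 nadp_c", 0, 1000, "MVA pathway")
    rx("MVAK", "mevalonate to IPP (lumped kinases + decarboxylase)",
      "mev_c + 3 atp_c -> ipdp_c + 3 adp_c + pi_c + co2_c + h_c", 0, 1000, "MVA pathway")
    rx("IDI", "IPP isomerase", "ipdp_c -> dmpp_c", -1000, 1000, "MVA pathway")
    rx("ISPS", "isoprene synthase", "dmpp_c -> isoprene_c + ppi_c", 0, 1000, "MVA pathway")
    rx("ISOPt", "isoprene diffusion", "isoprene_c -> isoprene_e", 0, 1000, "MVA pathway")
    rx("EX_isoprene_e", "isoprene exchange", "isoprene_e ->", 0, 1000, "exchange")
  }

  ## (10) respiration, maintenance, redox shuttles
  resp_n <- c(nadh_m = -1, h_m = -(1 + po_nadh), o2_m = -0.5,
    adp_m = -po_nadh, pi_m = -po_nadh,
    nad_m = 1, atp_m = po_nadh, h2o_m = 1 + po_nadh)
  rx("NADHRESP", "NADH respiration (lumped ETC + ATP synthase)", NULL,
    0, 1000, "respiration", stoich = resp_n)
  resp_f <- c(fadh2_m = -1, h_m = -po_fadh2, o2_m = -0.5,
    adp_m = -po_fadh2, pi_m = -po_fadh2,
    fad_m = 1, atp_m = po_fadh2, h2o_m = 1 + po_fadh2)
  rx("FADH2RESP", "FADH2 respiration (lumped ETC + ATP synthase)", NULL,
    0, 1000, "respiration", stoich = resp_f)
  rx("ATPM", "ATP maintenance", "atp_c + h2o_c -> adp_c + pi_c + h_c",
    atp_maintenance, 1000, "respiration")
  rx("NADHS", "NADH shuttle (malate-aspartate, lumped)",
    "nadh_c + nad_m -> nad_c + nadh_m", 0, 1000, "respiration")
  rx("THD", "NADPH source (lumped transhydrogenase)",
    "nadh_c + nadp_c -> nad_c + nadph_c", 0, 1000, "respiration")

  ## inter-compartment transport
  rx("ATPtm", "ATP/ADP translocase", "atp_m + adp_c -> atp_c + adp_m", -1000, 1000, "transport")
  rx("PItm", "phosphate mitochondrial transport", "pi_c -> pi_m", -1000, 1000, "transport")
  rx("Htm", "proton mitochondrial transport", "h_c -> h_m", -1000, 1000, "transport")
  rx("H2Otm", "water mitochondrial transport", "h2o_c -> h2o_m", -1000, 1000, "transport")
  rx("O2tm", "oxygen mitochondrial transport", "o2_c -> o2_m", -1000, 1000, "transport")
  rx("CO2tm", "CO2 mitochondrial transport", "co2_c -> co2_m", -1000, 1000, "transport")
  rx("MALtm", "malate mitochondrial transport", "mal_c -> mal_m", -1000, 1000, "transport")
  rx("SUCCtm", "succinate mitochondrial transport", "succ_c -> succ_m", -1000, 1000, "transport")

  ## gases, water, protons
  rx("O2t", "oxygen uptake", "o2_e -> o2_c", -1000, 1000, "transport")
  rx("EX_o2_e", "oxygen exchange", "o2_e ->", -1000, 1000, "exchange")
  rx("CO2t", "CO2 diffusion", "co2_c -> co2_e", -1000, 1000, "transport")
  rx("EX_co2_e", "CO2 exchange (secretion only: methanol is the sole carbon source)",
    "co2_e ->", 0, 1000, "exchange")
  rx("H2Ot", "water diffusion", "h2o_c -> h2o_e", -1000, 1000, "transport")
  rx("EX_h2o_e", "water exchange", "h2o_e ->", -1000, 1000, "exchange")
  rx("Ht", "proton diffusion", "h_c -> h_e", -1000, 1000, "transport")
  rx("EX_h_e", "proton exchange", "h_e ->", -1000, 1000, "exchange")
  rx("PIt", "phosphate uptake", "pi_e -> pi_c", -1000, 1000, "transport")
  rx("EX_pi_e", "phosphate exchange", "pi_e ->", -1000, 1000, "exchange")

  ## (11) lumped biomass; its pseudo-metabolite carries the exact elemental
  ## residual of the precursor draw so the reaction balances
  bm <- c(gap_c = -3, pyr_c = -5, accoa_m = -4, oaa_m = -3,
    nadph_c = -8, atp_c = -30, h2o_c = -30,
    coa_m = 4, nadp_c = 8, adp_c = 30, pi_c = 30, h_c = 30)
  bm_counts <- setNames(numeric(length(TRACKED_ELEMENTS)), TRACKED_ELEMENTS)
  for (mid in names(bm)) {
    base <- sub("_[cmxe]$", "", mid)
    bm_counts <- bm_counts - bm[[mid]] * parseFormula(.MET_FORMULA[[base]])
  }
  stopifnot(all(bm_counts >= 0))
  rx("BIOMASS", "biomass (lumped)", NULL, 0, 1000,
    "biomass", stoich = c(bm, biomass_c = 1))
  rx("EX_biomass_c", "biomass drain", "biomass_c ->", 0, 1000, "exchange")

  ## assemble tables
  rxn <- data.frame(
    id = vapply(rows, `[[`, "", "id"),
    name = vapply(rows, `[[`, "", "name"),
    lower_bound = vapply(rows, `[[`, 0, "lb"),
    upper_bound = vapply(rows, `[[`, 0, "ub"),
    subsystem = vapply(rows, `[[`, "", "sub"),
    stringsAsFactors = FALSE)
  rxn$metabolites <- lapply(rows, `[[`, "stoich")

  mids <- sort(unique(unlist(lapply(rxn$metabolites, names))))
  base <- sub("_[cmxe]$", "", mids)
  suffix <- sub("^.*_([cmxe])$", "\\1", mids)
  formula <- ifelse(base == "biomass", formatFormula(bm_counts),
    unname(.MET_FORMULA[base]))
  met <- data.frame(
    id = mids,
    name = ifelse(base == "biomass", "biomass (lumped)", unname(.MET_NAME[base])),
    compartment = unname(.COMP_NAME[suffix]),
    formula = formula,
    charge = NA_real_,
    stringsAsFactors = FALSE)

  newMetabolicModel(met, rxn,
    objective = list(reaction = "BIOMASS", direction = "max"),
    id = "methylotroph_core")
}

#' Map literature reaction aliases to core-model reaction ids
#'
#' The pathway-scenario literature refers to reactions of the full
#' genome-scale reconstruction by aliases (AKGDam, ICL, MDHm, PDHa1, PDHcm,
#' ACLSm, AKGDH1+2, CITtam, CITtap, CSp+m). The core model carries a single
#' analog for some of these isozyme/compartment pairs; such aliases map to
#' the single analog and are annotated `"merged"`. Lookups via
#' [resolveAlias()] are case-insensitive.
#'
#' @param model a model built by [buildCoreModel()]
#' @return a `data.frame` with columns `alias`, `reaction` (core-model id,
#'   or `NA` for an unmapped alias), and `note`
#' @examples
#' referenceReactionAliases(buildCoreModel())
#' @export
referenceReactionAliases <- function(model) {
  map <- data.frame(
    alias = c("AKGDam", "AKGDH1+2", "ICL", "MDHm", "PDHa1", "PDHcm",
      "ACLSm", "CITtam", "CITtap", "CSp+m"),
    reaction = c("AKGDm", "AKGDm", "ICL", "MDHm", "PDHm", "PDHm",
      NA, "CITtc", "CITtc", "CSm"),
    note = c("2-oxoglutarate dehydrogenase", "merged: single dehydrogenase",
      "", "", "merged: single PDH", "merged: single PDH",
      "unmapped: acetolactate synthase (branched-chain amino acid block absent)",
      "merged: single citrate transporter",
      "merged: single citrate transporter", "merged: single citrate synthase"),
    stringsAsFactors = FALSE)
  missing <- !map$reaction %in% reactionIds(model)
  map$reaction[missing] <- NA_character_
  map$note[missing] <- "unmapped: no core-model analog"
  map
}

#' @rdname referenceReactionAliases
#' @param aliases an alias map from [referenceReactionAliases()]
#' @param alias an alias string (case-insensitive)
#' @export
resolveAlias <- function(aliases, alias) {
  i <- match(tolower(alias), tolower(aliases$alias))
  if (is.na(i)) stop("unknown reaction alias: ", alias, call. = FALSE)
  if (is.na(aliases$reaction[i])) {
    stop("alias '", alias, "' is unmapped: ", aliases$note[i], call. = FALSE)
  }
  aliases$reaction[i]
}

#' Summarise the pathway blocks of a model
#'
#' @param model a [MetabolicModel-class]
#' @return a `data.frame` with one row per subsystem and its reaction count
#' @export
listSubsystems <- function(model) {
  tab <- table(model@reactions$subsystem)
  data.frame(subsystem = names(tab), reactions = as.integer(tab),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Carbon balance of an optimal solution
#'
#' Sums carbon inflow and outflow over the exchange reactions of a model,
#' weighting each exchange flux by the carbon count of the exchanged
#' species. At any steady-state optimum, uptake equals efflux within
#' numerical tolerance.
#'
#' @param model a [MetabolicModel-class]
#' @param solution an optimal [FluxSolution-class] for `model`
#' @return a list with `carbon_in`, `carbon_out` (mmol C/gDW/h) and
#'   `residual` (their difference)
#' @export
carbonBalance <- function(model, solution) {
  stopifnot(solutionStatus(solution) == "optimal")
  fmap <- setNames(model@metabolites$formula, model@metabolites$id)
  exch <- reactionIds(model)[isExchange(model)]
  v <- fluxes(solution)
  cin <- 0; cout <- 0
  for (rid in exch) {
    st <- model@reactions$metabolites[[match(rid, model@reactions$id)]]
    nc <- parseFormula(fmap[[names(st)]])[["C"]]
    flux <- v[[rid]] * unname(st)  # negative: species leaves the system pool
    cflux <- -flux * nc            # positive = carbon leaving the cell
    if (cflux >= 0) cout <- cout + cflux else cin <- cin - cflux
  }
  list(carbon_in = cin, carbon_out = cout, residual = cin - cout)
}
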