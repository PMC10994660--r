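name: hsc_central_carbon
description: >
  Central-carbon network for glucose metabolism in hematopoietic stem cells:
  glycolysis, oxidative and non-oxidative pentose phosphate pathway, the
  pyruvate branch point (lactate dehydrogenase, pyruvate dehydrogenase,
  pyruvate carboxylase) and a single-pool TCA cycle with lumped
  aconitase/isocitrate dehydrogenase, plus an unlabeled acetyl-CoA inflow
  standing for fatty-acid oxidation and fixed boundary drains. Atom maps
  follow standard carbon-transition conventions; symmetric succinate and
  fumarate are represented by equal-weight alternative maps.
metabolites:
  Glc:    {carbons: 6, role: input,    pathway: glycolysis}
  AcCoAx: {carbons: 2, role: input,    pathway: TCA}
  G6P:    {carbons: 6, role: internal, pathway: glycolysis}
  F6P:    {carbons: 6, role: internal, pathway: glycolysis}
  FBP:    {carbons: 6, role: internal, pathway: glycolysis}
  DHAP:   {carbons: 3, role: internal, pathway: glycolysis}
  GAP:    {carbons: 3, role: internal, pathway: glycolysis}
  PEP:    {carbons: 3, role: internal, pathway: glycolysis}
  PYR:    {carbons: 3, role: internal, pathway: glycolysis}
  LAC:    {carbons: 3, role: internal, pathway: glycolysis}
  AcCoA:  {carbons: 2, role: internal, pathway: TCA}
  OAA:    {carbons: 4, role: internal, pathway: TCA}
  CIT:    {carbons: 6, role: internal, pathway: TCA}
  AKG:    {carbons: 5, role: internal, pathway: TCA}
  SUC:    {carbons: 4, role: internal, pathway: TCA}
  FUM:    {carbons: 4, role: internal, pathway: TCA}
  MAL:    {carbons: 4, role: internal, pathway: TCA}
  CO2:    {carbons: 1, role: internal, pathway: TCA}
  Ru5P:   {carbons: 5, role: internal, pathway: PPP}
  X5P:    {carbons: 5, role: internal, pathway: PPP}
  R5P:    {carbons: 5, role: internal, pathway: NAS}
  S7P:    {carbons: 7, role: internal, pathway: PPP}
  E4P:    {carbons: 4, role: internal, pathway: PPP}
reactions:
  - {name: hk,       equation: "Glc[abcdef] -> G6P[abcdef]"}
  - {name: pgi,      equation: "G6P[abcdef] -> F6P[abcdef]", reversible: true}
  - {name: pfk,      equation: "F6P[abcdef] -> FBP[abcdef]"}
  - {name: ald,      equation: "FBP[abcdef] -> DHAP[cba] + GAP[def]", reversible: true}
  - {name: tpi,      equation: "DHAP[abc] -> GAP[abc]", reversible: true}
  - {name: gapdh,    equation: "GAP[abc] -> PEP[abc]", reversible: true}
  - {name: pk,       equation: "PEP[abc] -> PYR[abc]"}
  - {name: ldh,      equation: "PYR[abc] -> LAC[abc]"}
  - {name: pdh,      equation: "PYR[abc] -> AcCoA[bc] + CO2[a]"}
  - {name: pc,       equation: "PYR[abc] + CO2[d] -> OAA[abcd]"}
  - {name: accoa_in, equation: "AcCoAx[ab] -> AcCoA[ab]"}
  - {name: cs,       equation: "OAA[abcd] + AcCoA[ef] -> CIT[dcbfea]"}
  - {name: idh,      equation: "CIT[abcdef] -> AKG[abcde] + CO2[f]"}
  - {name: akgdh,    equation: "AKG[abcde] -> SUC[bcde] + CO2[a]"}
  - name: sdh
    equations:
      - {map: "SUC[abcd] -> FUM[abcd]", weight: 0.5}
      - {map: "SUC[abcd] -> FUM[dcba]", weight: 0.5}
  - name: fum
    reversible: true
    equations:
      - {map: "FUM[abcd] -> MAL[abcd]", weight: 0.5}
      - {map: "FUM[abcd] -> MAL[dcba]", weight: 0.5}
  - {name: mdh,      equation: "MAL[abcd] -> OAA[abcd]", reversible: true}
  - {name: g6pd,     equation: "G6P[abcdef] -> Ru5P[bcdef] + CO2[a]"}
  - {name: rpe,      equation: "Ru5P[abcde] -> X5P[abcde]", reversible: true}
  - {name: rpi,      equation: "Ru5P[abcde] -> R5P[abcde]", reversible: true}
  - {name: tkt1,     equation: "X5P[abcde] + R5P[fghij] -> S7P[abfghij] + GAP[cde]", reversible: true}
  - {name: tal,      equation: "S7P[abcdefg] + GAP[hij] -> E4P[defg] + F6P[abchij]", reversible: true}
  - {name: tkt2,     equation: "X5P[abcde] + E4P[fghi] -> F6P[abfghi] + GAP[cde]", reversible: true}
  - {name: lac_eff,  equation: "LAC[abc] ->"}
  - {name: pyr_eff,  equation: "PYR[abc] ->"}
  - {name: nas_eff,  equation: "R5P[abcde] ->"}
  - {name: oaa_eff,  equation: "OAA[abcd] ->"}
  - {name: co2_eff,  equation: "CO2[a] ->"}
inputs:
  Glc: tracer
  AcCoAx: unlabeled
constraints:
  glucose_uptake: {reaction: hk, value: 100}
  lactate_efflux: {reaction: lac_eff, value: 65}
fixed_effluxes: {pyr_eff: 85, nas_eff: 5, oaa_eff: 5}
free_fluxes: [tkt1, accoa_in]
measured: [LAC, PYR, F6P, FBP, R5P, E4P, CIT, AKG, SUC, FUM, MAL]
glycolysis_chain: [hk, pgi, pfk, ald, tpi, gapdh, pk]
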