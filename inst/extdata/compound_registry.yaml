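# Built-in compound registry: four intravenous colorectal-cancer drugs and
# their tracked active metabolites. Numeric values are carried exactly as
# printed in the source parameter table; unit strings are explicit and are
# checked at load time. Known oddities (kept as printed, flagged by the
# validator):
#   * sn38 lipophilicity is printed "3.1.4" (malformed); 3.1 is used.
#   * irinotecan per-kg clearances are implausibly large for plasma
#     clearances; used as printed.
#   * leucovorin/folitixorin solubility is printed in mg/L, others mg/mL.
compounds:
  - id: irinotecan
    name: Irinotecan
    role: parent
    physchem:
      molecular_weight: 586.7      # g/mol
      logP: 3.2
      pKa: {value: 10.9, type: base}
      solubility: {value: 0.107, unit: mg/mL}
      fraction_unbound: 0.49
    disposition:
      renal_clearance: {value: 86.68, unit: mL/min/kg}
      biliary_clearance: {value: 142.86, unit: mL/min/kg}
      enzymatic_clearance: {value: 501.22, unit: mL/min/kg}
    links:
      - metabolite: sn38
        enzyme: CES
        kinetics: linear
        fraction_converted: 1.0
  - id: sn38
    name: SN-38
    role: metabolite
    physchem:
      molecular_weight: 392.4
      logP: 3.1
      logP_printed: "3.1.4"
      pKa: {value: 9.66, type: acid}
      solubility: {value: 0.29, unit: mg/mL}
      fraction_unbound: 1
    disposition:
      total_clearance: {value: 13.01, unit: mL/min/kg, site: liver}
  - id: fluorouracil
    name: 5-FU
    role: parent
    physchem:
      molecular_weight: 130.08
      logP: -0.89
      pKa: {value: 8.02, type: acid}
      solubility: {value: 5.86, unit: mg/mL}
      fraction_unbound: 0.88
    disposition:
      renal_clearance: {value: 2.38, unit: mL/min/kg}
      km: {value: 3.17, unit: nmol/mL}
      vmax: {value: 22.5, unit: mL/min/g}
    links:
      - metabolite: fuh2
        enzyme: DPD
        kinetics: michaelis_menten
        fraction_converted: 0.9
  - id: fuh2
    name: FUH2
    role: metabolite
    physchem:
      molecular_weight: 114.1
      logP: -1.1
      pKa: {value: 11.73, type: acid}
      solubility: {value: 25.9, unit: mg/mL}
      fraction_unbound: 1
    disposition:
      total_clearance: {value: 1.18, unit: L/h/kg, site: liver}
  - id: oxaliplatin
    name: Oxaliplatin
    role: parent
    physchem:
      molecular_weight: 397.29
      logP: -0.47
      pKa: null                    # neutral compound
      solubility: {value: 27.5, unit: mg/mL}
      fraction_unbound: 0.1
    disposition:
      total_clearance: {value: 2.5, unit: L/h, site: kidney}
  - id: leucovorin
    name: Leucovorin
    role: parent
    physchem:
      molecular_weight: 473.446
      logP: -3.2
      pKa: {value: 3.47, type: acid}
      solubility: {value: 0.297, unit: mg/L}
      fraction_unbound: 0.85
    disposition:
      renal_clearance: {value: 1.14, unit: mL/min/kg}
      enzymatic_clearance: {value: 297, unit: mL/min}
    links:
      - metabolite: folitixorin
        enzyme: MTHFR
        kinetics: linear
        fraction_converted: 1.0
  - id: folitixorin
    name: Folitixorin
    role: metabolite
    physchem:
      molecular_weight: 459.5
      logP: -0.5
      pKa: {value: 3.23, type: acid}
      solubility: {value: 0.33, unit: mg/L}
      fraction_unbound: 0.44
    disposition:
      renal_clearance: {value: 1.21, unit: mL/min/kg}
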