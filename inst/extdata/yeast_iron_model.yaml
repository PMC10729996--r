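# Bundled iron-trafficking model for growing budding yeast.
# Concentrations are local to each component's compartment (uM); rates in
# uM/min; growth rates in 1/min. The three training states are W (wild type,
# iron-replete), Y (Yfh1/frataxin-deficient) and D (wild type, iron-
# deficient). reference_constants holds the published full-precision
# steady-state rates and rate constants used for validation.
model: yeast_iron_trafficking
version: 1
compartments:
  f_cyt: 0.8
  f_mit: 0.1
  f_vac: 0.1
components:
  - {id: FC,  compartment: cytosol,      description: labile Fe(II) pool, cytosol}
  - {id: CIA, compartment: cytosol,      description: cytosolic/nuclear iron destinations (ISC etc.)}
  - {id: F2,  compartment: vacuole,      description: vacuolar Fe(II)}
  - {id: F3,  compartment: vacuole,      description: vacuolar Fe(III)}
  - {id: FM,  compartment: mitochondria, description: labile Fe(II) pool, mitochondrial matrix}
  - {id: FS,  compartment: mitochondria, description: iron-sulfur clusters and hemes}
  - {id: MP,  compartment: mitochondria, description: ferric phosphate oxyhydroxide nanoparticles}
  - {id: O2,  compartment: mitochondria, description: dissolved O2 in the matrix}
reactions:
  - {id: cyt, equation: "IRON -> FC",    kind: saturating_import,       region: "E,C"}
  - {id: mit, equation: "FC -> FM",      kind: saturating_transfer,     region: "C,M"}
  - {id: vac, equation: "FC -> F2",      kind: saturating_transfer,     region: "C,V"}
  - {id: cia, equation: "FC -> CIA",     kind: saturating_transfer,     region: "C"}
  - {id: isu, equation: "FM -> FS",      kind: saturating_o2_inhibited, region: "M"}
  - {id: mp,  equation: "FM + O2 -> MP", kind: bilinear,                region: "M"}
  - {id: O2,  equation: "OXYGEN -> O2",  kind: linear_exchange,         region: "E,M"}
  - {id: res, equation: "O2 ->",         kind: saturating_catalytic,    region: "M"}
  - {id: "23", equation: "F2 -> F3",     kind: saturating_external,     region: "V"}
km:
  cyt: 10.0
  mit: 20.0
  vac: 20.0
  cia: 20.0
  "23": 200.0
  isu: 100.0
  res: 1.0
o2_setpoint: 1.0
states:
  "W":
    conc: {FC: 20.0, CIA: 80.0, F2: 200.0, F3: 3400.0, FM: 100.0, FS: 500.0, MP: 50.0, O2: 1.0}
    alpha: 0.003333
    IRON: 40.0
    OXYGEN: 100.0
    R_res: 9090.909091
  # Y and D [O2] are stored at the full precision implied by the published
  # rate constants (k_isu(Y) = 0.6666 and k_isu(D) = k_isu(W) = 6.666 with
  # k_res = 36.363636 in every state); the published concentration table
  # rounds them to 0.48 and 1.2.
  "Y":
    conc: {FC: 10.0, CIA: 70.0, F2: 30.0, F3: 420.0, FM: 200.0, FS: 150.0, MP: 8500.0, O2: 0.4813333}
    alpha: 0.0020
    IRON: 40.0
    OXYGEN: 100.0
    R_res: 1772.36
  "D":
    conc: {FC: 5.0, CIA: 68.0, F2: 20.0, F3: 60.0, FM: 50.0, FS: 300.0, MP: 20.0, O2: 1.2222222}
    alpha: 0.003333
    IRON: 1.0
    OXYGEN: 100.0
    R_res: 6000.0
reference_constants:
  "W":
    R_cia: 0.266640
    R_23: 11.332200
    R_isu: 1.666500
    R_mp: 0.166650
    R_vac: 1.499850
    R_mit: 0.270806
    R_cyt: 2.103960
    R_res: 9090.909091
    R_O2: 9091.080000
    D_FC: 0.066660
    D_CIA: 0.266640
    D_F2: 0.666600
    D_F3: 11.332200
    D_FM: 0.333300
    D_FS: 1.666500
    D_MP: 0.166650
    D_O2: 0.003333
    k_cia: 0.533280
    k_23: 0.226643
    k_isu: 6.666000
    k_mp: 0.001667
    k_vac: 2.999702
    k_mit: 0.541613
    k_cyt: 2.629947
    k_res: 36.363636
    k_O2: 91.829091
  "Y":
    R_cia: 0.140000
    R_23: 0.840000
    R_isu: 0.300000
    R_mp: 17.000000
    R_vac: 0.112500
    R_mit: 2.212500
    R_cyt: 2.485000
    R_res: 1772.360000
    R_O2: 1789.360000
    D_FC: 0.020000
    D_CIA: 0.140000
    D_F2: 0.060000
    D_F3: 0.840000
    D_FM: 0.400000
    D_FS: 0.300000
    D_MP: 17.000000
    D_O2: 0.000963
    k_cia: 0.420000
    k_23: 0.064400
    k_isu: 0.666600
    k_mp: 0.176597
    k_vac: 0.337501
    k_mit: 6.637541
    k_cyt: 3.106247
    k_res: 36.363636
    k_O2: 17.980069
  "D":
    R_cia: 0.226644
    R_23: 0.199980
    R_isu: 0.999900
    R_mp: 0.066660
    R_vac: 0.033330
    R_mit: 0.154151
    R_cyt: 0.430790
    R_res: 6000.000000
    R_O2: 6000.070000
    D_FC: 0.016665
    D_CIA: 0.226644
    D_F2: 0.066660
    D_F3: 0.199980
    D_FM: 0.166650
    D_FS: 0.999900
    D_MP: 0.066660
    D_O2: 0.004074
    k_cia: 1.133219
    k_23: 0.021998
    k_isu: 6.666000
    k_mp: 0.001091
    k_vac: 0.166650
    k_mit: 0.770759
    k_cyt: 4.738685
    k_res: 36.363636
    k_O2: 60.743001
crm_cases:
  case1:
    "23": {sensor: FC, "n": 0.249,   SP: 15.1,  k_reg: 0.294, k_unreg: 0.0,     mode: feedforward}
    cia:  {sensor: FM, "n": -0.0388, SP: 0.992, k_reg: 5.51,  k_unreg: 0.418,   mode: feedback}
    vac:  {sensor: FC, "n": 0.680,   SP: 14.0,  k_reg: 2.89,  k_unreg: 0.160,   mode: feedforward}
    mit:  {sensor: FS, "n": -0.022,  SP: 0.992, k_reg: 169.0, k_unreg: 0.539,   mode: feedback}
    cyt:  {sensor: FC, "n": -1.00,   SP: 8.74,  k_reg: 2.16,  k_unreg: 2.63,    mode: feedback}
    O2:   {sensor: FS, "n": 0.0135,  SP: 258.0, k_reg: 95.4,  k_unreg: 0.0,     mode: feedforward}
    mp:   {sensor: FM, "n": 0.0587,  SP: 225.0, k_reg: 0.931, k_unreg: 0.00106, mode: feedforward}
  case2:
    "23": {sensor: FC, "n": 0.249,   SP: 15.1,  k_reg: 0.294, k_unreg: 0.0,     mode: feedforward}
    cia:  {sensor: FM, "n": -0.0388, SP: 0.992, k_reg: 5.51,  k_unreg: 0.418,   mode: feedback}
    vac:  {sensor: FC, "n": 0.680,   SP: 14.0,  k_reg: 2.89,  k_unreg: 0.160,   mode: feedforward}
    mit:  {sensor: FS, "n": -0.022,  SP: 0.992, k_reg: 169.0, k_unreg: 0.539,   mode: feedback}
    cyt:  {sensor: F2, "n": -0.159,  SP: 7.91,  k_reg: 16.6,  k_unreg: 2.63,    mode: feedback}
    O2:   {sensor: FS, "n": 0.0135,  SP: 258.0, k_reg: 95.4,  k_unreg: 0.0,     mode: feedforward}
    mp:   {sensor: FM, "n": 0.0587,  SP: 225.0, k_reg: 0.931, k_unreg: 0.00106, mode: feedforward}
predictions:
  H_W:
    from: "W"
    crm: case1
    OXYGEN: 25.0
    target: {FC: 16.8, CIA: 174.0, F2: 1736.0, F3: 1194.0, FM: 44.7, FS: 545.0, MP: 1.93, O2: 0.13}
    alpha: 0.003333
  H_Y:
    from: "Y"
    crm: case1
    OXYGEN: 1.0
    target: {FC: 18.5, CIA: 100.0, F2: 5500.0, F3: 100.0, FM: 467.0, FS: 273.0, MP: 1129.0, O2: 0.0051}
    alpha: 0.0020
transitions:
  WY: {kind: primary_mutation, k_isu: 0.6666, alpha: 0.0020}
  WD: {kind: nutrient, IRON: 1.0}
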