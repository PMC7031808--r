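# Quasimolecular parsing of the averaged POPE/POPG (3:1) lipid and the two
# magainin-family peptides.  Volumes in cubic Angstrom per single
# occurrence; multiplicities per averaged-lipid unit cell.
groups:
  - {name: ENX, formula: C2H7N, volume: 51.0, n_exchangeable: 3, multiplicity: 0.75}
  - {name: PG2, formula: C3H7O2, volume: 71.0, n_exchangeable: 2, multiplicity: 0.25}
  - {name: PO4, formula: PO4, volume: 53.7}
  - {name: CG, formula: C5H5O4, volume: 146.8}
  - {name: CH, formula: CH, volume: 22.24, multiplicity: 2}
  - {name: CH2, formula: CH2, volume: 27.81, multiplicity: 28}
  - {name: CH3, formula: CH3, volume: 52.83, multiplicity: 2}
peptides:
  - {name: L18W-PGLa, sequence: GMASKAGAIAGKIAKVAWKAL, volume: 4927.8, cterm_amidated: true}
  - {name: MG2a, sequence: GIGKFLHSAKKFGKAFVGEIMNS, volume: 5748.0, cterm_amidated: true}
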