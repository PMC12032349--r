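# Default biogeochemical trait gene sets (synthetic default set).
# Editable stand-in covering the trait categories used throughout the
# package: inorganic transport, alternative resource forms, and
# regulation for Fe/N/P stress, plus CAZyme-style carbon degradation.
Fe_stress:
  system: KO
  genes:
    - {id: K02012, function: ferric iron ABC transporter}
    - {id: K02016, function: siderophore iron complex uptake}
    - {id: K23227, function: siderophore biosynthesis regulation}
    - {id: K02014, function: TonB-dependent iron receptor}
N_stress:
  system: KO
  genes:
    - {id: K01428, function: urea hydrolysis (urease)}
    - {id: K11959, function: urea ABC transporter}
    - {id: K15576, function: nitrate/nitrite transporter}
    - {id: K00370, function: nitrate reductase}
P_stress:
  system: KO
  genes:
    - {id: K01113, function: alkaline phosphatase}
    - {id: K02040, function: phosphate ABC transporter}
    - {id: K02044, function: phosphonate transporter}
    - {id: K05781, function: phosphonate degradation}
C_degradation:
  system: Pfam
  genes:
    - {id: PF00704, function: glycoside hydrolase}
    - {id: PF01373, function: glycoside hydrolase}
    - {id: PF02156, function: glycoside hydrolase}
    - {id: PF00722, function: glycosyl hydrolase polysaccharide binding}
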