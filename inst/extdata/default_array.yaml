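# Default four-FBG sensing array of the soft wearable patch.
# Sensitivities are in nm per millistrain (nm/me); geometry in mm.
array:
  edge_to_edge_spacing_mm: 20
  matrix_dims_mm: [230, 36, 1]
  gratings:
    - label: FBG1
      lambda_B0_nm: 1525
      S_eps_nm_per_me: 0.044
      S_T_nm_per_C: 0
      grating_length_mm: 10
      center_position_mm: 5
    - label: FBG2
      lambda_B0_nm: 1533
      S_eps_nm_per_me: 0.045
      S_T_nm_per_C: 0
      grating_length_mm: 10
      center_position_mm: 35
    - label: FBG3
      lambda_B0_nm: 1541
      S_eps_nm_per_me: 0.045
      S_T_nm_per_C: 0
      grating_length_mm: 10
      center_position_mm: 65
    - label: FBG4
      lambda_B0_nm: 1549
      S_eps_nm_per_me: 0.046
      S_T_nm_per_C: 0
      grating_length_mm: 10
      center_position_mm: 95
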