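{
  "n_vessels": 113,
  "n_outlets": 61,
  "n_renal_per_side": 38,
  "n_segmental_per_side": 5,
  "reference_cardiac_output_l_min": 5.74,
  "heart_rate_bpm": 70,
  "note": "Reconstructed fixture: the anatomical source publishes 49 outlets; this reconstruction terminates every distal interlobar branch in its own lumped R-C-R bed, giving the outlet count recorded here."
}
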