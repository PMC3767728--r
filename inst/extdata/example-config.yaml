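# Example partial configuration: liberal trigger, dearer epoetin.
# Omitted fields keep their base-case defaults.
name: liberal_trigger_dear_epo
n_patients: 5000
seed: 42
clinical:
  transfusion_trigger: 9.0
costs:
  epo_dose_cost: 250
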