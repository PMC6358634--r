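# Clinical dose-volume constraint presets per protocol. Types:
#   max_dose_at_volume          V(dose_Gy) <= volume %
#   min_dose_at_volume          V(dose_Gy) >= volume %
#   max_dose_at_absolute_volume volume (cm3) receiving >= dose_Gy <= volume
prostate_a:
  - {structure: rectum,       type: max_dose_at_volume, dose_Gy: 18.12, volume: 50, volume_unit: percent}
  - {structure: bladder,      type: max_dose_at_volume, dose_Gy: 18.12, volume: 50, volume_unit: percent}
  - {structure: femoral_head, type: max_dose_at_absolute_volume, dose_Gy: 20.00, volume: 10, volume_unit: cm3}
prostate_b:
  - {structure: ptv,     type: min_dose_at_volume, dose_Gy: 38.00, volume: 95, volume_unit: percent}
  - {structure: ptv,     type: min_dose_at_volume, dose_Gy: 47.50, volume: 50, volume_unit: percent}
  - {structure: ptv,     type: min_dose_at_volume, dose_Gy: 57.00, volume: 15, volume_unit: percent}
  - {structure: urethra, type: max_dose_at_volume, dose_Gy: 39.90, volume: 50, volume_unit: percent}
  - {structure: rectum,  type: max_dose_at_absolute_volume, dose_Gy: 28.50, volume: 2, volume_unit: cm3}
lung:
  - {structure: ptv,               type: min_dose_at_volume, dose_Gy: 50.00, volume: 95, volume_unit: percent}
  - {structure: proximal_bronchus, type: max_dose_at_absolute_volume, dose_Gy: 18.00, volume: 4, volume_unit: cm3}
liver:
  - {structure: ptv,          type: min_dose_at_volume, dose_Gy: 42.75, volume: 95, volume_unit: percent}
  - {structure: normal_liver, type: max_dose_at_volume, dose_Gy: 15.00, volume: 50, volume_unit: percent}
breast:
  - {structure: ptv,                type: min_dose_at_volume, dose_Gy: 35.00, volume: 95, volume_unit: percent}
  - {structure: ipsilateral_breast, type: max_dose_at_volume, dose_Gy: 17.50, volume: 40, volume_unit: percent}
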