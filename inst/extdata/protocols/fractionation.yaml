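# Hypofractionated SABR prescription presets (total dose in Gy / fractions).
prostate_a: {total_dose_gy: 36.25, fractions: 5, protocol: "RTOG 0938"}
prostate_b: {total_dose_gy: 38.00, fractions: 4, protocol: "Fuller et al."}
lung:       {total_dose_gy: 50.00, fractions: 5, protocol: "RTOG 0813"}
liver:      {total_dose_gy: 42.75, fractions: 3, protocol: "Vautravers-Dewas et al."}
breast:     {total_dose_gy: 35.00, fractions: 5, protocol: "RTOG 0413"}
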