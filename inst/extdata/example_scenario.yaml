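# Example treatment scenario: prolate tumor (aspect ratio 2, volume of a
# 0.5 cm sphere), single-slot antenna at the tumor center, 20 W at
# 2.45 GHz, stopping when the mean dead fraction over the healthy shell of
# eight tumor volumes reaches 10%.
shape: prolate
r_eq_mm: 5.0
lambda: 2.0
antenna_kind: single_slot
power_W: 20.0
frequency_GHz: 2.45
duration_s: 1200.0
dt_s: 0.5
T_init_C: 37.0
Ds: 0.10
monitor_mode: shell_8x
lesion_threshold: 0.5
cadence_s: 5.0
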