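# Example session configuration for vdtblink (read_session_config()).
# A 120-min recording at 60 frames/s split into four 30-min phases,
# with the incomplete-blink threshold calibrated on the first 10 min.
frame_rate: 60
phase_duration: 1800
n_phases: 4
calibration_window: 600
downsample_width: 600
downsample_height: 450
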