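# Demonstration six-phase fall simulation protocol.
# Schema: top-level keys sampling_rate_hz, noise_sd_g, optional clip_range_g,
# seed, and phases (ordered). Each phase carries label (1..6), duration_s and
# the parameters its kind requires:
#   1 steps:       step_frequency_hz, step_amplitude_g
#   2 fall_impact: freefall_duration_s, impact_peak_g, impact_duration_s,
#                  end_pitch_deg
#   3/5 rest:      pitch_deg
#   4 raise, 6 stand: start_pitch_deg, end_pitch_deg, transient_amplitude_g
# Pitch is trunk pitch in degrees (0 upright, 90 horizontal forward bend);
# accelerations are in g.
sampling_rate_hz: 100
noise_sd_g: 0.02
seed: 20
phases:
- label: 1
  duration_s: 4.0
  step_frequency_hz: 1.8
  step_amplitude_g: 0.25
- label: 2
  duration_s: 1.5
  freefall_duration_s: 0.3
  impact_peak_g: 3.0
  impact_duration_s: 0.15
  end_pitch_deg: 70.0
- label: 3
  duration_s: 1.5
  pitch_deg: 70.0
- label: 4
  duration_s: 1.5
  start_pitch_deg: 70.0
  end_pitch_deg: 15.0
  transient_amplitude_g: 0.15
- label: 5
  duration_s: 4.0
  pitch_deg: 15.0
- label: 6
  duration_s: 2.0
  start_pitch_deg: 15.0
  end_pitch_deg: 0.0
  transient_amplitude_g: 0.1
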