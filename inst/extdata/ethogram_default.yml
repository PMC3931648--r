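# Synthetic five-behaviour ethogram (Stand, Lying, Walk, Run, Crawl):
# 10 s per behaviour at 20 Hz.  Mirrors accelknn::default_ethogram().
# All template numbers are synthetic fixture choices; angles in degrees,
# amplitudes and noise in g, frequencies in Hz, phases in radians.
sample_rate: 20
seconds_per_behavior: 10
seed: 1
phase_jitter: true
behaviors:
  - name: Stand
    pitch: 0
    roll: 0
    noise_sd: 0.05
  - name: Lying
    pitch: 90
    roll: 0
    noise_sd: 0.05
  - name: Walk
    pitch: 15
    roll: 0
    noise_sd: 0.05
    components:
      - {axis: z, freq: 2, amp: 0.25, phase: 0}
      - {axis: x, freq: 2, amp: 0.1, phase: 1.5707963267948966}
  - name: Run
    pitch: 30
    roll: 0
    noise_sd: 0.05
    components:
      - {axis: z, freq: 3.5, amp: 0.5, phase: 0}
      - {axis: x, freq: 3.5, amp: 0.2, phase: 1.5707963267948966}
  - name: Crawl
    pitch: 60
    roll: 20
    noise_sd: 0.05
    components:
      - {axis: z, freq: 1, amp: 0.15, phase: 0}
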