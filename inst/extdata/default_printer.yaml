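# Piston-driven extruder: 5-ml syringe (12 mm bore) + 0.4 mm needle.
# Lengths/torques/speeds accept unit tags; bare numbers are SI.
hardware:
  max_torque: 40 N cm
  pitch: 0.8 mm
  efficiency: 0.5
  duty_fraction: 0.8
segments:
  - kind: cylinder
    length: 60 mm
    radius: 6 mm
  - kind: cone
    length: 10 mm
    radius_in: 6 mm
    radius_out: 0.2 mm
  - kind: cylinder
    length: 16 mm
    radius: 0.2 mm
inlet_velocity: 1e-5
material:
  label: C20_pH3.7
  K: 5.78
  n: 0.12
  E: 30
  eta0: 231.4
  nu: 0.49
  rho: 1000
  support:
    label: PVA-PVP bath
    E: 1000
    eta0: 1500
scaffold:
  strand_width: 0.77 mm
  layer_height: 0.55 mm
  inter_fiber_distance: 2.57 mm
  n_layers: 6
thresholds:
  shear_stress: 80
  collapse_strain: 0.05
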