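# Synthetic promoter fixture set (arbitrary fluorescence units).
# Two qualitative classes: amplifying (low Kd, high n; saturate within the
# physiological activator range) and filtering (high Kd, low n; respond only
# at high activator). The inaA-like Kd is 10x the micF-like Kd. Chimeras carry
# the activator-binding box of one parent in the backbone of the other and sit
# between their parents in (Kd, n). These are synthetic stand-in parameters
# realizing the qualitative classes, not measured values.
micF:
  V: 2500
  b: 50
  Kd: 70
  "n": 2.4
  klass: amplifying
marRAB:
  V: 1800
  b: 40
  Kd: 90
  "n": 2.0
  klass: amplifying
acrAB:
  V: 2200
  b: 60
  Kd: 700
  "n": 1.2
  klass: filtering
inaA:
  V: 2600
  b: 45
  Kd: 700
  "n": 1.1
  klass: filtering
sodA:
  V: 2000
  b: 55
  Kd: 850
  "n": 1.0
  klass: filtering
tolC:
  V: 2400
  b: 70
  Kd: 900
  "n": 0.9
  klass: filtering
chimera_am:           # acrAB backbone carrying the marRAB box
  V: 2200
  b: 60
  Kd: 250
  "n": 1.6
  klass: chimeric
  parents: [marRAB, acrAB]
chimera_ma:           # marRAB backbone carrying the acrAB box
  V: 1800
  b: 40
  Kd: 300
  "n": 1.5
  klass: chimeric
  parents: [marRAB, acrAB]
control:              # unregulated, constitutive
  V: 800
  b: 40
  Kd: 1
  "n": 1
  klass: control
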