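# Gastric wish-list for automated prioritized VMAT plan generation.
#
# Structure-name mapping to the structure_set masks:
#   "Patient" -> Body; "Left and Right Kidney" -> Kidneys (union);
#   "Left and Right Lung" -> Lungs (union); shells/skin ring as named.
# Dose quantities are Gy unless given as {percent_of_prescription: p}.
prescription:
  dose_gy: 45.0
  n_fractions: 25
relaxation: 0.03
constraints:
  - volume: PTV
    kind: maximum
    limit:
      percent_of_prescription: 105
  - volume: PTV Shell 39 mm
    kind: maximum
    limit:
      percent_of_prescription: 50
  - volume: Body
    kind: maximum
    limit:
      percent_of_prescription: 105
objectives:
  - priority: 1
    volume: PTV
    kind: LTCP
    goal: 0.4
    params:
      Dp: 45.0
      alpha: 4.0
  - priority: 2
    volume: PTV Shell 3 mm
    kind: maximum
    goal:
      percent_of_prescription: 90
  - priority: 3
    volume: Kidneys
    kind: mean
    goal: 8.0
  - priority: 4
    volume: Liver
    kind: mean
    goal: 15.0
  - priority: 5
    volume: Heart
    kind: EUD
    goal: 15.0
    params:
      k: 6.0
  - priority: 6
    volume: SpinalCord
    kind: EUD
    goal: 25.0
    params:
      k: 12.0
  - priority: 7
    volume: PTV Shell 18 mm
    kind: maximum
    goal:
      percent_of_prescription: 40
  - priority: 7
    volume: SkinRing
    kind: maximum
    goal:
      percent_of_prescription: 25
  - priority: 8
    volume: Kidneys
    kind: dose-volume
    goal: 25.0
    params:
      threshold: 12.0
  - priority: 8
    volume: Liver
    kind: dose-volume
    goal: 30.0
    params:
      threshold: 24.0
  - priority: 9
    volume: Lungs
    kind: dose-volume
    goal: 50.0
    params:
      threshold: 20.0
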