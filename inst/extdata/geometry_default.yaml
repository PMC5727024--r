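# Reduced lower-limb musculoskeletal geometry (right limb).
#
# Segment-local frames: X anterior, Y up along the segment, Z mediolateral
# (to the right); origin at the proximal joint centre (hip for thigh, knee
# for shank, ankle for foot, patella centre for patella, mid-pelvis for
# pelvis). Coordinates in metres for a reference limb (0.42 m thigh and
# shank, 0.25 m foot) and are rescaled per subject by scale_geometry().
#
# SYNTHETIC PLACEHOLDER DATA: attachment coordinates, PCSA values, ligament
# bounds and the rho lookup are plausible values chosen so the model is
# well-posed; they are not cadaver measurements. A richer file with the
# same schema (any muscle/ligament count) drops in unchanged.
sigma_max: 31.39          # N/cm^2, maximum isometric muscle stress
segments:
  pelvis:
    reference_length: 0.20
    mass_fraction: 0.1117
    com_fraction: 0.5
    gyration: [0.30, 0.30, 0.30]
  thigh:
    reference_length: 0.42
    mass_fraction: 0.1416
    com_fraction: 0.41
    gyration: [0.329, 0.329, 0.149]
  shank:
    reference_length: 0.42
    mass_fraction: 0.0433
    com_fraction: 0.44
    gyration: [0.251, 0.246, 0.102]
  foot:
    reference_length: 0.25
    mass_fraction: 0.0137
    com_fraction: 0.44
    gyration: [0.257, 0.245, 0.124]
  patella:
    reference_length: 0.04
    mass_fraction: 0.0
    com_fraction: 0.5
    gyration: [0.3, 0.3, 0.3]
muscles:
  - name: vastus_medialis
    group: quadriceps
    pcsa: 56.65
    attachments:
      - {segment: thigh, xyz: [0.0113, -0.2097, -0.0134]}
      - {segment: patella, xyz: [-0.0074, 0.0251, -0.002]}
  - name: vastus_intermedialis
    group: quadriceps
    pcsa: 60.3
    attachments:
      - {segment: thigh, xyz: [0.0099, -0.1782, 0.0018]}
      - {segment: patella, xyz: [-0.0026, 0.0282, -0.0068]}
  - name: vastus_lateralis
    group: quadriceps
    pcsa: 72.62
    attachments:
      - {segment: thigh, xyz: [0.0175, -0.2045, 0.0174]}
      - {segment: patella, xyz: [-0.0011, 0.03, 0.0064]}
  - name: rectus_femoris
    group: quadriceps
    pcsa: 33.71
    attachments:
      - {segment: pelvis, xyz: [0.0131, -0.0632, 0.0848]}
      - {segment: patella, xyz: [-0.0092, 0.037, 0.0113]}
  - name: biceps_femoris_long_head
    group: hamstrings
    pcsa: 31.49
    attachments:
      - {segment: pelvis, xyz: [-0.0449, -0.0724, 0.0689]}
      - {segment: shank, xyz: [0.0119, -0.0386, 0.0219]}
  - name: semitendinosus
    group: hamstrings
    pcsa: 15.26
    attachments:
      - {segment: pelvis, xyz: [-0.0476, -0.0539, 0.0652]}
      - {segment: shank, xyz: [0.0241, -0.0718, -0.0318]}
  - name: semimembranosus
    group: hamstrings
    pcsa: 46.2
    attachments:
      - {segment: pelvis, xyz: [-0.0553, -0.0597, 0.0558]}
      - {segment: shank, xyz: [-0.0108, -0.044, -0.0226]}
  - name: tensor_fasciae_latae
    group: other
    pcsa: 13.91
    attachments:
      - {segment: pelvis, xyz: [0.0325, 0.0025, 0.0918]}
      - {segment: shank, xyz: [0.0308, -0.0532, 0.022]}
  - name: gastrocnemius_medialis
    group: other
    pcsa: 40.42
    attachments:
      - {segment: thigh, xyz: [-0.0109, -0.3881, -0.0224]}
      - {segment: foot, xyz: [-0.058, -0.0511, -0.0064]}
  - name: gastrocnemius_lateralis
    group: other
    pcsa: 29.74
    attachments:
      - {segment: thigh, xyz: [-0.0294, -0.386, 0.0239]}
      - {segment: foot, xyz: [-0.0466, -0.0506, -0.0055]}
  - name: soleus
    group: other
    pcsa: 143.8
    attachments:
      - {segment: shank, xyz: [-0.0073, -0.1079, 0.0077]}
      - {segment: foot, xyz: [-0.0571, -0.0627, 0.0191]}
  - name: tibialis_anterior
    group: other
    pcsa: 27.54
    attachments:
      - {segment: shank, xyz: [0.0137, -0.1602, -0.0561]}
      - {segment: foot, xyz: [0.0443, -0.0375, -0.0192]}
  - name: peroneus_brevis
    group: other
    pcsa: 15.23
    attachments:
      - {segment: shank, xyz: [0.0166, -0.1266, 0.0233]}
      - {segment: foot, xyz: [0.0306, -0.045, 0.0431]}
  - name: tibialis_posterior
    group: other
    pcsa: 14.57
    attachments:
      - {segment: shank, xyz: [-0.0144, -0.1478, -0.0087]}
      - {segment: foot, xyz: [0.0544, -0.0675, -0.0461]}
  - name: peroneus_tertius
    group: other
    pcsa: 13.93
    attachments:
      - {segment: shank, xyz: [-0.0017, -0.3358, 0.0388]}
      - {segment: foot, xyz: [0.0875, -0.0501, 0.0217]}
  - name: gluteus_maximus
    group: other
    pcsa: 247.7
    attachments:
      - {segment: pelvis, xyz: [-0.0651, -0.0333, 0.0748]}
      - {segment: thigh, xyz: [-0.0322, -0.0696, 0.0338]}
  - name: gluteus_medius
    group: other
    pcsa: 105.5
    attachments:
      - {segment: pelvis, xyz: [0.0141, 0.0252, 0.0992]}
      - {segment: thigh, xyz: [-0.0131, -0.0325, 0.0549]}
  - name: iliopsoas
    group: other
    pcsa: 39.41
    attachments:
      - {segment: pelvis, xyz: [0.0297, -0.0226, 0.0436]}
      - {segment: thigh, xyz: [-0.0138, -0.0683, -0.0111]}
patellar_tendon:
  attachments:
    - {segment: patella, xyz: [0.002, -0.025, 0.000]}
    - {segment: shank, xyz: [0.040, -0.075, 0.000]}
ligaments:
  - name: ACL
    l_max: 1795
    attachments:
      - {segment: thigh, xyz: [-0.006, -0.410, 0.006]}
      - {segment: shank, xyz: [0.010, -0.020, 0.000]}
  - name: PCL
    l_max: 1803
    attachments:
      - {segment: thigh, xyz: [-0.010, -0.400, -0.006]}
      - {segment: shank, xyz: [-0.022, -0.030, 0.000]}
  - name: MCL
    l_max: 1433
    attachments:
      - {segment: thigh, xyz: [0.000, -0.400, -0.040]}
      - {segment: shank, xyz: [0.000, -0.080, -0.030]}
  - name: LCL
    l_max: 1005
    attachments:
      - {segment: thigh, xyz: [0.000, -0.400, 0.040]}
      - {segment: shank, xyz: [-0.004, -0.060, 0.035]}
contacts:
  medial:
    segment: shank
    xyz: [0.000, -0.004, -0.022]
  lateral:
    segment: shank
    xyz: [0.000, -0.004, 0.022]
  patellofemoral:
    segment: thigh
    xyz: [0.032, -0.400, 0.000]
rho_lookup:
  flexion_deg: [0, 30, 60, 90, 120]
  ratio: [1.05, 0.95, 0.80, 0.70, 0.65]
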