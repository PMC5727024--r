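Package: kneeload
Title: Knee Joint Contact Forces by Static Optimization and Their Test-Retest Reliability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A lower-limb musculoskeletal modelling pipeline for estimating
    muscle, ligament and knee joint contact forces from marker trajectories and
    ground reaction data, together with the test-retest reliability statistics
    used to qualify such estimates. Segment poses are fitted to marker clusters
    by orthogonal Procrustes, a per-frame indeterminate equilibrium system over
    foot, shank, thigh and patella is assembled from file-driven musculoskeletal
    geometry, and the muscle/ligament force distribution is resolved by
    minimizing the sum of cubed stresses subject to equilibrium and physiological
    bounds. Outcome waveforms (medial, lateral and total tibiofemoral and
    patellofemoral contact force, quadriceps and hamstrings force, knee flexion)
    are time-normalized to percent stance, and peak values feed intraclass
    correlation coefficients, standard error of measurement and minimal
    detectable change. A synthetic motion-capture study generator with a known
    variance structure exercises every stage without laboratory data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    yaml,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
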