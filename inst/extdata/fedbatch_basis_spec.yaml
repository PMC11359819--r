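air_overlay:
  phase1:
    family: polynomial
    n_basis: 1
  phase2:
    family: polynomial
    n_basis: 1
  phase3:
    family: polynomial
    n_basis: 1
  phase4:
    family: polynomial
    n_basis: 1
  phase5:
    family: polynomial
    n_basis: 1
air_sparger:
  phase1:
    family: polynomial
    n_basis: 1
  phase2:
    family: polynomial
    n_basis: 1
  phase3:
    family: polynomial
    n_basis: 1
  phase4:
    family: polynomial
    n_basis: 1
  phase5:
    family: polynomial
    n_basis: 1
DO1:
  phase1:
    family: polynomial
    n_basis: 1
  phase2:
    family: polynomial
    n_basis: 1
  phase3:
    family: polynomial
    n_basis: 1
  phase4:
    family: bspline_degree3
    n_basis: 28
  phase5:
    family: bspline_degree3
    n_basis: 28
DO2:
  phase1:
    family: polynomial
    n_basis: 1
  phase2:
    family: polynomial
    n_basis: 1
  phase3:
    family: polynomial
    n_basis: 1
  phase4:
    family: bspline_degree3
    n_basis: 28
  phase5:
    family: bspline_degree3
    n_basis: 28
o2_sparger:
  phase1:
    family: polynomial
    n_basis: 3
  phase2:
    family: polynomial
    n_basis: 3
  phase3:
    family: polynomial
    n_basis: 3
  phase4:
    family: bspline_degree3
    n_basis: 22
  phase5:
    family: bspline_degree3
    n_basis: 20
pH1:
  phase1:
    family: bspline_degree3
    n_basis: 24
  phase2:
    family: bspline_degree3
    n_basis: 9
  phase3:
    family: bspline_degree3
    n_basis: 40
  phase4:
    family: bspline_degree3
    n_basis: 5
  phase5:
    family: bspline_degree3
    n_basis: 8
pH2:
  phase1:
    family: bspline_degree3
    n_basis: 24
  phase2:
    family: bspline_degree3
    n_basis: 11
  phase3:
    family: bspline_degree3
    n_basis: 40
  phase4:
    family: bspline_degree3
    n_basis: 5
  phase5:
    family: bspline_degree3
    n_basis: 8
temperature:
  phase1:
    family: polynomial
    n_basis: 1
  phase2:
    family: polynomial
    n_basis: 1
  phase3:
    family: polynomial
    n_basis: 1
  phase4:
    family: polynomial
    n_basis: 1
  phase5:
    family: polynomial
    n_basis: 1
volume:
  phase1:
    family: polynomial
    n_basis: 2
  phase2:
    family: polynomial
    n_basis: 2
  phase3:
    family: polynomial
    n_basis: 2
  phase4:
    family: polynomial
    n_basis: 2
  phase5:
    family: polynomial
    n_basis: 2
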