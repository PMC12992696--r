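# Paper-profile fixture specifications.
#
# Each fixture is a 1,000-frame synthetic trajectory whose single driven
# target realizes the stated ground-truth fraction exactly (satisfying
# frames are a seeded permutation prefix, so e.g. 0.70 over 1000 frames is
# exactly 700 frames inside the geometric criterion).  The fractions are the
# per-system headline statistics of the study conditions:
#   trans1_thr160        indole N1-H ... Thr160(3.37) H-bond, 70%
#   trans1_asp155        protonated amine ... Asp155(3.32) salt bridge, 99%
#   trans1_asp231        methoxy O1 ... Asp231(5.35) backbone H-bond, 43%
#   cis1_rmsdi           indole-core RMSD_i < 2 A pose fraction, 75%
#   trans2_rmsdi         indole-core RMSD_i < 2 A pose fraction, 78%
#   cis2_thr160_active   methoxy ... Thr160(3.37) H-bond, active state, 66%
fixtures:
  trans1_thr160:
    n_frames: 1000
    seed: 42
    template: inactive
    targets:
      hb_indole_thr337:
        kind: hbond
        donor: {resnum: 900, name: N1}
        hydrogen: {resnum: 900, name: HN1}
        acceptor: {resnum: 160, name: OG1}
        riders:
          - {resnum: 160, name: HG1}
        fraction: 0.70
  trans1_asp155:
    n_frames: 1000
    seed: 42
    template: inactive
    targets:
      sb_amine_asp332:
        kind: salt_bridge
        basic: {resnum: 900, name: "N"}
        acidic: {resnum: 155, name: OD1}
        fraction: 0.99
  trans1_asp231:
    n_frames: 1000
    seed: 42
    template: inactive
    targets:
      hb_methoxy_asp535:
        kind: hbond
        donor: {resnum: 231, name: "N"}
        hydrogen: {resnum: 231, name: "H"}
        acceptor: {resnum: 900, name: O1}
        fraction: 0.43
  cis1_rmsdi:
    n_frames: 1000
    seed: 43
    template: inactive
    targets:
      pose_core_rmsd:
        kind: rmsd_below
        fraction: 0.75
  trans2_rmsdi:
    n_frames: 1000
    seed: 43
    template: inactive
    targets:
      pose_core_rmsd:
        kind: rmsd_below
        fraction: 0.78
  cis2_thr160_active:
    n_frames: 1000
    seed: 44
    template: active
    targets:
      hb_methoxy_thr337:
        kind: hbond
        donor: {resnum: 160, name: OG1}
        hydrogen: {resnum: 160, name: HG1}
        acceptor: {resnum: 900, name: O1}
        fraction: 0.66
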