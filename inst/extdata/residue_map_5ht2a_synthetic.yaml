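# Ballesteros-Weinstein annotation for the synthetic 5-HT2A scaffold.
# Residue numbering follows the human 5-HT2A receptor; resnums >= 501 are
# scaffold-only marker residues (vestibule reference and TM-bundle spacers).
residues:
  - {resnum: 155, chain: A, resname: ASP, bw: "3.32", role: anchor}
  - {resnum: 156, chain: A, resname: VAL, bw: "3.33", role: hydrophobic}
  - {resnum: 159, chain: A, resname: SER, bw: "3.36", role: hydrophobic}
  - {resnum: 160, chain: A, resname: THR, bw: "3.37", role: base}
  - {resnum: 162, chain: A, resname: SER, bw: "3.39", role: na_backup}
  - {resnum: 173, chain: A, resname: ARG, bw: "3.50", role: ionic_lock_arg}
  - {resnum: 318, chain: A, resname: GLU, bw: "6.30", role: ionic_lock_glu}
  - {resnum: 322, chain: A, resname: CYS, bw: "6.34", role: tm6_ref}
  - {resnum: 120, chain: A, resname: ASP, bw: "2.50", role: na_site}
  - {resnum: 332, chain: A, resname: PHE, bw: "6.44", role: na_lid}
  - {resnum: 336, chain: A, resname: TRP, bw: "6.48", role: toggle}
  - {resnum: 380, chain: A, resname: ASN, bw: "7.49", role: na_stabilizer}
  - {resnum: 239, chain: A, resname: SER, bw: "5.44", role: polar_ser1}
  - {resnum: 242, chain: A, resname: SER, bw: "5.46", role: polar_ser2}
  - {resnum: 343, chain: A, resname: ASN, bw: "6.55", role: polar_asn}
  - {resnum: 231, chain: A, resname: ASP, bw: "5.35", role: depth_anchor}
  - {resnum: 230, chain: A, resname: LEU, bw: "", role: hydrophobic}
  - {resnum: 235, chain: A, resname: VAL, bw: "5.39", role: hydrophobic}
  - {resnum: 243, chain: A, resname: PHE, bw: "5.47", role: hydrophobic}
  - {resnum: 340, chain: A, resname: PHE, bw: "6.52", role: hydrophobic}
  - {resnum: 501, chain: A, resname: GLY, bw: "", role: vestibule}
  - {resnum: 502, chain: A, resname: GLY, bw: "", role: vestibule}
  - {resnum: 601, chain: A, resname: GLY, bw: "", role: tm}
  - {resnum: 602, chain: A, resname: GLY, bw: "", role: tm}
  - {resnum: 603, chain: A, resname: GLY, bw: "", role: tm}
  - {resnum: 604, chain: A, resname: GLY, bw: "", role: tm}
  - {resnum: 605, chain: A, resname: GLY, bw: "", role: tm}
  - {resnum: 606, chain: A, resname: GLY, bw: "", role: tm}
  - {resnum: 607, chain: A, resname: GLY, bw: "", role: tm}
  - {resnum: 608, chain: A, resname: GLY, bw: "", role: tm}
  - {resnum: 609, chain: A, resname: GLY, bw: "", role: tm}
  - {resnum: 610, chain: A, resname: GLY, bw: "", role: tm}
  - {resnum: 611, chain: A, resname: GLY, bw: "", role: tm}
  - {resnum: 612, chain: A, resname: GLY, bw: "", role: tm}
  - {resnum: 613, chain: A, resname: GLY, bw: "", role: tm}
  - {resnum: 614, chain: A, resname: GLY, bw: "", role: tm}
  - {resnum: 615, chain: A, resname: GLY, bw: "", role: tm}
  - {resnum: 616, chain: A, resname: GLY, bw: "", role: tm}
  - {resnum: 617, chain: A, resname: GLY, bw: "", role: tm}
  - {resnum: 618, chain: A, resname: GLY, bw: "", role: tm}
  - {resnum: 619, chain: A, resname: GLY, bw: "", role: tm}
  - {resnum: 620, chain: A, resname: GLY, bw: "", role: tm}
  - {resnum: 621, chain: A, resname: GLY, bw: "", role: tm}
  - {resnum: 622, chain: A, resname: GLY, bw: "", role: tm}
  - {resnum: 623, chain: A, resname: GLY, bw: "", role: tm}
  - {resnum: 624, chain: A, resname: GLY, bw: "", role: tm}
  - {resnum: 625, chain: A, resname: GLY, bw: "", role: tm}
  - {resnum: 626, chain: A, resname: GLY, bw: "", role: tm}
  - {resnum: 627, chain: A, resname: GLY, bw: "", role: tm}
  - {resnum: 628, chain: A, resname: GLY, bw: "", role: tm}
ligand:
  resname: LIG
  chain: A
  atom_roles:
    amine_n: ["N"]
    indole_nh_n: [N1]
    indole_nh_h: [HN1]
    methoxy_o: [O1]
    core: [N1, C2, C3, C3A, C4, C5, C6, C7, C7A]
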