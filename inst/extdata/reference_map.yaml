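# TraR-anchored reference for conserved-residue scoring.
#
# The anchor is a synthetic TraR-like scaffold: the nine residues that are
# highly conserved across quorum-sensing LuxR-family receptors sit at their
# literal TraR-numbering positions (six ligand-binding-cavity residues and
# three helix-turn-helix residues); the residues between the key positions
# are a fixed synthetic stand-in, not the TraR sequence. A real TraR
# sequence can be substituted via reference_map(sequence = ...).
reference:
  name: TraR_anchor_synthetic
  length: 240
  sequence: >-
    WITCFWNNMNPTPTKCLCKIKHTFAYLVKPWNAEKTKSKPKERIDNSTDLYHFDILWQHVYDKDRASYADP
    HEAQWMHKYCILQWRNRYWKTCFYPETTWQSKEVNKITQVFGGNMWPPDWHTGSTLGDVHYCLKHWIGFTD
    YDQLWVTFDNVKSKFFPVNEALFYQFSPQNTLKLQETYNLKQFMCGANHDTQVFMDMWHYYLCMTHDPLGY
    TPCCMQCTPCVERTCERHVDNIITWKQ
key_positions:
  - {pos: 57, consensus: "W", domain: ligand_binding}
  - {pos: 61, consensus: "Y", domain: ligand_binding}
  - {pos: 70, consensus: "D", domain: ligand_binding}
  - {pos: 71, consensus: "P", domain: ligand_binding}
  - {pos: 85, consensus: "W", domain: ligand_binding}
  - {pos: 113, consensus: "G", domain: ligand_binding}
  - {pos: 178, consensus: "E", domain: hth}
  - {pos: 182, consensus: "L", domain: hth}
  - {pos: 188, consensus: "G", domain: hth}
motifs:
  canonical: WYDPWG
  pluR: TYDQCS
  pauR: TYDQYI
# Neighborhood-rule accessions (the survey sees Pfam domains, not gene
# names). pip: proline iminopeptidase, alpha/beta-hydrolase fold family.
# sdia_context: ABC-transporter + response-regulator context of enteric
# SdiA-like solos.
pip_pfam: PF00561
sdia_context_pfams: [PF00005, PF00072]
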