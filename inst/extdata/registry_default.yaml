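dna_fraction: 0.08
species:
- name: 23S
  rna_class: rRNA
  length_nt: 2904.0
  mass_fraction: 0.5
  acp3u_in_anticodon_region: no
  is_spike_marker: no
- name: 16S
  rna_class: rRNA
  length_nt: 1542.0
  mass_fraction: 0.27
  acp3u_in_anticodon_region: no
  is_spike_marker: no
- name: 5S
  rna_class: rRNA
  length_nt: 120.0
  mass_fraction: 0.03
  acp3u_in_anticodon_region: no
  is_spike_marker: no
- name: tRNA
  rna_class: tRNA
  length_nt: 76.0
  mass_fraction: 0.16
  acp3u_in_anticodon_region: no
  is_spike_marker: no
- name: other
  rna_class: other
  length_nt: 200.0
  mass_fraction: 0.04
  acp3u_in_anticodon_region: no
  is_spike_marker: no
trna_members:
- name: argVYZQ
  length_nt: 76.0
  pool_share: 0.0998
  acp3u_in_anticodon_region: yes
  is_spike_marker: no
- name: ileTUV
  length_nt: 76.0
  pool_share: 0.0998
  acp3u_in_anticodon_region: yes
  is_spike_marker: no
- name: leuPQVT
  length_nt: 76.0
  pool_share: 0.0998
  acp3u_in_anticodon_region: no
  is_spike_marker: no
- name: leuU
  length_nt: 76.0
  pool_share: 0.0998
  acp3u_in_anticodon_region: no
  is_spike_marker: no
- name: hisR
  length_nt: 76.0
  pool_share: 0.0998
  acp3u_in_anticodon_region: no
  is_spike_marker: no
- name: valT
  length_nt: 76.0
  pool_share: 0.0998
  acp3u_in_anticodon_region: no
  is_spike_marker: no
- name: gltTUVW
  length_nt: 76.0
  pool_share: 0.0998
  acp3u_in_anticodon_region: no
  is_spike_marker: no
- name: asnTUVW
  length_nt: 76.0
  pool_share: 0.0998
  acp3u_in_anticodon_region: no
  is_spike_marker: no
- name: tyrTV
  length_nt: 76.0
  pool_share: 0.0998
  acp3u_in_anticodon_region: no
  is_spike_marker: no
- name: serV
  length_nt: 93.0
  pool_share: 0.0998
  acp3u_in_anticodon_region: no
  is_spike_marker: no
- name: selC
  length_nt: 95.0
  pool_share: 0.002
  acp3u_in_anticodon_region: no
  is_spike_marker: yes
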