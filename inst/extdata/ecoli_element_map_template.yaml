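# Approximate element-map template for an E. coli 70S ribosome.
#
# Chain identifiers are accession specific: edit the `chain:` fields to
# match your structure file before use (e.g. for 5we4-style depositions the
# 16S rRNA, 23S rRNA and 5S rRNA sit on their own chains and every protein
# on its own chain).
#
# The rRNA domain boundaries below are APPROXIMATE transcriptions of the
# classical secondary-structure domain architecture (16S: 5', central,
# 3'-major, 3'-minor; 23S: domains I-VI by nucleotide number). They are
# meant as a starting point and should be curated against the numbering of
# the deposited model. The 23S "domain 0" core is discontinuous in
# sequence and cannot be expressed as a single interval; assign it
# explicitly if your analysis distinguishes it.
#
# Ranges use author residue numbering, inclusive.
elements:
  - name: 16S-5p
    category: rRNA_domain
    subunit: 30S
    chain: "2"
    ranges: [[1, 556]]
  - name: 16S-CD
    category: rRNA_domain
    subunit: 30S
    chain: "2"
    ranges: [[557, 918]]
  - name: 16S-3pM
    category: rRNA_domain
    subunit: 30S
    chain: "2"
    ranges: [[919, 1396]]
  - name: 16S-3pm
    category: rRNA_domain
    subunit: 30S
    chain: "2"
    ranges: [[1397, 1542]]
  - name: 23S-D1
    category: rRNA_domain
    subunit: 50S
    chain: "1"
    ranges: [[1, 561]]
  - name: 23S-D2
    category: rRNA_domain
    subunit: 50S
    chain: "1"
    ranges: [[562, 1269]]
  - name: 23S-D3
    category: rRNA_domain
    subunit: 50S
    chain: "1"
    ranges: [[1270, 1646]]
  - name: 23S-D4
    category: rRNA_domain
    subunit: 50S
    chain: "1"
    ranges: [[1647, 2014]]
  - name: 23S-D5
    category: rRNA_domain
    subunit: 50S
    chain: "1"
    ranges: [[2015, 2625]]
  - name: 23S-D6
    category: rRNA_domain
    subunit: 50S
    chain: "1"
    ranges: [[2626, 2904]]
  - name: 5S
    category: rRNA_domain
    subunit: 50S
    chain: "3"
    ranges: all
  # Proteins: one entry per chain, whole chain. Examples:
  - name: L2
    category: rprotein
    subunit: 50S
    chain: "C"
    ranges: all
  - name: S12
    category: rprotein
    subunit: 30S
    chain: "l"
    ranges: all
  - name: mRNA
    category: mRNA
    subunit: none
    chain: "x"
    ranges: all
  - name: tRNA-P
    category: tRNA
    subunit: none
    chain: "y"
    ranges: all
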