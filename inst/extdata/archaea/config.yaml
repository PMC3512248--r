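# Event-detection configuration for the bundled archaeal fixture tables.
clade_table: clades.tsv
linkage: linkage.tsv
dup_flags: dup_flags.tsv
categories: categories.tsv
clade_labels: clade_labels.tsv
support_threshold: 70
max_gap_orfs: 1
domain_age: 3.5
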