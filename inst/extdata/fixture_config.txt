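# Desk-scale demonstration configuration for `mybfam run-all`.
# Analysis thresholds keep their classic defaults except min_span, which is
# scaled to the small synthetic chromosomes (genome-scale value: 600000).
out_dir: mybfam_fixture_run
simulate: TRUE
prefix: MYB
bit_threshold: 30
min_separation: 5
coverage: 0.8
tandem_identity: 80
max_evalue: 0.0000000001
min_score: 100
segmental_identity: 90
min_span: 10000
min_anchors: 2
max_gap: 10000
fc_threshold: 1
alpha: 0.05
n_bootstrap: 100
tree_max_taxa: 10
promoter_length: 1500
expression_k: 5
seed: 1
genome.chromosome_length: 150000
genome.n_family_genes: 30
genome.n_background_genes: 40
genome.n_tandem_clusters: 2
genome.tandem_cluster_size: 2,3
genome.n_segmental_blocks: 1
genome.segmental_block_genes: 3
genome.segmental_span: 20000
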