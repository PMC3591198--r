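aad5b6ce52a453d83eb0fbf52950551d  panel_genes.tsv
aed21d16e335ce75174b4d129d28996f  cohort_runs.tsv
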