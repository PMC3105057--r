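# Distribution of the curated UniProtKB antifreeze-protein sequences across
# organism groups (independent evaluation cohort).
organism	n
Algae	17
Bacteria	101
Fish	123
Insects	105
Plants	23
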