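culture,enzyme,observed_length_bp,clone_id,expected_length_bp,annotation,similarity
AE/AE-13D,HhaI,337,AE/AE-13D-05-001,341,Hyphomicrobium sp. NDB2Meth4 (KY621474),99
AE/AE-13D,MspI,398,AE/AE-13D-05-001,403,Hyphomicrobium sp. NDB2Meth4 (KY621474),99
AE/AE-13B,HhaI,352,AE/AE-13B-07-011,355,Propioniferax sp. P7 (EU109728),99
AE/AE-13B,MspI,154,AE/AE-13B-07-011,158,Propioniferax sp. P7 (EU109728),99
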