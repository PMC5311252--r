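>hsa-miR-372-3p MIMAT0000724 Homo sapiens miR-372-3p
AAAGUGCUGCGACAUUUGAGCGU
>hsa-miR-373-3p MIMAT0000726 Homo sapiens miR-373-3p
GAAGUGCUUCGAUUUUGGGGUGU
>hsa-miR-519c-3p MIMAT0002832 Homo sapiens miR-519c-3p
AAAGUGCAUCUUUUUAGAGGAU
>hsa-miR-520c-3p MIMAT0002846 Homo sapiens miR-520c-3p
AAAGUGCUUCCUUUUAGAGGGU
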