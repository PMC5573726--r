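>hsa-miR-34a-5p MIMAT0000255
UGGCAGUGUCUUAGCUGGUUGU
>hsa-miR-34a-3p MIMAT0004557
CAAUCAGCAAGUAUACUGCCCU
>hsa-miR-34b-5p MIMAT0000685
UAGGCAGUGUCAUUAGCUGAUUG
>hsa-miR-34b-3p MIMAT0004676
CAAUCACUAACUCCACUGCCAU
>hsa-miR-34c-5p MIMAT0000686
AGGCAGUGUAGUUAGCUGAUUGC
>hsa-miR-34c-3p MIMAT0004677
AAUCACUAACCACACGGCCAGG
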