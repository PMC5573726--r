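>hsa-mir-34a MI0000268 Homo sapiens miR-34a stem-loop
GGCCAGCUGUGAGUGUUUCUUUGGCAGUGUCUUAGCUGGUUGUUGUGAGCAAUAGUAAGG
AAGCAAUCAGCAAGUAUACUGCCCUAGAAGUGCUGCACGUUGUGGGGCCC
>hsa-mir-34b MI0000742 Homo sapiens miR-34b stem-loop
GUGCUCGGUUUGUAGGCAGUGUCAUUAGCUGAUUGUACUGUGGUGGUUACAAUCACUAAC
UCCACUGCCAUCAAAACAAGGCAC
>hsa-mir-34c MI0000743 Homo sapiens miR-34c stem-loop
AGUCUAGUUACUAGGCAGUGUAGUUAGCUGAUUGCUAAUAGUACCAAUCACUAACCACAC
GGCCAGGUAAAAAGAUU
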