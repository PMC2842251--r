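>hsa-let-7d mature let-7d
AGAGGUAGUAGGUUGCAUAGUU
>mmu-let-7d mature let-7d (mouse)
AGAGGUAGUAGGUUGCAUAGUU
>hsa-miR-31 synthetic stand-in, 3' region constrained to published motifs
AGGCAAGAUGCUGGCAUAGCU
>mmu-miR-31 synthetic stand-in (mouse counterpart)
AGGCAAGUUGCUGGCAUAGCU
>hsa-miR-363 synthetic stand-in, 3' region constrained to published motifs
AAUUGCACGGUAUCCAUCUGUA
>mmu-miR-363 synthetic stand-in (mouse counterpart)
AAUUGCACGGUAUCCAUCUGUA
>hsa-miR-199a-3p synthetic stand-in, 3' region constrained to published motifs
ACAGUAGUCUGCACAUUGGUUA
>mmu-miR-199a-3p synthetic stand-in (mouse counterpart)
ACAGUAGUCUGCACAUUGGUUA
>hsa-miR-132 synthetic stand-in, 3' region constrained to published motifs
UAACAGUCUACAGCCAUGGUCG
>mmu-miR-132 synthetic stand-in (mouse counterpart)
UAACAGUCUACAGCCAUGGUCG
>hsa-miR-505 synthetic stand-in
CGUCAACACUUGCUGGUUUCCU
>mmu-miR-505 synthetic stand-in (mouse counterpart)
CGUCAACACUUGCUGGUUUCCU
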