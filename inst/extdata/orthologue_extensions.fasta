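>mammal_sp1_synthetic clade=mammal
XLEATNPKSLESVSAGCRL
>mammal_sp2_synthetic clade=mammal
XLEATNPKSLESVSAGCRL
>mammal_sp3_synthetic clade=mammal
XLEATNPKSLESVSAGCRL
>mammal_sp4_synthetic clade=mammal
XLEATNPKALESVSAGCRL
>mammal_sp5_synthetic clade=mammal
XLEATSPKSLESVSAGCRL
>mammal_sp6_synthetic clade=mammal
XLEATNPKSLESISAGCRL
>nonmammal_sp1_synthetic clade=non-mammal-vertebrate
XLEANNPKSLESVSAGSRL
>nonmammal_sp2_synthetic clade=non-mammal-vertebrate
XLEANNPKSLESVSAGSRL
>nonmammal_sp3_synthetic clade=non-mammal-vertebrate
XLEANNPKTLESVSAGSRL
>nonmammal_sp4_synthetic clade=non-mammal-vertebrate
XLEANNPKSLDSVSAGSRL
>nonmammal_sp5_synthetic clade=non-mammal-vertebrate
XLHANNPKSLESVSAGSRL
>amphibian_sp1_synthetic clade=other
XLEANNPKSLESVSAGAKL
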