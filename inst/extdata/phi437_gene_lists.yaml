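# Functional ORF lists for phage phi437, as printed in the source study's
# genome description (ranges use "-" and expand inclusively).
morphogenesis: "orf3, 5, 23, 28, 31, 48, 51, 54, 56, 57, 62, 70-77, 79, 80, 82, 84-88, 90"
tail: "orf3, 23, 31, 54, 56, 57, 62, 70, 71, 73, 75, 76, 77, 79, 80"
baseplate: "orf51, 53, 72, 74"
packaging_and_capsid: "orf84-90, 48, 5"
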