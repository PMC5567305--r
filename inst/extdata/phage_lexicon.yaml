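# Keyword lexicon mapping annotation text to phage functional categories.
# Matching is case-insensitive, longest-match-wins; ties broken by the
# category order in this file. Every keyword belongs to exactly one category.
# Categories flagged specific: true identify a concrete phage function and are
# eligible for best-hit-based category upgrades; generic phage words are not.
categories:
  integrase:
    specific: true
    keywords: [integrase, recombinase xerc, recombinase xerd]
  terminase:
    specific: true
    keywords: [terminase]
  portal:
    specific: true
    keywords: [portal]
  major_capsid:
    specific: true
    keywords: [major capsid, capsid]
  tail_sheath:
    specific: true
    keywords: [tail sheath, sheath]
  tape_measure:
    specific: true
    keywords: [tape measure, tape-measure]
  baseplate:
    specific: true
    keywords: [baseplate, base plate]
  tail:
    specific: true
    keywords: [tail fiber, tail fibers, tail tube, minor tail, tail protein,
               tail component, tail length, tail/dna circulation, head-tail,
               tail]
  lysin:
    specific: true
    keywords: [lysozyme, endolysin, holin, lysin]
  repressor:
    specific: true
    keywords: [repressor, ci repressor]
  antirepressor:
    specific: true
    keywords: [antirepressor]
  replication:
    specific: true
    keywords: [replication protein, dna replication, replisome]
  other_phage:
    specific: false
    keywords: [prophage, phage, virion, mu-like, myoviridae, siphovirus,
               siphoviridae, podoviridae, virus]
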