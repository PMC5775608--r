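---
title: "Methods: reconstructing ERV colonization histories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reconstructing ERV colonization histories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Endogenous retroviruses (ERVs) are germ-line copies of ancient retroviral
integrations, inherited Mendelianly. Because an integration happens once, at
one genomic position, its presence or absence at the *orthologous* position
across related species is a near-perfect cladistic character: present in
every descendant of the lineage that acquired it, absent (as a clean
pre-insertion "empty site") everywhere else. Comparing one ERV group across
a primate clade therefore reads out the group's colonization history —
which branches acquired how many copies, by which mechanism, and what
happened to them afterwards.

`ervography` implements that comparative procedure end-to-end:

1. **Discovery** — a seed-and-extend similarity search (exact k-mer index,
   diagonal chaining, ungapped X-drop extension) finds candidate loci of a
   query element in each genome.
2. **Structural classification** — each locus is classified as a
   *provirus* (two complete LTRs, each U3–R–U5, flanking the internal
   gag/pol/env region), an *L1-processed pseudogene* (a copy created by L1
   retrotransposition of an element transcript: its 5' LTR lacks U3, its 3'
   LTR lacks U5, and it carries a poly-A tail and target-site duplications),
   a *solitary LTR* (the single LTR left behind when LTR–LTR homologous
   recombination deletes the internal region and one LTR), or *undefined*
   (internal sequence without LTR-derived termini).
3. **Orthology** — each locus is anchored by 500 nt of flanking sequence on
   each side; a concordant flank pair in another genome identifies the
   orthologous site and its content is read as `full`, `solitary_ltr`,
   `empty`, or `unresolved`. Loci are clustered across species at their
   anchors in a reference genome (the tree's first species), the same
   back-mapping protocol the original analysis used, with reciprocity
   audited in both directions and direct cross-mapping as fallback for
   loci that cannot be anchored.
4. **Dollo dating** — an insertion is gained once; its formation branch is
   the stem of the LCA of all species where it is present (a solitary LTR
   counts as presence: the element was there, only its internal portion was
   lost). Absences below that branch are recorded as losses.
5. **Recombination inference** — within a cluster mixing full and solitary
   states, each maximal all-solitary clade with a full sister is explained
   by one LTR–LTR recombination on its stem. Processed pseudogenes are
   excluded: their truncated LTRs lack the homology this recombination
   needs.
6. **Comparative statistics** — majority-rule consensus of proviral copies,
   CpG-stripped p-distances, Kimura 2-parameter distances, neighbor-joining
   trees with bootstrap support, and windowed dot-plots.

A forward simulator plants colonization histories with complete ground
truth, so every stage is validated against known answers.

## The simulator and what it emulates

`simulate_erv_history()` evolves one ancestral background genome down a
dated species tree. Its defaults are the study conditions the package is
validated under:

* **Tree** — `default_catarrhini_tree()`: human, chimpanzee, gorilla,
  orangutan, gibbon, rhesus with split ages 7, 10, 17, 20, 30 MYa and a
  13 MY stem above the crown (back to 43 MYa). These are the round
  published divergence ages for this clade.
* **Element** — `erv_model()`: a 780 nt LTR partitioned U3 455 | R 70 |
  U5 255, and a 7000 nt internal region segmented pre-gag 1900 | gag 1500 |
  pol 2400 | env 1200, matching the published element's overall geometry
  (a ~9.5 kb provirus with a "pre-gag" region between the 5' LTR and gag).
  Gene segments are generated as intact ORFs so putein extraction has a
  defined truth. Master sequences are i.i.d. random DNA: real nucleotide
  composition is not emulated, which makes spurious self-hits essentially
  impossible and keeps discovery honest.
* **Temporal profile** — per-MY insertion intensity peaks on the crown stem
  and is 10× lower on all crown branches (`default_insertion_rates()`),
  emulating a major colonization wave before the deepest split of the
  sampled species followed by a long decline. The paper-scale condition
  used in validation expects 150 events.
* **Mechanism mix** — each event is a provirus with probability 1/3, an
  L1-processed pseudogene otherwise (the 2:1 pseudogene:provirus ratio
  reported for this group). Pseudogene copies are emitted with the
  truncated-LTR signature and a 12 nt poly-A tail.
* **Integration mechanics** — every insertion duplicates a 4 nt target
  site. Insertion positions come from a pre-sampled pool of ancestral
  positions kept at least `2*flank_len + merge_gap + 1000` nt apart, so
  loci never nest, flanks never overlap a neighbouring element, and
  orthologous positions never collide across lineages. This follows the
  locus-level bookkeeping of the published analysis, which treats loci as
  independent.
* **Substitutions** — every site accumulates Poisson(rate × branch length)
  substitution events under a transition-biased two-class model
  (κ = 2 by default), applied sequentially so multiple hits and
  back-substitutions arise naturally. The default rate is 2.2e-3
  substitutions/site/MY, a standard primate neutral rate; the source
  analysis cites no rate, so this is an explicit package choice.
* **Later events** — planted proviruses can collapse to solitary LTRs on a
  strictly descendant branch (`n_recomb`), and loci can be deleted per
  species (`p_del`). A deletion restores a clean empty site; the truth
  table remembers it as `deleted_region`, but the mapper — correctly — sees
  `empty`. This is exactly why Dollo dating degrades when a basal witness
  is deleted, and the package's robustness checks measure that degradation
  rather than hide it.

Two simplifications are deliberate: insertions take effect at the top of
their branch (no within-branch event times), and the two target-site
duplication copies are realised from the same background bases and so stay
identical over time. Neither affects any quantity the package reports;
both keep coordinate bookkeeping exact. Indels, selection, gene
conversion, segmental duplication and nested insertion are out of scope, so
passing the synthetic validation says nothing about robustness to assembly
artefacts or nested repeats in real genomes — the flank-anchoring and
N-run/`unresolved` rules are the designed mitigations there.

## Discovery parameters

The search is a deliberate stand-in for BLAT at desk scale: its contract is
recall at the divergences in play (≤ ~30%), not BLAT parity.

* `seed_k = 12`: at 13% flank divergence (human–rhesus paths) an intact
  12-mer survives at ~19% of positions, leaving ~90 seeds per 500 nt
  flank — chaining is saturated. Random 12-mer noise in a 12 Mb genome is
  removed by requiring 2 seeds per chain and 60% identity over ≥ 100 nt.
* `min_hit_identity = 0.6`: permissive on purpose, so distant relatives of
  the query (the "ERV-like" tier at ~63% identity) remain discoverable and
  can be triaged downstream rather than silently lost.
* `merge_gap = 2000` nt merges hits split by diverged internal stretches;
  the simulator's 4 kb minimum locus spacing guarantees distinct loci are
  never bridged.
* Extension is ungapped with an X-drop of 20 on a ±32-diagonal band. The
  simulator plants no indels by default, so banded-gapped extension would
  buy nothing in validation; at the divergences involved, ungapped X-drop
  extension recovers ≥ 95% of each planted interval.

## Orthology parameters

* Flank concordance: both flanks must align at ≥ 75% identity over ≥ 300 of
  the 500 nt, on the same contig and strand, in the correct order — the
  source protocol requires 500 nt flanks but quantifies no acceptance
  threshold, so these are explicit config values.
* Empty sites allow ≤ 50 nt of residue (plus one TSD): pre-insertion
  alleles are never restored bit-exactly in real genomes.
* An interval overlapping a ≥ 10 nt N-run is `unresolved`, mirroring the
  caveat that absences in poor assemblies are not evidence. Flanks mapping
  to different contigs are likewise `unresolved`.
* Cell filling: species with a discovered locus contribute their
  classification; other species receive the majority state of the cluster
  members' mappings, with deterministic tie priority full > solitary >
  empty > unresolved.

## Numerical and procedural choices

* **Alignment** — pairwise alignment is Needleman–Wunsch/Smith–Waterman
  with match +1, mismatch −1, gap open 4, gap extend 1 (Biostrings).
  Multiple alignment uses MAFFT, the same aligner family the original
  protocol used; `progressive_msa()` verifies losslessness of every row.
* **CpG stripping** — a column is removed if it is the C or the G of a CpG
  dinucleotide in *either* aligned row, testing adjacency across gaps.
  "Removal of CpG dinucleotides" is underspecified in the source; the
  either-row rule is the conservative reading and is applied symmetrically.
* **K2P** — `d = -½ ln((1−2P−Q)√(1−2Q))`; a non-positive logarithm argument
  is reported as `Inf` with a saturation flag, and saturated taxa are
  dropped (with a warning) before neighbor joining, never silently.
* **NJ determinism** — labels are canonicalised to alphabetical order
  before joining so ties always break identically; negative branch lengths
  are clamped to zero with a warning.
* **LTR dating** — age = d_K2P/(2 × rate); the binomial (Clopper–Pearson)
  95% CI on the mismatch proportion is pushed through the K2P correction,
  preserving the observed transition:transversion split. Estimates from
  alignments < 200 nt or with d > 0.3 are flagged unreliable — at such
  divergences this dating method is known to be unstable.
* **Consensus** — strict-majority gap columns are deleted; residue ties
  emit N; support is the emitted residue's row frequency.
* **Classification order** — solitary LTR → provirus → processed
  pseudogene → undefined. The ambiguous "one complete, one truncated LTR"
  case resolves to processed pseudogene with an audit flag, because L1
  truncation is one-sided in practice.
* **Dot-plots** — window 100 nt, highlight at ≥ 50% identity (the published
  figure parameters); the step defaults to 25 nt, which the source figure
  does not state.
* **Seeds** — every stochastic stage takes one seed; the simulator splits
  its stream internally, and bootstrap replicates derive from the seed plus
  replicate index. Output bundles contain no timestamps by default, so
  same-seed runs are byte-identical (the manifest can record wall-clock
  time on request).

## Problem sizes used in validation

The packaged checks run a 6-species clade with 150 expected insertions
(~12 Mb per genome, auto-sized to 10× the planted sequence), once without
and once with 5% per-species deletion; module tests use a miniature element
(120 nt LTR, 600 nt internal) on 0.4 Mb genomes that exercises every code
path at a fraction of the cost. These sizes are the package's validation
conditions; the code itself has no hard-coded scale.

## Known limitations

* Orthology anchors on flank similarity only; orthology through
  chromosomal rearrangement breakpoints is out of scope.
* The locus search does not stitch spliced or trans-located hits across
  contigs.
* Putein extraction is a three-frame ORF scan; it does not reconstruct
  frameshift-spliced proteins or motif-level features (PBS, PPT).
* Maximum-likelihood tree search is intentionally replaced by NJ +
  bootstrap: every validated property concerns topology recovery, which NJ
  achieves deterministically at desk scale.
* The simulator's background is unstructured random DNA; repeat-rich real
  genomes will produce `unresolved` calls and discovery ambiguities this
  validation cannot measure.
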