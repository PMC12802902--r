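---
title: "Methods: noncanonical proteoform discovery and PTM landscapes with proteomapr"
author: "proteomapr authors"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Methods: noncanonical proteoform discovery and PTM landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proteomapr)
```

# Scope and model

Standard proteomic database searches only see peptides present in the
canonical proteome FASTA. proteomapr builds the *custom search space* that
makes four classes of noncanonical proteoforms visible at the peptide level,
and provides the post-search analyses that turn identifications into
biology:

1. **N-terminal extensions from alternative translation-initiation sites
   (TIS).** Ribosomes can initiate at AUG or at the near-cognate codons ACG,
   CUG, GUG and UUG in the 5' UTR. For every such codon that is in frame
   with the annotated CDS and has no intervening in-frame stop, the package
   emits the extended protein. The initiator residue is always methionine
   — initiator tRNA delivers Met even at non-AUG codons — so the entry is
   `M` + translation from the codon after the TIS through the annotated
   protein, which is therefore a strict suffix of the entry.
2. **Upstream open reading frames (uORFs).** Every start-codon occurrence in
   any of the three frames of the 5' UTR opens a candidate ORF translated to
   its first stop codon; ORFs reaching into the CDS are kept but flagged
   CDS-overlapping. In-frame TIS are therefore a subset of the three-frame
   scan: the same upstream codon legitimately appears once as an
   `nterm_extension` entry and once as a CDS-overlapping `uorf` entry, and a
   peptide contained in both is reported as multi-category by the
   classifier.
3. **Translational readthrough.** Decoding a stop codon (UAG, UAA, UGA) as a
   sense codon C-terminally extends the protein into the 3' UTR until the
   next in-frame stop. Because a search engine needs concrete sequences, the
   builder emits 20 entries per transcript — annotated protein + substituted
   residue + extension tract — rather than one wildcard entry. Each entry
   records the stop codon and the minimum Hamming distance from that codon
   to any codon of the substituted residue, the quantity used downstream to
   separate plausible single-nucleotide recodings (UGA→UGG, tryptophan) from
   events that would need two or three simultaneous changes.
4. **Novel splice junctions.** For exon–exon boundaries of assembled
   transcripts that are absent from the annotated junction set, a window of
   up to 96 nt on each side of the junction (clipped to the CDS and snapped
   to its frame; all three frames for non-coding transcripts) is translated,
   long enough to cover tryptic peptides of up to ~32 residues crossing the
   boundary.

Around this search space the package implements in-silico tryptic digestion
(cleavage after K/R, not before P, up to two missed cleavages by default,
with optional N-terminal Met excision for small second residues),
monoisotopic mass arithmetic (peptide, b/y fragment and immonium masses),
PSM post-filtering, PTM landscape summaries, missing-protein evidence
reporting, and mRNA–protein abundance integration.

# Post-search filtering and the modification registry

Search engines that consider many variable modifications produce
identifications whose spectra deserve an extra quality gate. The package
applies a **fragment-ion coverage filter**: the number of annotated residues
divided by the peptide length must be *strictly greater than* 0.5, so a
record at exactly half coverage is rejected. Upstream tables supply
`annotated_residues` as a count; when a caller needs to derive it from
matched fragments, the operational rule is that residue *i* counts as
annotated when a matched b/y boundary falls on either backbone bond
flanking it.

The **modification registry** holds 39 classes split into 27 biologically
relevant PTMs (acetylation of the protein N terminus and of K/S/T,
phosphorylation of S/T/Y, mono/di/tri-methylation of K, methylation of
R/H/E, hydroxylation of P/K, the lysine acylations propionyl/butyryl/
crotonyl/lactyl/succinyl/malonyl/glutaryl/2-hydroxyisobutyryl, the GlyGly
ubiquitin remnant, citrullination and Nε-formylation) and 12 post-isolation
artifacts (oxidation and dioxidation of M and W, deamidation of N/Q,
carbamidomethylation, carbamylation, pyro-Glu formation and N-terminal
formylation). The registry ships as an editable TSV
(`inst/extdata/modifications.tsv`) with standard monoisotopic deltas; the
27 + 12 partition is asserted at load time and can be relaxed for
user-edited registries. Delta masses feed the mass layer directly: the
immonium ion of methylated histidine — the diagnostic used to validate
histidine-methylation sites — computes to

```{r immonium}
round(immonium_mz("H", "Methyl (H)"), 2)
```

**PTM summaries** operate on *sites*, the triple (protein, protein
position, modification name), counted once however many PSMs report them.
`site_frequency()` tabulates sites per residue and modification;
`protein_ptm_summary()` counts per protein the distinct modified positions
and distinct modification names over biological PTMs only — the two axes
are independent, since one lysine can carry methyl, trimethyl and several
acyl marks.

**Readthrough plausibility** keeps identified readthrough events whose
recoded stop codon is one nucleotide away from a codon of the substituted
residue and reports the kept events per stop codon. **Missing-protein
evidence** counts, for proteins of existence level PE2 or worse, the
distinct peptides unique to one parent; uniqueness is assessed at the
parent-transcript level with I/L collapsed, because all 20 readthrough
variants of a transcript contain its annotated protein and must not destroy
uniqueness.

# Expression integration

Per-gene mRNA–protein agreement is measured by Spearman rank correlation
across cell types, using pairwise-complete observations, for genes with
both layers observed in at least 25% of cell types (the boundary is
inclusive). Rank correlation was chosen because abundances span orders of
magnitude and no distributional form is assumed; a flag switches to Pearson
on log values. "Significant positive correlation" is operationalized as a
positive coefficient with two-sided p < 0.05. Protein replicates are
averaged per cell type before analysis; missing protein values stay missing
(no zero imputation by default).

Cell-type enrichment applies the standard thresholds — Benjamini–Hochberg
adjusted p < 0.01 and |log2 fold change| > 1, after removing genes below
0.01 CPM everywhere — on top of a one-vs-rest Wilcoxon rank-sum test with a
pseudocount of 0.01 on group means. The Wilcoxon test is a deliberate,
clearly-labelled lightweight surrogate for a count-model differential test;
`apply_enrichment_thresholds()` applies the same thresholds to externally
computed fold-change/p tables. Because the fold-change criterion is
two-sided, a gene enriched in group A is also legitimately called (as
depleted) in the complementary comparisons; recovery on synthetic data is
therefore evaluated per gene, not per (gene, group) pair.

# The synthetic-data generator

The generator emulates every input the pipeline consumes — genome FASTA,
annotation GTF, novel-transcript GTF, PSM TSV, protein-existence table and
paired expression matrices — with a machine-readable truth ledger, so that
recovery can be asserted exactly.

*Sequence design.* 5' UTR background is drawn from the {A, C} alphabet,
which cannot contain a start codon (all five permitted starts carry G or T)
or a stop codon in any frame; planted inserts use codons chosen so no start
codon arises across codon boundaries either (uORF stops are restricted to
UAA/UAG, and a fixed CC linker precedes each insert), and the generator
asserts after assembly that the start codons found in each UTR are exactly
the planted ones. CDS bodies are uniform sense codons — no attempt is made
to model codon-usage realism, which is irrelevant to the correctness of the
machinery. 3' UTRs start with a sense-codon extension tract followed by a
planted stop, so every complete transcript has a defined readthrough
extension. Novel junction transcripts extend an acceptor exon 5' by an
inserted coding segment placed after an arginine codon, making the inserted
peptide tryptically observable. Designed transcripts plant the diagnostic
peptides (an ACG-initiated extension yielding MESDPER, a uORF yielding
VLHLLSVAR after Met excision, a junction insert SQQTLDTTSSVPAPK, and a UGA
readthrough whose tryptophan entry carries DLWLVSSR), a multi-PTM showcase
protein carrying 26 modified sites across 13 modification types with one
lysine bearing six acyl/methyl marks, a missing protein with two unique
peptides, and a pair of proteins sharing a tryptic segment.

*Defaults as study conditions.* 300 transcripts with TIS/uORF/junction/
incomplete-CDS rates of 0.10/0.10/0.05/0.02; 28 cell types; 5,000 genes
with 200 planted group-specific genes at a log2 effect of 3; latent
(Gaussian-copula) mRNA–protein correlation 0.4; 50 genes planted below and
10 exactly at the 25% joint-coverage boundary; dioxidation planted at 394
tryptophan and 102 methionine sites — a 10-fold scale-down of the
3,942 : 1,018 site counts that motivated the tryptophan-oxidation analysis,
because a 300-protein toy proteome cannot host ~5,000 distinct W/M sites;
the ratio is preserved. The root seed is 17 and all randomness flows from
it, making every emitted file byte-identical across runs. Tests of the
correlation machinery use 2,000 genes with no planted enrichment so the
latent correlation is unperturbed.

*What passing recovery shows — and does not.* The generator plants events
under the same grammar the builder recognises, so 100% recovery
demonstrates the correctness of coordinate arithmetic, frame handling,
strand handling and classification logic, not performance on real data:
real 5' UTRs contain incidental near-cognate codons (the builder will emit
them; whether they are translated is an experimental question), real PSM
tables carry search-engine score noise the generator does not model, and
real mRNA–protein correlation is not a single homogeneous latent value.

# Numerical and design choices

- Coordinates are 0-based half-open internally; GTF I/O converts at the
  boundary. The CDS span includes the stop codon; `stop_codon` GTF features
  are merged on import. Transcripts whose CDS length is not a multiple of 3
  are flagged and excluded from database building; transcripts without a
  terminal stop are kept for TIS/uORF building but excluded from
  readthrough, which is undefined without a stop.
- U and T are interchangeable on input; sequences are held as DNA
  internally and codons are displayed in RNA letters.
- Masses are standard monoisotopic values carried at full double precision;
  display rounding (2 decimals for m/z) is applied only at reporting time.
  Fragment-pair closure (b_i + y_{n−i} = peptide mass + 2 protons) is
  asserted to 1e-6 in the tests.
- Peptide length bounds default to 7–40 aa for matching; the uORF length
  floor defaults to 6 aa (long enough to yield an observable tryptic
  peptide). I/L are collapsed in novelty and uniqueness checks only — never
  at database-build time.
- The near-cognate start set {AUG, ACG, CUG, GUG, UUG} is configurable, as
  is the trypsin proline rule (`trypsin_p`), the junction window (96 nt)
  and every threshold.
- Readthrough extension length is uncapped; when the 3' UTR lacks an
  in-frame stop the extension runs to the last complete codon and the entry
  is flagged.
- Annotation completeness tags (e.g. CDS end flags carried by reference
  annotations) are not consulted; completeness is derived from the sequence
  itself (terminal stop present or not), which is the only criterion that
  matters for readthrough construction.

# Known limitations

- The enrichment test is a rank-test surrogate, not a count model; with
  very small groups its discreteness limits attainable adjusted p-values.
- Junction entries for non-coding novel transcripts are emitted in all
  three frames, which triples their search-space contribution.
- The registry's exact 39-class membership follows the modifications the
  field's studies routinely report; laboratories with a different panel
  should edit the TSV (the 27 + 12 assertion can be disabled).
- The generator's PSM tables contain no decoys and no score column; FDR
  machinery is out of scope.
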