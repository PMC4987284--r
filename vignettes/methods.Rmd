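---
title: "SomaticTx: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SomaticTx: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

SomaticTx detects and classifies the direct transcriptional consequences of
somatic mutation in cancer RNA-seq. This vignette documents the models and
algorithms, the tunable parameters and why their defaults are what they
are, the numerical and design choices made where the design was genuinely
open, and what the synthetic fixtures do and do not establish about real
data.

## Split-read junction discovery

The mapper looks for reads that span two genomic loci that are never
adjacent in the annotated transcriptome. Its stages and their contracts:

1. **Pre-filter.** A read is removed when the annotated transcriptome
   explains it: it is a substring of some spliced transcript sequence
   (this single test covers both "fully contained in an exon" and "split
   across adjacent exons"), in either orientation. Pairs with an end
   matching the mitochondrial contig and reads with two or more N bases
   are also removed. The filter is total — everything else goes on.
   The containment test runs natively against the annotation; no external
   aligner is involved.
2. **Index.** Every distinct annotated exon contributes all of its
   *wordSize* = 9 bp words with their genomic positions. Nine is the
   published operating point balancing sensitivity against index size;
   exons shorter than the word contribute nothing (warned).
3. **Shatter.** Reads are cut into *kmerSize* = 13 bp k-mers: `floor(L/k)`
   k-mers from the 5' end plus one short k-mer holding the 3' end, the
   lowest-quality part of a short read. A 75-bp read gives five 13-mers
   and a 10-mer. The scanner additionally tries the 3'-anchored k-mer
   phase (offsets `L - k, L - 2k, ...`): a breakpoint that leaves at least
   k bases on a side then always leaves an intact k-mer there, whatever
   the breakpoint's offset modulo k. This removes a blind spot of a purely
   5'-anchored grid without changing the anchor requirement.
4. **Merge and extend.** K-mer hits are matched exactly (a candidate
   position is verified base-for-base against the genome). Hits sharing a
   diagonal — same contig and strand, reference offset differences equal to
   read offset differences — merge into fragments. Fragments then grow one
   base at a time into their unmapped neighbours; a mismatch is accepted
   only when preceded, in the direction of extension, by a 2-bp perfect
   match, up to *maxMismatch* = 2 per direction. A read resolves when a
   left fragment reaches read position 0, a right fragment reaches the
   read end, and their extension ranges meet.
5. **Clean.** Where the two sides' extensions overlap (microhomology),
   every split in the overlap is equivalent at the sequence level. The
   split whose flanking dinucleotides read GT..AG — on either sense; a
   minus-strand junction reads CT..AC on the forward genome — is chosen.
   With no canonical option, or several, the placement with the leftmost
   genomic coordinate of the left locus wins, which makes the output
   deterministic. Reads that fail to resolve are retried against a
   genome-wide index with *relaxedWordSize* = 7 and a relaxed mismatch
   policy (one perfect base before a mismatch, up to 5). The genome-wide
   retry is what lets junctions into un-annotated territory — novel
   antisense exons inside introns, for instance — resolve at all.
6. **Aggregate.** Distinct breakpoint pairs become junction events with
   read support split by orientation (forward vs reverse-complement),
   distinct-read counts, splice dinucleotides, and the mean number of
   genomic bases each supporting read contributes that no other supporting
   read covers ("unique bases per read", kept as a metric only; its exact
   published semantics are not stated anywhere we could follow).

A junction must hold at least one fully exact 13-mer on each side. Reads
whose fragments admit more than one distinct resolved junction are parked
as ambiguous rather than guessed at.

Premature-polyadenylation candidates are reads whose 5' portion maps but
whose tail is a pure A run (T run at the read start for the opposite
orientation). Trailing mismatches consumed by the extension are rolled
back before the tail test, so the recorded junction position is exact
rather than shifted by forced mismatch consumption.

## Event taxonomy

Accepted junctions must be novel twice over: absent from the annotation
(no transcript's adjacent-exon splice matches the loci) and seen in the
normal-organoid background with fewer than *organoidMaxReads* = 2 reads.
The organoid table is produced by running the mapper on normal-sample
reads and keyed on GT-AG-normalized coordinates, pooled across organoids.

The decision tree for a novel junction: both loci in one transcript in
5'→3' exon order is an **exon skip** (the isoform minimizing exons lost is
reported); 3'→5' order is an **exon reusage** (tandem-duplication
signature); adjacent exons with an edge shifted off the canonical border
are an **alternative donor/acceptor** and must carry GT-AG context; skips
and reusages additionally require at least one forward and one reverse
split read, and are subcategorized by canonical vs cryptic edges. A
junction between two genes becomes a **fusion**, subclassified by whether
each side runs sense to its gene: sense/sense (same orientation, with
reading-frame prediction), sense/antisense (5'-to-5' inward pairs),
antisense/sense (3'-to-3'). When a supplied rearrangement table shows the
donor gene broken into intergenic space with the RNA acceptor downstream
of the DNA breakpoint (within a 300-kb scan window), the junction is a
**gene-to-intergenic fusion**; the entered exon rank is recorded (exon 2
of the first intact downstream sense gene is the canonical outcome,
because exon 1 starts at the transcription start site and has no splice
acceptor), along with the created intron length and a novel-exon flag.

**Premature polyA** calls require the A run to be non-templated (the
genome must not continue with *polyAMinRun* = 8 A's past the junction in
transcript sense), the junction to sit inside an exon of a protein-coding
gene, and more than *polyAMinDistance* = 10 bp of distance from the
transcript's canonical 3' edge; calls are split into coding-exon vs UTR by
the CDS span. The 8-base minimum run is our choice — no published value
exists — set high enough that a templated or sequencing-error tail cannot
fake it at the error rates the mapper tolerates.

**Reading frame.** The cumulative CDS length 5' of the breakpoint in the
donor must agree modulo 3 with the phase entering the acceptor's CDS.
Breakpoints in UTR yield `utr_involved`, flagged potentially productive
when the acceptor keeps its own translation start (the first exon of many
genes carries the ATG, so such fusions can still translate). Non-coding
partners yield `noncoding`; a protein-coding model without a CDS is an
error, not a silent downgrade. Tests check this against an independent
codon-walking oracle: the fused CDS is assembled at the sequence level and
translated; because fixture CDS interiors are free of stop codons in every
frame, "in frame" is equivalent to the translation running clean to a
single terminal stop.

**Antisense exons.** For 5'-to-5' fusions, per-base depth is accumulated
over the antisense gene's footprint from the reads the transcriptome
cannot explain; maximal runs of depth ≥ *antisenseMinDepth* = 3 are
reported as novel antisense exons with strand-aware GT-AG flags at both
edges. The threshold of 3 (with a 2-bp edge-consensus tolerance) encodes
the observation that these exons have surprisingly fixed edges without any
published number to import. Reciprocal pairs — both promoters active,
each gene donating sense sequence into the other's antisense — are flagged.

## Discordant-pair fusion calling

Pair ends are remapped as singletons (exact genome matches, both strands);
pairs bridging two genes cluster per gene pair, excluding pairs with a
mitochondrial end. Metrics per candidate: supporting and distinct
fragments per gene (fragments, not read ends, answer "unique reads"),
multimapping fraction, orientation-inconsistency percentage (relative to
the cluster's modal orientation), and a per-gene coefficient of variation
of mapping positions. The CV's reference frame is not published; we
measure positions inside the insert-size window anchored at the
breakpoint-proximal cluster edge, so a tight stack near the breakpoint
scores a low CV while scatter across the window scores high. (Measuring
relative to the minimum position would fix the CV of any uniform scatter
near 58% regardless of its width, making the 25% threshold undiscriminating;
the anchored frame restores the intended contrast.)

"Extremely high ranking" requires all of: more than 5 unique fragments in
each gene, CV below 25% on both sides, inconsistency below 5%, and a
multimapping fraction at or below 0.20 (the multimapping criterion has no
published threshold; 20% is our configurable interpretation). A fusion is
high-confidence when a split-read junction links the same gene pair with
compatible breakpoints — pair positions within the library insert size
(default 500 bp) of the split breakpoint on each gene — or when the
ranking passes outright.

## The X-inactivation Dirichlet-process model

At SNP *i*, `y_i ~ Bin(n_i, p_i)` with
`p_i = lambda_i * pi_i + (1 - pi_i)/2`: tumor transcripts are monoallelic
(X inactivation is clonal in the tumor), stromal transcripts balanced
(mosaic). `pi` gets a Dirichlet-process prior in truncated stick-breaking
form with C = 40 clusters, `V_h ~ Beta(1, alpha)`, `V_C = 1`,
`lambda_i ~ Bern(0.5)`, base measure U(0,1), `alpha ~ Gamma(0.01, 0.01)`.
Copy-number-aberrant regions must be excluded by the caller — the model
assumes diploid X territory.

The Gibbs sweep: (1) categorical allocation of each SNP using stick
weights times binomial likelihoods, computed in log space and normalized
per SNP so underflow can never zero a row; (2) conjugate Beta stick
updates; (3) a Metropolis-Hastings move per cluster location with proposal
`Beta(x'd, d(1-x'))` — mean-preserving around the current value — against
the collapsed target
`((1+pi)/2)^a * ((1-pi)/2)^b` with `a = sum(2*lam*y - lam*n + n - y)`,
`b = sum(y - 2*lam*y + lam*n)` over the cluster's SNPs; boundary proposals
are rejected because the proposal density is undefined there, and an empty
cluster reduces to the flat base measure; (4) phase flips with
`Pr(lambda=1|-) = 1/(1 + ((1-pi)/(1+pi))^(2y-n))`, computed through the
log ratio so `pi = 1` degenerates to the correct limits without division
errors (only `log(1-pi)` is clipped, by 1e-12, so `pi = 0` stays exactly
1/2); (5) `alpha | - ~ Gamma(C + A - 1, B - sum log(1 - V_l))` with the
same 1e-12 clip inside the log.

Chain defaults — 5,000 iterations, 2,000 burn-in, thinning 5 — are our
own: no published chain lengths exist. The proposal scale starts at
d = 20 and is auto-tuned during burn-in toward a 20–50% acceptance rate,
the "reasonable acceptance proportion" a practitioner would tune to by
hand. A split-half rhat above 1.1 on the overall-fraction trace warns,
never fails. Everything is reproducible from a single seed.

Summaries: per-SNP posterior mean tumor fraction; a stick-weighted kernel
density of cluster locations (invariant to cluster relabelling, bandwidth
0.02); and the **overall tumor-derived transcript fraction**, defined here
as the `n_i`-weighted posterior mean of `pi` over SNPs — the published
account says only that the per-patient data are integrated, so the
read-weighted mean is our explicit interpretation. The sampler accepts a
fixed `alpha` as an option; the dense-integration oracle used in testing
(grid over the two cluster locations and the stick fraction at C = 2)
needs a fixed concentration to be well defined, and fixing it is a
configuration choice, not a model change. The formulas treat SNPs as
exchangeable, so multiple SNPs in one gene carry independent phase
indicators — the per-SNP reading of the published per-SNP formulas.

## Excess aberrance ranking

Each rearrangement's carrier sample is ranked among n = 23 cohort samples
by normalized aberrant expression (any per-sample scalar is accepted;
aberrant junction reads per million mapped is the recommended one). Ties
break by average rank, with "max" available as a carrier-favouring
option. The mixture — top rank with probability theta, uniform otherwise
— makes the top-rank count `k ~ Bin(m, theta + (1-theta)/n)`, so
`theta_hat = (k/m - 1/n)/(1 - 1/n)`, truncated to [0,1]. Only the
top-rank point mass is modelled; effects at sub-maximal ranks would bias
theta downward, a deliberate conservatism. The 95% CI is profile
likelihood (chi-square cutoff), with a percentile bootstrap as an option;
at the cohort geometry used in testing (m = 4,234) the two agree closely.

## Mutation-expression analyses

VAFs are `alt/(ref+alt)` per assay; zero RNA coverage leaves the
transcriptomic VAF NA with the record kept. The NMD target zone is
"more than 50 bp upstream of the last exon-exon junction" in transcript
coordinates (the mechanistic literature says 50–55; the threshold is
configurable across that window); stops in the last exon, and single-exon
transcripts, escape. Transcript choice defaults to the longest CDS, and a
call that would differ on another isoform is flagged ambiguous rather than
silently committed. Splice positions count +1, +2, ... into the intron
from the donor and -1, -2, ... back from the acceptor, with exonic
positions reported separately; the per-position aberrant-splice table
carries exact binomial CIs against a deep-intron (> 100 bp) baseline.
Formal significance modelling between mutation classes is out of scope by
design; the tables are inputs to external statistics.

## The synthetic fixture and what it shows

The default fixture is a ~9.3-kb gene contig plus a 600-bp mitochondrial
decoy: five genes (three-to-five exons of 120 bp, introns 200–400 bp, all
edged GT..AG strand-aware, one minus-strand gene), 30-bp UTRs, CDS
interiors drawn from {A,C,G} so no reading frame can hit a stop before the
planted terminal TAA, and engineered features at fixed offsets: a cryptic
donor 10 bp inside an exon, alternative donor/acceptor motifs 6–7 bp into
introns, a premature-polyA junction 50 bp from the transcript end (backed
by a CCC plant so templated A-matching cannot blur it), and a latent
150-bp antisense exon (AC/CT motifs on the forward strand, i.e. GT-AG on
the antisense) inside an intron of the 5'-to-5' partner gene.

Junction reads (default depth 10, 75 bp, error-free) tile each engineered
junction at split offsets 16–42 so both sides keep an intact 13-mer, in
both orientations; the antisense fusion transcript is tiled end to end
with stacked edge windows so the antisense exon gets plateau coverage
with exact edges. Background reads tile every canonical transcript and
exist to be eaten by the pre-filter. Read errors are substitutions only,
honouring the mapper's mismatch rule; an indel mode is deliberately off.
X-SNP counts follow the generative model exactly (about 300 SNPs, cluster
locations 0.9/0.1 with weights 0.8/0.2, depth about 50 — the regime the
deconvolution is meant for); rank data use n = 23 samples and m = 4,234
rearrangements with a planted excess of 0.116, the cohort geometry the
estimator targets.

What passing on these fixtures shows: coordinate-exact agreement of the
seed-and-extend mapper with an exhaustive all-split-position aligner on
clean reads; category-exact end-to-end recovery of every event class with
zero false calls against a same-reference organoid background; parameter
recovery and grid-oracle agreement for the sampler; unbiasedness of the
excess estimator at cohort geometry. What it does not show: robustness to
sequencing indels, to paralogy and repetitive sequence (the toy genome is
nearly repeat-free), to expression-level heterogeneity (no
negative-binomial expression model), to annotation incompleteness, or to
genuinely diploid-violating X territory. Real-data use still needs the
usual vigilance on those fronts.

## Problem sizes and runtime posture

The shipped tests run the full pipeline on the fixture above (a few
hundred reads), the sampler at N = 300 / C = 40 / 4,000 iterations and at
N = 5 / C = 2 / 8,000 iterations against the dense oracle, and 200
replicates of the m = 4,234 rank simulation. These sizes were chosen to
make every oracle comparison sharp at desk scale; all of the algorithms
are linear in reads or SNPs and run unchanged at larger sizes.

## Known limitations

- The mapper resolves two-fragment reads; reads crossing two breakpoints
  (three fragments) are parked as unresolved rather than chained.
- Discordant-pair insert size comes from configuration, not estimated
  from data.
- The junction store is a flat TSV with a documented schema rather than an
  embedded database; the split-read placements export as text.
- Overlapping genes make breakpoint gene-assignment ambiguous; both genes
  are reported with an ambiguity flag, and the lexicographically first is
  used for labelling.
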