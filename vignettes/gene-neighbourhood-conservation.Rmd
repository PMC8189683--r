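---
title: "Methods: gene neighbourhood conservation with genecontext"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene neighbourhood conservation with genecontext}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem and the model

Genes that remain adjacent across large evolutionary distances are likely
to be functionally linked — members of one operon, a toxin–antitoxin pair,
a secretion system. `genecontext` quantifies and draws this signal. The
analysis object is the *neighbourhood*: a query gene plus up to *n*
flanking genes per side, counted by gene index in the annotation (not by a
base-pair window), so overlapping genes each occupy one slot and
pseudogenes and RNA genes count as flanks even though they encode no
protein.

Homology between neighbourhood-encoded proteins is decided by pairwise
local alignment significance, and *homologous groups* are the connected
components of the significant-hit graph. Single linkage was chosen
deliberately: an iterative profile search (the external backend) is
transitive by construction — if A recruits B and B recruits C, all three
belong to one family — and connected components are the graph-theoretic
expression of that semantics. The cost of single linkage, chaining through
promiscuous domains, is real on biological data but negligible on the
synthetic data used for validation; it is listed under limitations.

A group is *conserved* when its members come from at least two distinct
neighbourhoods. Conserved groups are numbered 1…G by descending
neighbourhood count, then descending member count, then first occurrence
in input order — so group 1 is always the most widely conserved flanking
family. The query family is always numbered and drawn in a reserved style,
even in the degenerate single-query case where "conserved in ≥ 2
neighbourhoods" cannot hold; there the conserved flag stays FALSE while
the number is kept, which is the one place the package departs from a
strict number ⇔ conserved equivalence.

## Scoring model and constants

The builtin scorer is Smith–Waterman with affine gaps under BLOSUM62
(values hard-coded as data): a gap of length *k* costs 11 + *k* (opening
11, extension 1), the classic protein-search default. Raw scores are
converted to bit scores with fixed Karlin–Altschul constants λ = 0.267 and
K = 0.041 — the published values for gapped BLOSUM62 11/1 — rather than
estimated per run, trading a little statistical fidelity for bit-for-bit
reproducibility across platforms. The E-value uses query-length ×
database-residues search-space scaling,

  E = m · N · 2^(−S′),

with N the total residue count over all neighbourhood proteins in the run.
Because E scales with the first sequence's length it is directional; an
undirected edge takes the smaller of the two directed E-values
(equivalently, the shorter sequence acts as query). Ambiguity codes
B/J/Z/X are scored by their BLOSUM62 rows; other symbols are rejected with
the offending character named.

The builtin backend performs a single search pass; the *iterations*
parameter binds only to the external `jackhmmer` backend (per-pair
E-values parsed from its tabular output). Running the builtin backend with
iterations > 1 records a warning rather than imitating profile iteration
poorly.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `n_flank` | 4 | flanking genes per side (count, not bp) |
| `evalue_cutoff` | 1e-3 | per-pair significance threshold; lower = stricter, fewer/cleaner groups |
| `iterations` | 3 | profile-search rounds, external backend only |
| `backend` | builtin | `builtin` Smith–Waterman or `external_profile` (jackhmmer) |
| `bp_per_px` | 20 | diagram scale; glyph widths and gaps stay proportional to bp |
| `seed` | 0 | rotates the palette hue phase; all outputs deterministic given config + seed |

Defaults for `n_flank`, `evalue_cutoff` and `iterations` are conventional
sane values for neighbourhood analysis; the knobs, not the defaults, come
from the tool tradition this package follows.

## Rendering semantics

Every gene is an arrow to scale (lengths and intergenic gaps proportional
to bp; ratio error below one pixel). Strand normalization mirrors
minus-strand queries — coordinates reflected through the contig, strands
inverted, sides swapped — so all queries point right and homologous
contexts align visually; the `flipped` flag is kept in the legend. Styles:
conserved = filled with the group colour and numbered; query family =
reserved red; non-conserved coding = unfilled, grey border; pseudogene =
grey fill, blue border; non-coding = hatch (our invention; the visual
tradition defines only the first three). Truncated contig edges end at the
last real gene — no placeholder glyphs. Palettes are evenly spaced HSV
hues in group order (spacing 360°/G, fixed saturation/value); the seed
only rotates the phase, so group colours are stable across reruns.

The pennant-flag tree reduces each neighbourhood to a strip of triangular
flags beside its leaf, one flag per slot *including* non-conserved and
pseudogene slots (the alternative — omitting unnumbered slots — was
considered and rejected because flag counts then no longer reflect
neighbourhood size). Strips are left-padded so query flags form a column.

## The guide tree

When no user Newick is given, the tree is neighbour joining on
d = 1 − fractional identity, identity taken over the columns of the
builtin local alignment. Leaves are pre-sorted lexicographically so NJ
tie-breaking is deterministic; the tree is midpoint-rooted; negative NJ
branch lengths are clamped to zero with a logged note. This is a
convenience tree for ordering rows, not a phylogenetic inference tool —
users wanting a defensible phylogeny should pass their own Newick, which
takes precedence.

## The synthetic world

`generate_fixture()` emulates the structures the pipeline must handle:
multi-contig assemblies, RefSeq-dialect GFF3 (CDS rows carrying
`protein_id`, pseudogenes flagged three ways, RNA genes), one planted
query family spanning all assemblies, and F planted flanking families each
placed at a fixed slot relative to the query (synteny), with members
derived from a family ancestor by substitution-only mutation to an exact
target identity. Defaults — 6 assemblies, 2 contigs × 9 genes, 4 families
at ancestor-identity 0.8, pseudogene and non-coding rates 0.1, protein
lengths 80–150 aa — were chosen once as a realistic small bacterial
neighbourhood panel and are not tuned against test outcomes; validation
sweeps the stated bounds (3–10 assemblies, 2–12 families, identity
0.6–1.0) from fixed seeds.

What the generator does **not** emulate: sequence indels (substitutions
only, so identity arithmetic stays exact), codon-level evolution, gene
rearrangement within neighbourhoods, paralogy between background genes,
and circular replicons. A green planted-family test therefore establishes
that the machinery recovers unambiguous families at moderate divergence —
not that the E-value model matches real database statistics.

## Numerical and design choices

- Coordinates stay GFF3 1-based inclusive everywhere; pixel conversion is
  the single explicit division by `bp_per_px`.
- Multi-segment CDS sharing a `protein_id` merge to min(start)…max(end).
- Pseudogene detection: `pseudo=true`, `gene_biotype=pseudogene`, or
  feature type `pseudogene` — the annotation dialects RefSeq actually
  ships.
- A protein accession found in several assemblies without a
  disambiguating assembly id is a hard error naming the candidates;
  guessing a genome silently would corrupt the conservation counts.
- Circular replicons are truncated at contig boundaries (flagged), since
  annotation files do not reliably mark circularity.
- No coverage or bidirectional-best-hit filters are applied beyond the
  E-value cut-off; the cut-off is the single stringency knob.
- Outputs are written to a temporary directory and renamed into place, so
  failed runs leave no partial files; SVG emission contains no timestamps
  or random ids, making reruns byte-identical.

## Known limitations

Single-linkage chaining through shared domains can merge distinct
families on real proteomes; no domain-level decomposition is attempted.
The fixed Karlin–Altschul constants are approximations for short or
compositionally biased sequences. The builtin all-vs-all scales
quadratically in total neighbourhood proteins — fine for tens of queries,
not for thousands (use the external profile backend there). Eukaryotic
gene models beyond multi-segment CDS merging are out of scope, as are
live database fetching and the upstream homologue-search step of the web
workflow.
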