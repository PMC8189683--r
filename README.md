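# genecontext

Conservation of gene order over evolutionary distance is a strong signal of
functional association: genes that stay neighbours across distantly related
bacteria, archaea or phages are often parts of one operon, pathway or
system (toxin–antitoxin pairs, secretion systems, biosynthesis clusters).
`genecontext` analyses and visualizes this signal for a user-chosen set of
query proteins against locally stored annotated genome assemblies, for
microbiologists and molecular evolution researchers who want full control
over the genomes being compared and publication-quality vector output.

## What it computes

Given queries *q₁…q_Q* (protein accessions, optionally pinned to an
assembly) and assemblies in RefSeq-dialect GFF3 + protein FASTA:

1. **Locate & extract.** Each query gene is found in its assembly and its
   neighbourhood — the query plus up to *n* flanking genes per side,
   counted by gene index — is extracted. Pseudogenes and non-coding genes
   occupy flank slots; neighbourhoods are mirrored when the query is on the
   minus strand so the query always points right; contig edges set
   truncation flags instead of inventing placeholders.
2. **Cluster.** All neighbourhood-encoded proteins (queries included) are
   compared all-vs-all with a Smith–Waterman local aligner (BLOSUM62,
   affine gaps 11 + k). Raw scores *S* become bit scores
   *S′ = (λS − ln K)/ln 2* with fixed Karlin–Altschul constants
   (λ = 0.267, K = 0.041), and pairs are kept when
   *E = m·N·2^(−S′) ≤* the cut-off (*m* = query length, *N* = total
   database residues). Homologous groups are the connected components of
   this significant-hit graph (single linkage). An external iterative
   profile search (`jackhmmer`) can replace the builtin scorer.
3. **Assign & render.** Components found in ≥ 2 neighbourhoods are
   *conserved* and numbered 1…G (widest spread first); singletons are drawn
   empty with grey borders, pseudogenes grey with blue borders, non-coding
   genes hatched. Outputs: a to-scale SVG gene-arrow diagram, a
   tab-separated legend, and (optionally) a phylogenetic tree — built by
   neighbour joining on alignment identities, or user-supplied Newick —
   annotated with colour- and number-coded triangular pennant flags.

A deterministic fixture generator (`fixture_spec()` / `generate_fixture()`)
creates synthetic assemblies with planted homologous families and a ground
truth table, so the whole pipeline is testable offline.

## Worked example

```r
library(genecontext)

fx <- generate_fixture(fixture_spec(n_assemblies = 4, n_families = 3, seed = 42),
                       dir = "demo_fx")
cfg <- run_config("demo_fx/queries.txt",
                  lapply(seq_along(fx$assemblies), function(i)
                    list(gff = fx$files$gff[i], faa = fx$files$faa[i],
                         assembly_id = fx$assemblies[[i]]$assembly_id)),
                  n_flank = 3, evalue_cutoff = 1e-6, seed = 1,
                  outdir = "demo_out")
report <- run_neighbourhood_analysis(cfg)
print(report)
#> <run_report> 4/4 queries ok; 4 numbered group(s)
#>   outputs: neighbourhoods.svg, description.tsv, tree.nwk, tree.svg
#>   1 log message(s)
report$groups[, c("group_id", "colour", "product", "neighbourhood_count")]
#>   group_id  colour                  product neighbourhood_count
#> 1        1 #D9BF62 planted family 3 protein                   4
#> 2        2 #62D9BF planted family 1 protein                   4
#> 3        3 #e41a1c    planted query protein                   4
#> 4        4 #BF62D9 planted family 2 protein                   4
```

All three planted flanking-gene families and the query family were
recovered in all 4 neighbourhoods, so each is numbered and coloured
(the query family keeps the reserved red). The legend file pairs every
drawn gene with its group, colour and coordinates:

```
#query_id      assembly_id  contig     slot  protein_id     group  colour   product                   strand  start  end   flipped
WP_00100005.1  GCF_000001.1 NZ_CTG1_1  -3    WP_00100002.1  NC     none     hypothetical protein      +       448    780   false
WP_00100005.1  GCF_000001.1 NZ_CTG1_1  -2    WP_00100003.1  1      #D9BF62  planted family 3 protein  -       891    1235  false
...
```

`NC` marks a coding gene not conserved in the dataset (drawn unfilled with
a grey border). `demo_out/tree.nwk` holds the midpoint-rooted
neighbour-joining guide tree over the queries, and `tree.svg` the same tree
with one pennant flag per neighbourhood gene.

The same run works from the command line:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/genecontext.R", package="genecontext"))')" \
  --queries demo_fx/queries.txt \
  --assembly demo_fx/GCF_000001.1.gff,demo_fx/GCF_000001.1.faa,GCF_000001.1 \
  --assembly demo_fx/GCF_000002.1.gff,demo_fx/GCF_000002.1.faa,GCF_000002.1 \
  --flank 3 --evalue 1e-6 --seed 1 --outdir demo_out
```

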