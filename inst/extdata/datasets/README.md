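# Curated training sets (user-supplied)

The benchmark reproduction tests look here for the curated GenBank-derived
training sets, which are not redistributable with the package. To run those
benchmarks, place the following uncompressed protein FASTA files in this
directory (annotations in the headers) before installing:

- `structural_positive.fasta` / `structural_negative.fasta` — phage virion
  components (capsid, tail, fiber, baseplate, portal, connector, tape
  measure, neck, collar) vs. non-structural phage/prokaryotic proteins,
  deduplicated at 90% identity, minimum length 200.
- `capsid_positive.fasta` / `capsid_negative.fasta` — major capsid proteins
  vs. non-capsid proteins, minimum length 300.
- `tail_positive.fasta` / `tail_negative.fasta` — tail apparatus proteins
  vs. non-tail proteins, minimum length 150.

Without these files, the corresponding acceptance tests report a failure
explaining that the data are absent; all other tests are self-contained.
Synthetic stand-ins can be generated with `make_benchmark()` or the
`simulate` CLI subcommand, but they measure the pipeline, not the published
sequence sets.
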