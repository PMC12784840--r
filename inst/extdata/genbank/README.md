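# GenBank records for the mygalomorph comparison

The reference-reproduction checks and the worked examples on real data
expect the seven complete mygalomorph mitochondrial genomes in this
directory as GenBank flat files (`*.gb`). The records are fetched from
NCBI and are not redistributed with the package:

- *Brachypelma albiceps* — accession `NC_062668` (BioProject PRJNA904502)
- *Cyriopagopus hainanus*
- *Cyriopagopus schmidti*
- *Atypus karschi*
- *Calisoga longitarsis*
- *Phyxioschema suthepium*
- *Bothriocyrtum californicum*

Fetch, e.g., with EDirect or plain HTTPS:

```sh
acc=NC_062668
curl -o ${acc}.gb "https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi?db=nuccore&id=${acc}&rettype=gb&retmode=text"
```

For the six comparison species, search `"<species name>"[Organism] AND
mitochondrion[Title] AND complete genome[Title]` in the nuccore database
and fetch the matching accession the same way. Any file name ending in
`.gb` works; records are identified by their ORGANISM line.
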