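# Hand-built gene-record rows for aligner tests. The gene is laid out as
# stem5 (7) + body + stem3 (7) + whatever 3' residues the test appends;
# contexts are 10 bases.
makeRecord <- function(gene, downstream = "AUGCAUGCAU",
                       upstream = "AAAAAAAAAA",
                       acc3 = ".", recordId = "r1", priorClass = "Met") {
  data.frame(
    record_id = recordId,
    genome_id = "G1",
    taxon_id = 1000L,
    gene_seq = gene,
    upstream = upstream,
    downstream = downstream,
    anticodon = "CAU",
    prior_class = priorClass,
    acc5_pos = paste(1:7, collapse = ","),
    acc3_pos = acc3
  )
}

# gene: stem5 GCGGAUU + 45-base body + stem3 AAUCCGC (the complement,
# 66..72) + tail3p appended after the stem (discriminator etc.)
makeStemGene <- function(tail3p, body = strrep("A", 45)) {
  paste0("GCGGAUU", body, "AAUCCGC", tail3p)
}

sprinzlBase <- function(ann, coord) {
  cd <- sprinzlCoords(ann)
  cd$base[cd$sprinzl == coord]
}
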