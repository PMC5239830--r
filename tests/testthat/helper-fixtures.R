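# Small in-code fixtures shared across test files.

# a tiny two-tier + genome reference set with known sequences
tiny_tiers <- function(seed = 42) {
  set.seed(seed)
  t1 <- reference_tier(
    1,
    c(adapter_x = random_dna(35), trna1 = random_dna(80),
      rrna1 = random_dna(500), mito1 = random_dna(300)),
    c("adapter", "tRNA", "rRNA", "mitochondrial_RNA"),
    "tiny tier 1")
  t2 <- reference_tier(
    2,
    c(mrna1 = random_dna(800), mrna2 = random_dna(600),
      ncrna1 = random_dna(400)),
    c("mRNA", "mRNA", "ncRNA"),
    "tiny tier 2")
  t3 <- reference_tier(3, c(chr1 = random_dna(3000)),
                       description = "tiny genome")
  list(t1, t2, t3)
}

# color-encode a nucleotide read the way the platform would
as_color_read <- function(bases, primer = "T", id = "read1") {
  color_reads(id, primer, oracle_encode(bases, primer))
}

# write a tier to fasta + classmap files, return the two paths
write_tier_files <- function(tier, dir, stem) {
  fa <- file.path(dir, paste0(stem, ".fasta"))
  cm <- file.path(dir, paste0(stem, "_classmap.tsv"))
  write_fasta(tier$seqs, fa)
  write_class_map(tier$classes, cm)
  c(fa, cm)
}
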