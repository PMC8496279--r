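# Shared fixtures, built in code at test time.

# Small synthetic SFS dataset with known parameters.
quick_sfs <- function(gamma = 0, kappa = 3, theta = 1000, n = 21L,
                      seed = 1L, ...) {
  simulate_class_sfs(sim_config(
    gamma = gamma, kappa = kappa,
    theta_ws = theta, theta_sw = theta, theta_neu = theta,
    n = n, seed = seed, ...
  ))
}

# Toy two-chromosome genome and matching GFF3 annotation.  Gene layout on
# chrA (+): exon 1-100, intron 101-165 (65 bp), exon 166-260,
# intron 261-326 (66 bp), exon 327-400.
# On chrB (-): exon 1-80, intron 81-145 (65 bp), exon 146-240.
toy_genome <- function(seed = 42L) {
  set.seed(seed)
  seqs <- Biostrings::DNAStringSet(c(
    chrA = paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE),
                 collapse = ""),
    chrB = paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                 collapse = "")
  ))
  seqs
}

toy_gff_lines <- function() {
  c(
    "##gff-version 3",
    "chrA\ttoy\tgene\t1\t400\t.\t+\t.\tID=g1",
    "chrA\ttoy\tmRNA\t1\t400\t.\t+\t.\tID=t1;Parent=g1",
    "chrA\ttoy\texon\t1\t100\t.\t+\t.\tID=e1;Parent=t1",
    "chrA\ttoy\texon\t166\t260\t.\t+\t.\tID=e2;Parent=t1",
    "chrA\ttoy\texon\t327\t400\t.\t+\t.\tID=e3;Parent=t1",
    "chrB\ttoy\tgene\t1\t240\t.\t-\t.\tID=g2",
    "chrB\ttoy\tmRNA\t1\t240\t.\t-\t.\tID=t2;Parent=g2",
    "chrB\ttoy\texon\t1\t80\t.\t-\t.\tID=e4;Parent=t2",
    "chrB\ttoy\texon\t146\t240\t.\t-\t.\tID=e5;Parent=t2"
  )
}

write_toy_gff <- function(lines = toy_gff_lines()) {
  path <- tempfile(fileext = ".gff3")
  writeLines(lines, path)
  path
}

# WGA-BED rows mapping species-a positions to identical species-b and
# outgroup positions (same coordinates, different chrom labels).
toy_wga <- function(pos_a, allele_a = "A", allele_b = "A",
                    allele_out = "A", chrom_a = "chrA",
                    chrom_b = "chrB2", chrom_out = "chrO") {
  tibble::tibble(
    chrom_a = chrom_a, start_a = pos_a, end_a = pos_a + 1L, strand_a = "+",
    allele_a = allele_a,
    chrom_b = chrom_b, start_b = pos_a, end_b = pos_a + 1L, strand_b = "+",
    allele_b = allele_b,
    chrom_out = chrom_out, start_out = pos_a, end_out = pos_a + 1L,
    strand_out = "+", allele_out = allele_out
  )
}

# Independent brute-force SFS shape by adaptive quadrature.
brute_force_shape <- function(gamma, n) {
  vapply(seq_len(n - 1L), function(j) {
    stats::integrate(function(x) {
      choose(n, j) * x^j * (1 - x)^(n - j) *
        (1 - exp(-gamma * (1 - x))) / ((1 - exp(-gamma)) * x * (1 - x))
    }, 0, 1, rel.tol = 1e-10)$value
  }, numeric(1))
}
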