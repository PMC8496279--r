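test_that("short introns yield the strand-aware 8-30 bp region", {
  genome <- toy_genome()
  si <- extract_short_introns(write_toy_gff(), genome)
  # chrA: intron 101-165 (65 bp, +): SI = genomic 108..130 (23 sites);
  # the 66 bp intron 261-326 is excluded entirely.
  # chrB: intron 81-145 (65 bp, -): SI = genomic 96..138 5' from the right.
  expect_equal(nrow(si), 2L)
  plus <- si[si$strand == "+", ]
  expect_equal(plus$chrom, "chrA")
  expect_equal(plus$start, 107L) # 0-based half-open for 1-based 108..130
  expect_equal(plus$end, 130L)
  expect_equal(plus$si_length, 23L)
  expect_equal(plus$intron_length, 65L)
  expect_equal(plus$seq,
               as.character(Biostrings::subseq(genome[["chrA"]], 108, 130)))

  minus <- si[si$strand == "-", ]
  expect_equal(minus$chrom, "chrB")
  # 5' end of a minus-strand intron is its right edge (145): positions
  # 8..30 from the 5' end are genomic 116..138
  expect_equal(minus$start, 115L)
  expect_equal(minus$end, 138L)
  expect_equal(
    minus$seq,
    as.character(Biostrings::reverseComplement(
      Biostrings::subseq(genome[["chrB"]], 116, 138)
    ))
  )
  expect_equal(si$gc, compute_gc(si$seq))
})

test_that("SI candidates overlapping exons or long introns are excluded", {
  # add an exon covering the chrA SI region via a second transcript
  lines <- c(toy_gff_lines(),
             "chrA\ttoy\tmRNA\t90\t160\t.\t+\t.\tID=t3;Parent=g1",
             "chrA\ttoy\texon\t90\t160\t.\t+\t.\tID=e6;Parent=t3")
  si <- extract_short_introns(write_toy_gff(lines), toy_genome())
  expect_false(any(si$chrom == "chrA"))
  expect_true(any(si$chrom == "chrB"))
})

test_that("malformed annotation reports the offending line", {
  lines <- toy_gff_lines()
  lines[4] <- "chrA\ttoy\texon\t1\t100" # truncated record
  expect_error(extract_short_introns(write_toy_gff(lines), toy_genome()),
               "line 4")
  lines2 <- toy_gff_lines()
  lines2[5] <- "chrA\ttoy\texon\tX\t260\t.\t+\t.\tID=e2;Parent=t1"
  expect_error(extract_short_introns(write_toy_gff(lines2), toy_genome()),
               "line 5")
  # annotation beyond the reference is a coordinate error
  lines3 <- c(toy_gff_lines(),
              "chrB\ttoy\tmRNA\t1\t900\t.\t+\t.\tID=t9;Parent=g2",
              "chrB\ttoy\texon\t1\t700\t.\t+\t.\tID=e9;Parent=t9",
              "chrB\ttoy\texon\t766\t900\t.\t+\t.\tID=e10;Parent=t9")
  expect_error(extract_short_introns(write_toy_gff(lines3), toy_genome()),
               "beyond|not in the genome")
})

test_that("reverse-strand SI sequences equal the reverse complement slice", {
  set.seed(33)
  for (rep in 1:5) {
    L <- 400L
    genome <- Biostrings::DNAStringSet(c(chrZ = paste(
      sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")))
    ilen <- sample(30:65, 1)
    istart <- 101L
    iend <- istart + ilen - 1L
    lines <- c(
      "##gff-version 3",
      sprintf("chrZ\tt\tmRNA\t1\t%d\t.\t-\t.\tID=tt;Parent=gg", iend + 50L),
      sprintf("chrZ\tt\texon\t1\t%d\t.\t-\t.\tID=x1;Parent=tt", istart - 1L),
      sprintf("chrZ\tt\texon\t%d\t%d\t.\t-\t.\tID=x2;Parent=tt",
              iend + 1L, iend + 50L)
    )
    si <- extract_short_introns(write_toy_gff(lines), genome)
    expect_equal(nrow(si), 1L)
    expect_equal(
      si$seq,
      as.character(Biostrings::reverseComplement(
        Biostrings::subseq(genome[["chrZ"]], si$start + 1L, si$end)
      ))
    )
    expect_equal(si$si_length, min(30L, ilen) - 8L + 1L)
  }
})

make_si_pair <- function() {
  genome <- toy_genome()
  si_a <- extract_short_introns(write_toy_gff(), genome)
  si_a <- si_a[si_a$chrom == "chrA", ]
  # species b: same SI interval on its own chromosome label
  si_b <- si_a
  si_b$chrom <- "chrB2"
  si_b$intron_id <- sub("chrA", "chrB2", si_b$intron_id)
  list(si_a = si_a, si_b = si_b)
}

test_that("homologous intersection keeps only dual-SI, gap-free columns", {
  p <- make_si_pair()
  wga <- dplyr::bind_rows(
    toy_wga(110L), # inside both SI regions
    toy_wga(50L), # outside both
    toy_wga(111L)[, ] |> dplyr::mutate(chrom_b = "elsewhere"), # SI in a only
    toy_wga(112L, allele_out = "-"), # outgroup gap
    toy_wga(113L, allele_b = "N"), # missing species b allele
    toy_wga(114L, chrom_out = NA) # column without the outgroup
  )
  sites <- intersect_homologous_sites(p$si_a, p$si_b, wga)
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$pos_a, 110L)
  expect_equal(attr(sites, "n_skipped"), 1L)
  # retained coordinates round-trip through the WGA mapping
  expect_equal(sites$pos_b,
               wga$start_b[match(sites$pos_a, wga$start_a)])
})

test_that("site filters drop masked, low-quality, and excluded sites", {
  p <- make_si_pair()
  wga <- dplyr::bind_rows(
    toy_wga(110L),
    toy_wga(115L, allele_a = "a"), # soft-masked in species a
    toy_wga(120L),
    toy_wga(125L),
    toy_wga(128L)
  )
  sites <- intersect_homologous_sites(p$si_a, p$si_b, wga)
  expect_equal(nrow(sites), 5L)
  qual <- tibble::tibble(chrom = "chrA", pos = c(120L, 125L),
                         qual = c(29, 45))
  ncx <- tibble::tibble(chrom = "chrA", start = 128L, end = 129L)
  filtered <- apply_site_filters(
    sites,
    autosomes_a = "chrA", autosomes_b = "chrB2",
    qual = qual, qual_threshold = 30,
    exclude_a = ncx
  )
  # masked 115 out, QUAL 29 at 120 out, excluded region 128 out;
  # 110 (no variant record -> passes) and 125 (QUAL 45) stay
  expect_equal(sort(filtered$pos_a), c(110L, 125L))
  att <- attr(filtered, "attrition")
  expect_equal(att$removed[att$filter == "soft_masked"], 1L)
  expect_equal(att$removed[att$filter == "low_qual"], 1L)
  # idempotence
  again <- apply_site_filters(
    filtered, autosomes_a = "chrA", autosomes_b = "chrB2",
    qual = qual, qual_threshold = 30, exclude_a = ncx
  )
  expect_equal(again$site_id, filtered$site_id)
})

test_that("polymorphism mode drops sites with missing sample alleles", {
  p <- make_si_pair()
  wga <- dplyr::bind_rows(toy_wga(110L), toy_wga(118L))
  sites <- intersect_homologous_sites(p$si_a, p$si_b, wga)
  sites$ingroup_alleles <- c("ACGTA", "ACGNN")
  div <- apply_site_filters(sites, mode = "divergence")
  expect_equal(nrow(div), 2L)
  pol <- apply_site_filters(sites, mode = "polymorphism")
  expect_equal(nrow(pol), 1L)
  expect_equal(pol$pos_a, 110L)
})
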